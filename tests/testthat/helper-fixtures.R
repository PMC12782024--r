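# Shared fixtures: small deterministic data generators used across tests.

# single-condition trial frame at the standard design (7 durations x n_rep)
make_trials <- function(n_rep = 8L) {
  data.frame(condition_category = "environmental", condition_valence = "pleasant",
             duration_s = rep(bisection_durations(), each = n_rep),
             stringsAsFactors = FALSE)
}

# binomial counts drawn from a logistic psychometric curve
counts_from_logistic <- function(alpha, beta, gamma = 0, lambda = 0,
                                 n_trials = 8L, seed = NULL, exact = FALSE) {
  durs <- bisection_durations()
  p <- gamma + (1 - gamma - lambda) * plogis((durs - alpha) / beta)
  n_long <- if (exact) {
    round(p * n_trials)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rbinom(length(durs), n_trials, p)
  }
  data.frame(duration_s = durs, n_long = n_long, n_trials = n_trials)
}

# dense 4-D grid maximum of the penalized log-likelihood: the independent
# brute-force oracle the multi-start MLE is checked against
grid_search_loglik <- function(counts, family = "logistic",
                               penalty_shape = 20) {
  t <- counts$duration_s; nl <- counts$n_long; nt <- counts$n_trials
  F <- if (family == "logistic") plogis else pnorm
  alphas <- seq(1.5, 5.5, by = 0.05)
  betas <- seq(0.04, 1.6, by = 0.04)
  asyms <- seq(0, 0.25, by = 0.025)
  best <- -Inf
  for (g in asyms) for (l in asyms) {
    pen <- (penalty_shape - 1) * (log(1 - g) + log(1 - l))
    for (b in betas) {
      P <- g + (1 - g - l) * F(outer(alphas, t, "-") * (-1 / b))
      P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      ll <- as.numeric(log(P) %*% nl + log1p(-P) %*% (nt - nl)) + pen
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}

# small synthetic long-format metrics table for the mixed model
make_long_metrics <- function(seed = 1, group_effect = 0, category_effect = 0,
                              n_per_group = c(controls = 6, AD = 4, bvFTD = 4),
                              sd_participant = 0.3, sd_resid = 0.3) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      pid <- pid + 1
      u <- rnorm(1, 0, sd_participant)
      for (cat in c("environmental", "human")) for (val in c("pleasant", "unpleasant")) {
        mu <- 3.5 + u +
          (if (cat == "human") category_effect else 0) +
          (if (g != "controls") group_effect else 0)
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = sprintf("P%03d", pid), group = g,
          semantic_category = cat, valence = val,
          bp = rnorm(1, mu, sd_resid), log_wr = rnorm(1, log(0.2), 0.3),
          wr = 0.2, fit_ok = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# patient table with deltas + covariates for association tests
make_assoc_data <- function(seed = 1, n = 46, slope = 0, noise_sd = 0.5,
                            regions = default_roi_family(),
                            planted_region = "right_precuneus",
                            condition = "environmental-pleasant") {
  set.seed(seed)
  groups <- rep(c("AD", "lvPPA", "nfvPPA", "svPPA", "bvFTD"),
                length.out = n)
  ids <- sprintf("P%03d", seq_len(n))
  deltas <- data.frame(participant_id = ids, group = groups,
                       condition = condition,
                       semantic_category = strsplit(condition, "-")[[1]][1],
                       valence = strsplit(condition, "-")[[1]][2],
                       delta = rnorm(n, 0.3, 0.5), stringsAsFactors = FALSE)
  cov <- data.frame(participant_id = ids, group = groups,
                    age = rnorm(n, 69, 6), tiv = rnorm(n, 1400, 110),
                    mmse = round(pmin(27, rnorm(n, 21, 4))),
                    stringsAsFactors = FALSE)
  eff <- data.frame(region = planted_region, condition = condition,
                    slope = slope, stringsAsFactors = FALSE)
  roi <- simulate_roi_volumes(deltas, cov, effects = eff, regions = regions,
                              noise_sd = noise_sd, seed = seed + 1)
  sd_tab <- structure(list(
    deltas = deltas,
    condition_sign = data.frame(condition = condition, control_mean = 3.5,
                                overall_sign = sign(mean(deltas$delta)),
                                stringsAsFactors = FALSE)),
    class = "signed_differences")
  list(roi = roi, sd_tab = sd_tab, deltas = deltas, cov = cov)
}
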