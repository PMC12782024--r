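# Scalar-timing (pacemaker-accumulator) responder model.
#
# A responder accumulates pulses at a condition-dependent rate: arousal and
# attention open the pacemaker gate, so subjective duration is gain * t with
# multiplicative (scalar) noise whose SD grows proportionally with t. The
# trial decision compares the noisy subjective duration against a fixed,
# memory-derived criterion; lapses replace the decision with a coin flip.

#' Construct internal-clock parameters for a synthetic responder
#'
#' @param gain Positive pacemaker gain; either a single number or a named
#'   vector over condition labels (arousal/attention modulation per
#'   condition).
#' @param criterion Decision boundary in subjective seconds, strictly between
#'   the 2 s and 5 s references.
#' @param weber_coef Positive coefficient of variation of subjective
#'   duration; scalar or named per-condition vector.
#' @param lapse Probability in `[0, 0.5)` of a stimulus-independent random
#'   response.
#' @return An object of class `clock_params`.
#' @export
clock_params <- function(gain, criterion = 3.5, weber_coef = 0.15, lapse = 0) {
  stopifnot(all(gain > 0), all(weber_coef > 0))
  if (criterion <= 2 || criterion >= 5) {
    stop("criterion must lie strictly between the 2 s and 5 s references",
         call. = FALSE)
  }
  if (lapse < 0 || lapse >= 0.5) stop("lapse must be in [0, 0.5)", call. = FALSE)
  structure(list(gain = gain, criterion = criterion,
                 weber_coef = weber_coef, lapse = lapse),
            class = "clock_params")
}

param_for <- function(x, condition) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (is.null(names(x)) || !condition %in% names(x)) {
    stop(sprintf("no parameter value for condition '%s'", condition),
         call. = FALSE)
  }
  unname(x[[condition]])
}

#' Analytic probability of a "long" response under the clock model
#'
#' `P(long | t) = lapse/2 + (1 - lapse) * Phi((g*t - c) / (w*g*t))`, the exact
#' response curve implied by normally distributed subjective duration with
#' scalar noise and a fixed criterion.
#'
#' @param params A [clock_params()] object.
#' @param t Stimulus duration(s) in seconds.
#' @param condition Condition label used to resolve per-condition parameters
#'   (ignored for scalar parameters).
#' @return Probability vector the same length as `t`.
#' @export
clock_p_long <- function(params, t, condition = NULL) {
  g <- if (is.null(condition)) unname(params$gain[1]) else param_for(params$gain, condition)
  w <- if (is.null(condition)) unname(params$weber_coef[1]) else param_for(params$weber_coef, condition)
  core <- stats::pnorm((g * t - params$criterion) / (w * g * t))
  params$lapse / 2 + (1 - params$lapse) * core
}

#' Analytic bisection point and Weber's ratio of the clock model
#'
#' With zero lapse the response curve crosses 0.5 at `criterion / gain`; its
#' quantiles are `t_p = criterion / (gain * (1 - w * z_p))`, giving Weber's
#' ratio `2*w*z75 / (1 - (w*z75)^2)` independently of gain.
#'
#' @inheritParams clock_p_long
#' @return List with `bp`, `q25`, `q75`, `wr`.
#' @export
clock_metrics <- function(params, condition = NULL) {
  g <- if (is.null(condition)) unname(params$gain[1]) else param_for(params$gain, condition)
  w <- if (is.null(condition)) unname(params$weber_coef[1]) else param_for(params$weber_coef, condition)
  z <- stats::qnorm(0.75)
  if (w * z >= 1) stop("weber_coef too large: 0.75 quantile undefined", call. = FALSE)
  bp <- params$criterion / g
  q25 <- params$criterion / (g * (1 + w * z))
  q75 <- params$criterion / (g * (1 - w * z))
  list(bp = bp, q25 = q25, q75 = q75, wr = (q75 - q25) / bp)
}

#' Invert target bisection point and Weber's ratio to clock parameters
#'
#' Solves for the pacemaker gain and Weber coefficient so that the model's
#' analytic (lapse-free) response curve crosses 0.5 exactly at `bp` and its
#' analytic Weber's ratio equals `wr`: `gain = criterion / bp` and
#' `w = (sqrt(1 + wr^2) - 1) / (wr * z75)` with `z75 = qnorm(0.75)`.
#'
#' @param bp Target bisection point in seconds, strictly inside (2, 5).
#' @param wr Target Weber's ratio, > 0.
#' @param lapse Lapse probability (does not move the 0.5 crossing because
#'   lapses split evenly between responses).
#' @param criterion Decision criterion in seconds.
#' @return A single-condition [clock_params()] object.
#' @export
params_from_targets <- function(bp, wr, lapse = 0, criterion = 3.5) {
  if (bp <= 2 || bp >= 5) stop("target bp must lie strictly in (2, 5)", call. = FALSE)
  if (wr <= 0) stop("target wr must be positive", call. = FALSE)
  z <- stats::qnorm(0.75)
  w <- (sqrt(1 + wr^2) - 1) / (wr * z)
  clock_params(gain = criterion / bp, criterion = criterion,
               weber_coef = w, lapse = lapse)
}

#' Simulate short/long responses for scheduled trials
#'
#' With probability `lapse` the response is a fair coin flip; otherwise the
#' subjective duration is drawn `Normal(g*t, (w*g*t)^2)` and the response is
#' "long" iff it exceeds the criterion.
#'
#' @param params [clock_params()] for the responder.
#' @param trials Schedule data.frame with `condition_category`,
#'   `condition_valence`, `duration_s`.
#' @return Character vector of "short"/"long", one per trial row.
#' @export
simulate_responses <- function(params, trials) {
  cond <- paste(trials$condition_category, trials$condition_valence, sep = "-")
  t <- trials$duration_s
  g <- vapply(cond, function(cc) param_for(params$gain, cc), 0)
  w <- vapply(cond, function(cc) param_for(params$weber_coef, cc), 0)
  tau <- stats::rnorm(length(t), mean = g * t, sd = w * g * t)
  resp <- ifelse(tau > params$criterion, "long", "short")
  if (params$lapse > 0) {
    lapse_trial <- stats::runif(length(t)) < params$lapse
    coin <- stats::runif(length(t)) < 0.5
    resp[lapse_trial] <- ifelse(coin[lapse_trial], "long", "short")
  }
  unname(resp)
}

#' Default cohort specification emulating the six study groups
#'
#' Group sizes, per-condition bisection-point and Weber's-ratio targets with
#' their between-participant SDs, mean valence ratings, and covariate
#' distributions (age, MMSE on the telephone 0-27 scale, total intracranial
#' volume, digit spans, matrix reasoning) follow the reported group profiles
#' of the clinical cohort the simulator emulates: healthy controls plus the
#' five dementia syndromes (AD, lvPPA, nfvPPA, svPPA, bvFTD).
#'
#' @param lapse Common lapse probability for all synthetic responders.
#' @return A list with elements `groups`, `valence`, `covariates`, `lapse`.
#' @export
default_cohort_spec <- function(lapse = 0.02) {
  conds <- c("environmental-pleasant", "environmental-unpleasant",
             "human-pleasant", "human-unpleasant")
  tgt <- function(bp, bp_sd, wr, wr_sd) {
    list(bp = stats::setNames(bp, conds), bp_sd = stats::setNames(bp_sd, conds),
         wr = stats::setNames(wr, conds), wr_sd = stats::setNames(wr_sd, conds))
  }
  groups <- list(
    controls = c(list(n = 24L), tgt(c(3.6, 3.3, 4.1, 4.3), c(0.4, 0.4, 0.4, 0.5),
                                    c(0.23, 0.20, 0.22, 0.18), c(0.08, 0.07, 0.07, 0.06))),
    AD = c(list(n = 11L), tgt(c(3.3, 3.1, 4.4, 4.5), c(0.5, 0.6, 0.6, 0.5),
                              c(0.28, 0.27, 0.27, 0.20), c(0.11, 0.07, 0.12, 0.12))),
    lvPPA = c(list(n = 8L), tgt(c(3.3, 3.3, 4.4, 4.7), c(0.5, 0.5, 0.5, 0.4),
                                c(0.25, 0.25, 0.24, 0.24), c(0.07, 0.08, 0.10, 0.08))),
    nfvPPA = c(list(n = 8L), tgt(c(3.3, 2.9, 4.3, 4.7), c(0.7, 0.6, 0.7, 0.6),
                                 c(0.28, 0.22, 0.27, 0.21), c(0.11, 0.10, 0.09, 0.08))),
    svPPA = c(list(n = 11L), tgt(c(3.3, 3.4, 3.9, 4.3), c(0.3, 0.4, 0.3, 0.5),
                                 c(0.19, 0.17, 0.24, 0.19), c(0.09, 0.04, 0.08, 0.05))),
    bvFTD = c(list(n = 8L), tgt(c(3.6, 3.4, 4.5, 4.5), c(0.5, 0.4, 0.6, 0.5),
                                c(0.31, 0.29, 0.26, 0.21), c(0.15, 0.17, 0.09, 0.04)))
  )
  valence <- list(
    means = c("environmental-pleasant" = 74, "environmental-unpleasant" = 26,
              "human-pleasant" = 68, "human-unpleasant" = 25),
    sds = c("environmental-pleasant" = 16, "environmental-unpleasant" = 20,
            "human-pleasant" = 18, "human-unpleasant" = 18),
    item_sd = 10
  )
  covariates <- list(
    age = list(controls = c(69.4, 6.5), AD = c(71.3, 5.4), lvPPA = c(70.4, 5.4),
               nfvPPA = c(69.4, 5.7), svPPA = c(66.0, 9.3), bvFTD = c(67.9, 7.2)),
    mmse = list(controls = c(26.0, 1.3), AD = c(18.7, 3.8), lvPPA = c(17.5, 6.2),
                nfvPPA = c(23.4, 2.9), svPPA = c(21.8, 3.9), bvFTD = c(20.9, 5.4)),
    tiv = list(default = c(1400, 120)),
    digit_span_forward = list(controls = c(6.8, 0.9), AD = c(5.2, 1.5),
                              lvPPA = c(4.5, 1.2), nfvPPA = c(5.1, 1.9),
                              svPPA = c(6.5, 0.9), bvFTD = c(5.8, 2.3)),
    digit_span_reverse = list(controls = c(5.6, 1.2), AD = c(3.3, 1.2),
                              lvPPA = c(3.4, 1.4), nfvPPA = c(3.9, 1.5),
                              svPPA = c(4.9, 1.4), bvFTD = c(4.1, 2.0)),
    wasi_matrices = list(controls = c(26.1, 3.0), AD = c(12.4, 9.6),
                         lvPPA = c(17.1, 8.2), nfvPPA = c(22.0, 7.2),
                         svPPA = c(22.5, 6.8), bvFTD = c(17.3, 9.1))
  )
  list(groups = groups, valence = valence, covariates = covariates,
       lapse = lapse)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

# mean of a Normal(mu, sd) censored to [lo, hi]
censored_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * stats::pnorm(-b) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a))
}

# latent location whose censored mean equals the target, so bounded scales
# (e.g. 0-100 ratings) hit their configured means without truncation bias
latent_mean_for <- function(target, sd, lo, hi) {
  stats::uniroot(function(mu) censored_mean(mu, sd, lo, hi) - target,
                 c(lo - 6 * sd, hi + 6 * sd), tol = 1e-8)$root
}

#' Simulate one participant's experimental responses
#'
#' Draws per-condition clock parameters from the participant's targets and
#' produces one response per experimental trial of the schedule.
#'
#' @param targets List with named per-condition `bp` and `wr` vectors.
#' @param schedule Experimental schedule (see [build_experiment_schedule()]).
#' @param lapse Lapse probability.
#' @param criterion Decision criterion in seconds.
#' @return List with `params` ([clock_params()]) and `responses` (the
#'   schedule with a `response` column).
#' @export
simulate_participant <- function(targets, schedule, lapse = 0.02,
                                 criterion = 3.5) {
  conds <- names(targets$bp)
  per <- lapply(conds, function(cc) {
    params_from_targets(targets$bp[[cc]], targets$wr[[cc]],
                        lapse = lapse, criterion = criterion)
  })
  params <- clock_params(
    gain = stats::setNames(vapply(per, function(p) p$gain, 0), conds),
    criterion = criterion,
    weber_coef = stats::setNames(vapply(per, function(p) p$weber_coef, 0), conds),
    lapse = lapse
  )
  ex <- as.data.frame(schedule)
  ex <- ex[ex$phase == "experimental", , drop = FALSE]
  ex$response <- simulate_responses(params, ex)
  list(params = params, responses = ex)
}

#' Simulate a full synthetic cohort
#'
#' For each group in the spec, draws per-participant condition targets around
#' the group means, a per-participant block order (seeded from participant
#' id), and trial-level responses from the scalar-clock model, plus
#' covariates and valence ratings.
#'
#' @param spec Cohort specification (see [default_cohort_spec()]).
#' @param seed Integer root seed; named substreams derive from it.
#' @param n_blocks Blocks per participant (default 8).
#' @return List with `trials` (long response log), `participants`
#'   (covariates), `ratings` (valence ratings), and `spec`.
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), seed = 1L,
                            n_blocks = 8L) {
  base_schedule <- build_experiment_schedule(
    n_blocks = n_blocks, seed = substream_seed(seed, "schedule"))
  trials_list <- list()
  cov_list <- list()
  pid <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    for (i in seq_len(g$n)) {
      pid <- pid + 1L
      id <- sprintf("P%03d", pid)
      targets <- with_temp_seed(substream_seed(seed, paste0("targets:", id)), {
        conds <- names(g$bp)
        list(bp = stats::setNames(rnorm_trunc(length(conds), g$bp[conds],
                                              g$bp_sd[conds], 2.1, 4.9), conds),
             wr = stats::setNames(pmax(0.03, stats::rnorm(length(conds), g$wr[conds],
                                                          g$wr_sd[conds])), conds))
      })
      # per-participant block-order randomization
      sched <- as.data.frame(base_schedule)
      perm <- with_temp_seed(substream_seed(seed, paste0("blockorder:", id)),
                             sample.int(n_blocks))
      sched$block <- match(sched$block, perm)
      sched <- sched[order(sched$block), , drop = FALSE] # stable: keeps within-block order
      sched$trial <- seq_len(nrow(sched))
      sim <- with_temp_seed(substream_seed(seed, paste0("responses:", id)),
                            simulate_participant(targets, sched, lapse = spec$lapse))
      resp <- sim$responses
      resp$participant_id <- id
      resp$group <- gname
      trials_list[[id]] <- resp
      cov_list[[id]] <- with_temp_seed(substream_seed(seed, paste0("covariates:", id)), {
        draw <- function(name, lo, hi) {
          ms <- spec$covariates[[name]][[gname]] %||% spec$covariates[[name]][["default"]]
          rnorm_trunc(1L, ms[1], ms[2], lo, hi)
        }
        data.frame(
          participant_id = id, group = gname,
          age = round(draw("age", 45, 90), 1),
          tiv = round(draw("tiv", 1000, 1900), 1),
          mmse = round(draw("mmse", 0, 27)),
          digit_span_forward = round(draw("digit_span_forward", 0, 9), 1),
          digit_span_reverse = round(draw("digit_span_reverse", 0, 9), 1),
          wasi_matrices = round(draw("wasi_matrices", 0, 32), 1),
          stringsAsFactors = FALSE
        )
      })
    }
  }
  trials <- do.call(rbind, trials_list)
  rownames(trials) <- NULL
  participants <- do.call(rbind, cov_list)
  rownames(participants) <- NULL
  ratings <- simulate_valence_ratings(spec, participants,
                                      seed = substream_seed(seed, "ratings"))
  list(trials = trials, participants = participants, ratings = ratings,
       spec = spec)
}

#' Simulate per-item valence ratings
#'
#' Thirty-six items (nine per condition) rated on a 0-100 pleasantness scale.
#' Each participant has a latent per-condition mean drawn around the
#' configured condition mean; item ratings add independent noise and are
#' truncated to the scale.
#'
#' @param spec Cohort spec carrying `valence` means/sds.
#' @param participants Data.frame with `participant_id`.
#' @param n_items Total number of rated items (multiple of 4).
#' @param seed Integer seed.
#' @return Long data.frame: participant_id, item, semantic_category,
#'   valence (pre-assigned), rating.
#' @export
simulate_valence_ratings <- function(spec, participants, n_items = 36L,
                                     seed = 1L) {
  conds <- names(spec$valence$means)
  per_cond <- n_items %/% length(conds)
  items <- data.frame(
    item = sprintf("item%02d", seq_len(per_cond * length(conds))),
    condition = rep(conds, each = per_cond),
    stringsAsFactors = FALSE
  )
  latent <- vapply(conds, function(cc) {
    latent_mean_for(spec$valence$means[[cc]], spec$valence$sds[[cc]], 0, 100)
  }, 0)
  with_temp_seed(seed, {
    out <- lapply(participants$participant_id, function(id) {
      mu <- rnorm_trunc(length(conds), latent[conds],
                        spec$valence$sds[conds], 0, 100)
      names(mu) <- conds
      r <- rnorm_trunc(nrow(items), mu[items$condition],
                       spec$valence$item_sd, 0, 100)
      cbind(data.frame(participant_id = id, stringsAsFactors = FALSE),
            items, split_condition(items$condition), rating = r)
    })
    out <- do.call(rbind, out)
    out$condition <- NULL
    rownames(out) <- NULL
    out
  })
}

#' Default region-of-interest family (right hemisphere)
#'
#' The five pre-specified timing-related regions: dorsolateral prefrontal
#' cortex, insula/frontal operculum, inferior parietal lobule (including
#' supramarginal gyrus), supplementary motor area, precuneus.
#' @return Character vector of region names.
#' @export
default_roi_family <- function() {
  c("right_dlpfc", "right_insula", "right_inferior_parietal",
    "right_sma", "right_precuneus")
}

#' Default planted grey-matter effects
#'
#' Slopes (volume units per second of signed bisection-point difference) for
#' the region-condition pairs where an association is planted; unspecified
#' pairs are pure null regions. Signs follow the atrophy convention: where
#' the cohort's signed differences are overall positive (environmental
#' sounds) atrophy shows as a negative slope, and where they are overall
#' negative (human sounds) as a positive slope.
#' @return Data.frame with region, condition, slope.
#' @export
default_roi_effects <- function() {
  data.frame(
    region = c("right_precuneus", "right_insula", "right_inferior_parietal"),
    condition = c("environmental-pleasant", "human-unpleasant", "human-pleasant"),
    slope = c(-0.8, 0.8, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Simulate regional grey-matter volumes for patients
#'
#' `volume(region, i) = baseline + slope(region, condition) * delta(i,
#' condition) + covariate terms + Normal(0, noise_sd)`. Regions without a
#' planted slope are null regions.
#'
#' @param deltas Signed-difference table (see [build_signed_differences()]):
#'   columns participant_id, condition, delta.
#' @param covariates Participant covariates (age, tiv, mmse).
#' @param effects Data.frame region/condition/slope (default
#'   [default_roi_effects()]).
#' @param regions Region names (default [default_roi_family()]).
#' @param noise_sd Residual SD of volumes (default 0.5).
#' @param baseline Baseline volume (default 10).
#' @param seed Integer seed.
#' @return Wide data.frame: one row per patient, one column per region, plus
#'   covariates and group.
#' @export
simulate_roi_volumes <- function(deltas, covariates,
                                 effects = default_roi_effects(),
                                 regions = default_roi_family(),
                                 noise_sd = 0.5, baseline = 10, seed = 1L) {
  pts <- unique(deltas$participant_id)
  cov <- covariates[match(pts, covariates$participant_id), , drop = FALSE]
  if (anyNA(cov$participant_id)) {
    stop("covariates missing for some patients in the delta table", call. = FALSE)
  }
  with_temp_seed(seed, {
    vol <- matrix(baseline, nrow = length(pts), ncol = length(regions),
                  dimnames = list(pts, regions))
    # mild covariate structure so nuisance regressors have something to absorb
    cov_term <- 0.004 * (cov$tiv - 1400) - 0.01 * (cov$age - 69) +
      0.02 * (cov$mmse - 22)
    vol <- vol + cov_term
    for (k in seq_len(nrow(effects))) {
      reg <- effects$region[k]
      if (!reg %in% regions) next
      d <- deltas[deltas$condition == effects$condition[k], , drop = FALSE]
      dv <- d$delta[match(pts, d$participant_id)]
      dv[is.na(dv)] <- 0
      vol[, reg] <- vol[, reg] + effects$slope[k] * dv
    }
    vol <- vol + matrix(stats::rnorm(length(vol), 0, noise_sd),
                        nrow = nrow(vol))
    out <- data.frame(participant_id = pts, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(vol))
    out$group <- cov$group
    out$age <- cov$age
    out$tiv <- cov$tiv
    out$mmse <- cov$mmse
    rownames(out) <- NULL
    out
  })
}
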