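# Psychometric-curve estimation for the bisection task.
#
# The response curve is P(long | t) = gamma + (1 - gamma - lambda) * F((t -
# alpha) / beta) with a logistic or cumulative-normal core F. gamma (guess)
# and lambda (lapse) set the lower and upper asymptotes; the upper asymptote
# 1 - lambda is the probability of responding long at infinitely long
# durations. Parameters are estimated by penalized binomial maximum
# likelihood; with only 7 design points the asymptotes are weakly identified,
# so they carry a Beta(1, 20)-shaped log-penalty and a hard bound at 0.25.

#' Tabulate long-response counts per condition and duration
#'
#' The proportion of long responses is the number of long responses divided
#' by the number of presentations (the number of blocks under the standard
#' design) for each condition at each duration.
#'
#' @param records Data.frame of experimental responses with columns
#'   `condition_category`, `condition_valence`, `duration_s`, `response`
#'   ("short"/"long").
#' @return Data.frame: condition_category, condition_valence, duration_s,
#'   n_long, n_trials, p_long.
#' @export
tabulate_counts <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("empty record list: nothing to tabulate", call. = FALSE)
  }
  bad <- !records$response %in% c("short", "long")
  if (any(bad)) {
    stop(sprintf("unknown response token at row(s) %s",
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  key <- interaction(records$condition_category, records$condition_valence,
                     records$duration_s, drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(condition_category = d$condition_category[1L],
               condition_valence = d$condition_valence[1L],
               duration_s = d$duration_s[1L],
               n_long = sum(d$response == "long"),
               n_trials = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg$p_long <- agg$n_long / agg$n_trials
  agg <- agg[order(agg$condition_category, agg$condition_valence,
                   agg$duration_s), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

psych_core <- function(family) {
  switch(family,
         logistic = stats::plogis,
         cumulative_normal = stats::pnorm,
         stop(sprintf("unknown curve family '%s'", family), call. = FALSE))
}

#' Evaluate a fitted psychometric curve
#'
#' @param curve A `psych_curve` object from [fit_curve()].
#' @param t Durations in seconds.
#' @return `P(long | t)` including the asymptotes.
#' @export
curve_p_long <- function(curve, t) {
  F <- psych_core(curve$family)
  curve$gamma + (1 - curve$gamma - curve$lambda) * F((t - curve$alpha) / curve$beta)
}

penalized_loglik <- function(theta, t, n_long, n_trials, family,
                             penalty_shape) {
  alpha <- theta[1L]; beta <- exp(theta[2L])
  gamma <- theta[3L]; lambda <- theta[4L]
  F <- psych_core(family)
  p <- gamma + (1 - gamma - lambda) * F((t - alpha) / beta)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  ll <- sum(n_long * log(p) + (n_trials - n_long) * log(1 - p))
  ll + (penalty_shape - 1) * (log(1 - gamma) + log(1 - lambda))
}

#' Fit a psychometric curve by penalized maximum likelihood
#'
#' Maximizes the binomial log-likelihood plus a weak Beta(1, `penalty_shape`)
#' log-penalty on the guess and lapse rates (hard-bounded at `asym_max`).
#' Optimization is multi-start L-BFGS-B from a fixed, data-scaled grid, so
#' the fit is a deterministic function of the data.
#'
#' @param counts Counts for one condition (columns `duration_s`, `n_long`,
#'   `n_trials`), at least 4 distinct durations.
#' @param family "logistic" (default; closed-form quantiles) or
#'   "cumulative_normal".
#' @param penalty_shape Beta shape of the asymptote penalty (default 20).
#' @param asym_max Hard upper bound for guess and lapse (default 0.25).
#' @return A `psych_curve` object: alpha (threshold, s), beta (scale, s),
#'   gamma (guess), lambda (lapse), family, loglik (penalized), fit_ok,
#'   message.
#' @export
fit_curve <- function(counts, family = c("logistic", "cumulative_normal"),
                      penalty_shape = 20, asym_max = 0.25) {
  family <- match.arg(family)
  t <- counts$duration_s
  n_long <- counts$n_long
  n_trials <- counts$n_trials
  if (length(unique(t)) < 4L) {
    stop("at least 4 distinct durations are required to fit a curve",
         call. = FALSE)
  }
  if (any(n_trials < 1L) || any(n_long < 0L) || any(n_long > n_trials)) {
    stop("invalid counts: need 0 <= n_long <= n_trials, n_trials >= 1",
         call. = FALSE)
  }
  fail <- function(msg) {
    structure(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                   lambda = NA_real_, family = family, loglik = NA_real_,
                   fit_ok = FALSE, message = msg), class = "psych_curve")
  }
  p_emp <- n_long / n_trials
  if (all(p_emp == 0) || all(p_emp == 1)) {
    return(fail("degenerate data: all responses identical across durations"))
  }
  rng <- range(t)
  span <- diff(rng)
  lower <- c(rng[1] - 2 * span, log(span * 0.005), 0, 0)
  upper <- c(rng[2] + 2 * span, log(span * 3), asym_max, asym_max)
  # phase 1: vectorized coarse-grid screen over the fixed, data-scaled grid
  grid <- expand.grid(
    alpha = rng[1] + span * seq(0.05, 0.95, length.out = 10L),
    logb = log(span * c(0.03, 0.06, 0.12, 0.22, 0.40, 0.70)),
    gam = c(0, 0.08, 0.2), lam = c(0, 0.08, 0.2),
    KEEP.OUT.ATTRS = FALSE
  )
  F <- psych_core(family)
  zg <- outer(grid$alpha, t, function(a, tt) tt - a) / exp(grid$logb)
  P <- grid$gam + (1 - grid$gam - grid$lam) * F(zg)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12) # arg order keeps the matrix dims
  gll <- P
  gll[] <- log(P) * rep(n_long, each = nrow(grid)) +
    log1p(-P) * rep(n_trials - n_long, each = nrow(grid))
  score <- rowSums(gll) +
    (penalty_shape - 1) * (log(1 - grid$gam) + log(1 - grid$lam))
  top <- order(score, decreasing = TRUE)[seq_len(4L)]
  # phase 2: polish the best grid points with box-constrained quasi-Newton
  best <- NULL
  for (k in top) {
    th0 <- c(grid$alpha[k], grid$logb[k],
             min(grid$gam[k], asym_max), min(grid$lam[k], asym_max))
    fit <- tryCatch(
      stats::optim(th0, penalized_loglik, t = t, n_long = n_long,
                   n_trials = n_trials, family = family,
                   penalty_shape = penalty_shape,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(fnscale = -1, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value > best$value)) best <- fit
  }
  if (is.null(best)) return(fail("optimization failed from every start"))
  structure(list(alpha = best$par[1L], beta = exp(best$par[2L]),
                 gamma = best$par[3L], lambda = best$par[4L],
                 family = family, loglik = best$value,
                 fit_ok = TRUE, message = "ok"),
            class = "psych_curve")
}

#' @export
print.psych_curve <- function(x, ...) {
  if (!isTRUE(x$fit_ok)) {
    cat(sprintf("<psych_curve: fit failed (%s)>\n", x$message))
    return(invisible(x))
  }
  cat(sprintf("<psych_curve %s: alpha=%.3f s, beta=%.3f s, guess=%.3f, lapse=%.3f, pen.loglik=%.3f>\n",
              x$family, x$alpha, x$beta, x$gamma, x$lambda, x$loglik))
  invisible(x)
}

invert_curve <- function(curve, p, tol = 1e-8) {
  lo_asym <- curve$gamma
  hi_asym <- 1 - curve$lambda
  if (p <= lo_asym + 1e-9 || p >= hi_asym - 1e-9) return(NA_real_)
  f <- function(t) curve_p_long(curve, t) - p
  lo <- curve$alpha - 10 * curve$beta
  hi <- curve$alpha + 10 * curve$beta
  while (f(lo) > 0 && lo > curve$alpha - 1e6 * curve$beta) lo <- lo - 10 * curve$beta
  while (f(hi) < 0 && hi < curve$alpha + 1e6 * curve$beta) hi <- hi + 10 * curve$beta
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Extract bisection point and Weber's ratio from a fitted curve
#'
#' The bisection point is the duration at which the curve (asymptotes
#' included, by default) reaches 50% probability of a "long" response;
#' Weber's ratio is (duration at P = 0.75 minus duration at P = 0.25)
#' divided by the bisection point. Inversion is numeric bisection to 1e-8 s.
#'
#' @param curve A `psych_curve` from [fit_curve()].
#' @param on_core If `TRUE`, invert the core sigmoid F instead of the full
#'   curve (sensitivity analysis).
#' @return List of class `bisection_metrics`: bp, q25, q75, wr, log_wr,
#'   fit_ok, message.
#' @export
extract_metrics <- function(curve, on_core = FALSE) {
  fail <- function(msg) {
    structure(list(bp = NA_real_, q25 = NA_real_, q75 = NA_real_,
                   wr = NA_real_, log_wr = NA_real_, fit_ok = FALSE,
                   message = msg), class = "bisection_metrics")
  }
  if (!isTRUE(curve$fit_ok)) return(fail(curve$message))
  cv <- curve
  if (on_core) { cv$gamma <- 0; cv$lambda <- 0 }
  q25 <- invert_curve(cv, 0.25)
  bp <- invert_curve(cv, 0.50)
  q75 <- invert_curve(cv, 0.75)
  if (anyNA(c(q25, bp, q75))) {
    return(fail("curve does not cross 0.25/0.5/0.75 (asymptote too high/low)"))
  }
  if (bp <= 0) return(fail("non-positive bisection point"))
  wr <- (q75 - q25) / bp
  structure(list(bp = bp, q25 = q25, q75 = q75, wr = wr, log_wr = log(wr),
                 fit_ok = TRUE, message = "ok"), class = "bisection_metrics")
}

#' Fit curves and extract metrics for every participant and condition
#'
#' @param trials Long response log (columns participant_id, group,
#'   condition_category, condition_valence, duration_s, response).
#' @param family Curve family passed to [fit_curve()].
#' @return Data.frame, one row per participant x condition, with curve
#'   parameters, bp, q25, q75, wr, log_wr and fit_ok.
#' @export
fit_participant_metrics <- function(trials, family = "logistic") {
  out <- list()
  for (id in unique(trials$participant_id)) {
    p_tr <- trials[trials$participant_id == id, , drop = FALSE]
    counts <- tabulate_counts(p_tr)
    combos <- unique(counts[, c("condition_category", "condition_valence")])
    for (k in seq_len(nrow(combos))) {
      sel <- counts$condition_category == combos$condition_category[k] &
        counts$condition_valence == combos$condition_valence[k]
      curve <- fit_curve(counts[sel, , drop = FALSE], family = family)
      m <- extract_metrics(curve)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = id, group = p_tr$group[1L],
        semantic_category = combos$condition_category[k],
        valence = combos$condition_valence[k],
        alpha = curve$alpha, beta = curve$beta, gamma = curve$gamma,
        lambda = curve$lambda, bp = m$bp, q25 = m$q25, q75 = m$q75,
        wr = m$wr, log_wr = m$log_wr,
        fit_ok = isTRUE(curve$fit_ok) && isTRUE(m$fit_ok),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a mean valence rating
#'
#' A mean rating of 50 or higher counts as pleasant, below 50 as unpleasant.
#'
#' @param mean_rating Numeric rating(s) on the 0-100 scale.
#' @return "pleasant" or "unpleasant".
#' @export
classify_valence <- function(mean_rating) {
  ifelse(mean_rating >= 50, "pleasant", "unpleasant")
}

#' Recompute condition valence from individual ratings
#'
#' For each participant and pre-assigned condition, the valence label is
#' recomputed from that participant's mean rating of the condition's items
#' (>= 50 pleasant, < 50 unpleasant). If both valence sets of a semantic
#' category map to the same label for a participant, that participant's
#' category is flagged ambiguous (the conditions can no longer be
#' distinguished and are excluded downstream, mirroring per-cell missingness
#' bookkeeping).
#'
#' @param ratings Long ratings table from [simulate_valence_ratings()] (or
#'   real data with the same columns).
#' @return Data.frame: participant_id, semantic_category, valence_pre,
#'   mean_rating, valence_new, reassigned, ambiguous.
#' @export
reassign_valence <- function(ratings) {
  key <- interaction(ratings$participant_id, ratings$semantic_category,
                     ratings$valence, drop = TRUE)
  map <- do.call(rbind, lapply(split(ratings, key), function(d) {
    data.frame(participant_id = d$participant_id[1L],
               semantic_category = d$semantic_category[1L],
               valence_pre = d$valence[1L],
               mean_rating = mean(d$rating),
               stringsAsFactors = FALSE)
  }))
  map$valence_new <- classify_valence(map$mean_rating)
  map$reassigned <- map$valence_new != map$valence_pre
  amb_key <- paste(map$participant_id, map$semantic_category)
  amb <- tapply(map$valence_new, amb_key,
                function(v) length(unique(v)) < 2L)
  map$ambiguous <- unname(amb[amb_key])
  rownames(map) <- NULL
  map[order(map$participant_id, map$semantic_category, map$valence_pre), ]
}

#' Apply a valence reassignment to a trial log
#'
#' Relabels `condition_valence` per the participant-level mapping from
#' [reassign_valence()]; trials in ambiguous participant-categories are
#' dropped and counted.
#'
#' @param trials Long response log.
#' @param mapping Output of [reassign_valence()].
#' @return List: `trials` (relabelled log) and `n_dropped` (trials removed
#'   for ambiguous categories).
#' @export
apply_valence_reassignment <- function(trials, mapping) {
  key_t <- paste(trials$participant_id, trials$condition_category,
                 trials$condition_valence)
  key_m <- paste(mapping$participant_id, mapping$semantic_category,
                 mapping$valence_pre)
  idx <- match(key_t, key_m)
  if (anyNA(idx)) {
    stop("mapping does not cover every participant-condition in the trial log",
         call. = FALSE)
  }
  drop <- mapping$ambiguous[idx]
  out <- trials[!drop, , drop = FALSE]
  out$condition_valence <- mapping$valence_new[idx][!drop]
  list(trials = out, n_dropped = sum(drop))
}
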