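# Signed-difference grey-matter association analysis at region-of-interest
# scale. The regressor of interest for each sound condition is the signed
# difference: mean control bisection point for the condition minus the
# patient's bisection point. Volumes are modelled per region with the delta
# plus diagnosis (5-level factor) and the nuisance covariates age, total
# intracranial volume and MMSE; family-wise error over the ROI family is
# controlled by max-|t| permutation (delta permuted within diagnosis strata)
# or Bonferroni.

#' Build the signed-difference duration-estimation regressor
#'
#' For every patient and condition: delta = (mean bisection point over all
#' controls with a valid fit for that condition) minus the patient's
#' bisection point. The overall sign of the deltas per condition is recorded;
#' under the study's group patterns it is expected positive for environmental
#' and negative for human conditions.
#'
#' @param metrics Per-participant x condition metrics table with columns
#'   participant_id, group, semantic_category, valence, bp, fit_ok.
#' @param control_group Label of the control group (default "controls").
#' @return List of class `signed_differences`: `deltas` (participant_id,
#'   group, condition, semantic_category, valence, delta) and
#'   `condition_sign` (condition, control_mean, overall_sign).
#' @export
build_signed_differences <- function(metrics, control_group = "controls") {
  m <- metrics[metrics$fit_ok %in% TRUE & is.finite(metrics$bp), , drop = FALSE]
  m$condition <- paste(m$semantic_category, m$valence, sep = "-")
  ctl <- m[m$group == control_group, , drop = FALSE]
  pat <- m[m$group != control_group, , drop = FALSE]
  conds <- sort(unique(m$condition))
  ctl_mean <- vapply(conds, function(cc) {
    v <- ctl$bp[ctl$condition == cc]
    if (length(v) == 0L) {
      stop(sprintf("no valid control bisection points for condition '%s'", cc),
           call. = FALSE)
    }
    mean(v)
  }, 0)
  deltas <- pat[, c("participant_id", "group", "condition",
                    "semantic_category", "valence"), drop = FALSE]
  deltas$delta <- ctl_mean[pat$condition] - pat$bp
  sign_tab <- data.frame(
    condition = conds,
    control_mean = unname(ctl_mean),
    overall_sign = vapply(conds, function(cc) {
      s <- mean(deltas$delta[deltas$condition == cc])
      if (s >= 0) 1 else -1
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rownames(deltas) <- NULL
  structure(list(deltas = deltas, condition_sign = sign_tab),
            class = "signed_differences")
}

# Residualize y against the nuisance design Z (QR projection).
resid_on <- function(y, qrZ) y - qr.fitted(qrZ, y)

#' Regional GLM of grey-matter volume on the signed difference
#'
#' Per region: `volume ~ delta + diagnosis + age + tiv + mmse` over the
#' combined patient cohort for one condition. Reports the delta slope with
#' its t statistic and p value, and whether a significant slope in that
#' direction would indicate atrophy given the overall sign of the condition's
#' deltas (positive overall sign: negative slope = atrophy; negative overall
#' sign: positive slope = atrophy).
#'
#' @param roi Wide ROI volume table (one column per region, plus group, age,
#'   tiv, mmse; see [simulate_roi_volumes()]).
#' @param sd_tab A `signed_differences` object.
#' @param condition Condition label, e.g. "human-unpleasant".
#' @param regions Region columns to test (default [default_roi_family()]).
#' @return Data.frame of class `assoc_result`: region, condition, slope, t,
#'   df, p_raw, atrophy_direction.
#' @export
fit_roi_glm <- function(roi, sd_tab, condition,
                        regions = default_roi_family()) {
  d <- sd_tab$deltas[sd_tab$deltas$condition == condition, , drop = FALSE]
  dat <- merge(roi, d[, c("participant_id", "delta")], by = "participant_id")
  dat <- dat[stats::complete.cases(dat[, c("delta", "group", "age", "tiv", "mmse")]), ]
  if (nrow(dat) < 10L) {
    stop("fewer than 10 patients with complete rows", call. = FALSE)
  }
  dat$group <- droplevels(factor(dat$group))
  X <- stats::model.matrix(~ delta + group + age + tiv + mmse, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("rank-deficient design; aliased terms: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  osign <- sd_tab$condition_sign$overall_sign[
    sd_tab$condition_sign$condition == condition]
  rows <- lapply(regions, function(reg) {
    fit <- stats::lm(dat[[reg]] ~ delta + group + age + tiv + mmse, data = dat)
    co <- summary(fit)$coefficients["delta", ]
    slope <- unname(co["Estimate"])
    tval <- unname(co["t value"])
    data.frame(region = reg, condition = condition, slope = slope, t = tval,
               df = fit$df.residual, p_raw = unname(co["Pr(>|t|)"]),
               atrophy_direction = (osign > 0 && slope < 0) ||
                 (osign < 0 && slope > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "data") <- dat
  attr(out, "regions") <- regions
  class(out) <- c("assoc_result", "data.frame")
  out
}

# t statistics of delta for all regions given a delta vector, via
# Frisch-Waugh partialling: residualize volumes and delta on the nuisance
# design once, then simple regressions on the residualized delta.
delta_tstats <- function(Yres, dres, df) {
  ss_d <- sum(dres^2)
  b <- as.numeric(crossprod(Yres, dres)) / ss_d
  rss <- colSums(Yres^2) - b^2 * ss_d
  se <- sqrt(rss / df / ss_d)
  b / se
}

#' Family-wise error correction over an ROI family
#'
#' `permutation_maxT` permutes the delta regressor within diagnosis strata
#' and adjusts each region's p value against the permutation distribution of
#' the maximum absolute t statistic over the family (nuisance covariates
#' partialled out before permutation). `bonferroni` multiplies raw p by the
#' family size, capped at 1.
#'
#' @param assoc An `assoc_result` from [fit_roi_glm()].
#' @param method "permutation_maxT" (default) or "bonferroni".
#' @param n_perm Number of permutations (>= 100 recommended; < 10 is an
#'   error).
#' @param seed Integer seed for the permutation stream.
#' @param stratify Permute within diagnosis strata (default TRUE; diagnosis
#'   is in the model, so unstratified permutation is logged with a warning).
#' @return The association table with a `p_fwe` column.
#' @export
fwe_correct <- function(assoc, method = c("permutation_maxT", "bonferroni"),
                        n_perm = 2000L, seed = 1L, stratify = TRUE) {
  method <- match.arg(method)
  out <- as.data.frame(assoc)
  if (method == "bonferroni") {
    out$p_fwe <- pmin(1, out$p_raw * nrow(out))
    class(out) <- c("assoc_result", "data.frame")
    return(out)
  }
  if (n_perm < 10L) stop("n_perm < 10: permutation null too coarse", call. = FALSE)
  if (n_perm < 100L) warning("n_perm < 100: adjusted p values will be coarse")
  if (!stratify) warning("unstratified permutation while diagnosis is in the model")
  dat <- attr(assoc, "data")
  regions <- attr(assoc, "regions")
  Z <- stats::model.matrix(~ group + age + tiv + mmse, data = dat)
  qrZ <- qr(Z)
  df <- nrow(dat) - ncol(Z) - 1L
  Yres <- apply(as.matrix(dat[, regions, drop = FALSE]), 2L,
                resid_on, qrZ = qrZ)
  d <- dat$delta
  t_obs <- delta_tstats(Yres, resid_on(d, qrZ), df)
  strata <- if (stratify) as.character(dat$group) else rep("all", nrow(dat))
  idx_by_stratum <- split(seq_along(d), strata)
  max_null <- with_temp_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      dp <- d
      for (ii in idx_by_stratum) dp[ii] <- dp[sample(ii)]
      max(abs(delta_tstats(Yres, resid_on(dp, qrZ), df)))
    }, 0)
  })
  out$p_fwe <- vapply(t_obs, function(tt) {
    (1 + sum(max_null >= abs(tt))) / (n_perm + 1)
  }, 0)
  # permutation p cannot undercut the parametric raw p's evidence ordering,
  # but guarantee the adjusted >= raw invariant explicitly
  out$p_fwe <- pmax(out$p_fwe, out$p_raw)
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "data") <- dat
  attr(out, "regions") <- regions
  out
}

#' Threshold-then-max screening for synthetic voxel families
#'
#' Mirrors cluster-forming logic at ROI-table scale: voxels (columns) whose
#' raw p passes the cluster-forming threshold are carried forward; the
#' family-wise adjusted p of the surviving peak is taken from the max-|t|
#' permutation null of the whole family.
#'
#' @param assoc_fwe An `assoc_result` with `p_fwe` (from [fwe_correct()]).
#' @param forming_p Cluster-forming threshold on raw p (default 0.001).
#' @param peak_p Peak-level FWE threshold (default 0.05).
#' @return The table with `survives_forming` and `significant` columns.
#' @export
threshold_then_max <- function(assoc_fwe, forming_p = 0.001, peak_p = 0.05) {
  out <- as.data.frame(assoc_fwe)
  out$survives_forming <- out$p_raw < forming_p
  out$significant <- out$survives_forming & out$p_fwe < peak_p
  class(out) <- c("assoc_result", "data.frame")
  out
}
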