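# Group-level statistics: confound screening, linear mixed models on
# bisection point and log Weber's ratio, post hoc contrasts of estimated
# marginal means, deviation scores, and exploratory correlations.

#' Screen candidate confounders across diagnostic groups
#'
#' Each candidate is tested for group differences with a one-way ANOVA when
#' Levene's test (median-centred) and a Shapiro normality screen of the
#' residuals both pass; otherwise with a Kruskal-Wallis test. Candidates with
#' p < `alpha` are flagged for inclusion as nuisance covariates.
#'
#' @param data Data.frame with a `group` column and candidate columns.
#' @param candidates Character vector of candidate column names.
#' @param alpha Flagging threshold (default 0.05).
#' @param normality_p Shapiro p-value threshold below which residuals are
#'   treated as non-normal (default 0.05; a fixed rule so runs reproduce).
#' @return Data.frame: candidate, test, statistic, p, include_as_covariate,
#'   degenerate.
#' @export
screen_confounders <- function(data, candidates, alpha = 0.05,
                               normality_p = 0.05) {
  grp <- factor(data$group)
  if (nlevels(grp) < 2L || min(table(grp)) < 2L) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  rows <- lapply(candidates, function(v) {
    x <- data[[v]]
    ok <- stats::complete.cases(x, grp)
    x <- x[ok]; g <- droplevels(grp[ok])
    if (length(unique(x)) <= 1L) {
      return(data.frame(candidate = v, test = "none", statistic = NA_real_,
                        p = NA_real_, include_as_covariate = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    lev_p <- tryCatch(car::leveneTest(x ~ g)[1, "Pr(>F)"],
                      error = function(e) 0)
    res <- stats::resid(stats::lm(x ~ g))
    sh_p <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) 0)
    if (isTRUE(lev_p > alpha) && isTRUE(sh_p > normality_p)) {
      a <- summary(stats::aov(x ~ g))[[1]]
      data.frame(candidate = v, test = "anova", statistic = a$`F value`[1L],
                 p = a$`Pr(>F)`[1L],
                 include_as_covariate = a$`Pr(>F)`[1L] < alpha,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    } else {
      k <- stats::kruskal.test(x ~ g)
      data.frame(candidate = v, test = "kruskal", statistic = unname(k$statistic),
                 p = k$p.value, include_as_covariate = k$p.value < alpha,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the group-level linear mixed model
#'
#' `response ~ group * semantic_category * valence + (1 | participant_id)`,
#' fitted by REML: the full factorial of diagnostic group, semantic category
#' and valence as fixed effects with participant identity as the only random
#' effect. Fixed effects are reported with Wald z statistics.
#'
#' @param data Long metrics table (one row per participant x condition) with
#'   columns participant_id, group, semantic_category, valence and the
#'   response.
#' @param response "bp" or "log_wr".
#' @return List of class `group_model`: `fit` (the merMod), `coefficients`
#'   (estimate, se, z, p), `ranef_var`, `resid_var`, `converged`, `response`.
#' @export
fit_mixed_model <- function(data, response = c("bp", "log_wr")) {
  response <- match.arg(response)
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  d$group <- factor(d$group)
  d$semantic_category <- factor(d$semantic_category)
  d$valence <- factor(d$valence)
  if (min(table(d$group[!duplicated(d$participant_id)])) < 2L) {
    warning("groups with a single participant: random-intercept variance unidentifiable")
  }
  fml <- stats::as.formula(
    paste(response, "~ group * semantic_category * valence + (1 | participant_id)"))
  msgs <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(fml, data = d, REML = TRUE),
      warning = function(w) { msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning") },
      message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") }
    ),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(
      fit = NULL, response = response,
      coefficients = data.frame(term = character(), estimate = numeric(),
                                se = numeric(), z = numeric(), p = numeric()),
      ranef_var = NA_real_, resid_var = NA_real_, converged = FALSE,
      messages = c(msgs, conditionMessage(fit))
    ), class = "group_model"))
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  conv_issue <- length(fit@optinfo$conv$lme4) > 0 ||
    any(grepl("failed to converge", msgs, ignore.case = TRUE))
  co <- summary(fit)$coefficients
  z <- co[, "Estimate"] / co[, "Std. Error"]
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], z = z,
                      p = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fit = fit, response = response, coefficients = coefs,
    ranef_var = vc$vcov[vc$grp == "participant_id"],
    resid_var = vc$vcov[vc$grp == "Residual"],
    converged = !singular && !conv_issue,
    messages = msgs
  ), class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model on %s: %d fixed effects, ranef var %.4g, resid var %.4g, converged: %s>\n",
              x$response, nrow(x$coefficients), x$ranef_var, x$resid_var,
              x$converged))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Post hoc contrasts of estimated marginal means
#'
#' Pairwise z contrasts for a named interaction family, averaging over the
#' remaining factors with equal (balanced-design) weights. Raw p values are
#' reported by default; Holm adjustment is available.
#'
#' @param model A `group_model` from [fit_mixed_model()].
#' @param family One of "category:diagnosis" (groups compared within each
#'   semantic category), "category:valence" (valence compared within each
#'   category), "diagnosis" (group main-effect comparisons).
#' @param adjust "none" (default) or "holm".
#' @return Data.frame: description, estimate, z, p.
#' @export
posthoc_contrasts <- function(model, family = c("category:diagnosis",
                                                "category:valence",
                                                "diagnosis"),
                              adjust = c("none", "holm")) {
  family <- match.arg(family)
  adjust <- match.arg(adjust)
  if (!isTRUE(model$converged)) {
    warning("contrasts computed on a model flagged as non-converged")
  }
  spec <- switch(family,
                 "category:diagnosis" = ~ group | semantic_category,
                 "category:valence" = ~ valence | semantic_category,
                 "diagnosis" = ~ group)
  emm <- emmeans::emmeans(model$fit, spec, lmer.df = "asymptotic")
  cz <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = adjust))
  zcol <- if ("z.ratio" %in% names(cz)) "z.ratio" else "t.ratio"
  desc <- if ("semantic_category" %in% names(cz)) {
    paste0(cz$contrast, " [", cz$semantic_category, "]")
  } else cz$contrast
  data.frame(description = desc, estimate = cz$estimate, z = cz[[zcol]],
             p = cz$p.value, stringsAsFactors = FALSE)
}

#' Deviation of a bisection point from the arithmetic reference mean
#'
#' The arithmetic mean of the 2 s and 5 s references is 3.5 s. Positive
#' deviations indicate duration underestimation (curve shifted right),
#' negative deviations overestimation.
#'
#' @param bp Bisection point(s) in seconds.
#' @return `bp - 3.5`.
#' @export
deviation_from_arithmetic_mean <- function(bp) {
  bp - mean(reference_durations())
}

#' Exploratory correlations between bisection metrics and cognitive scores
#'
#' Participant-level mean bp and mean wr (averaged across the four
#' conditions) are correlated with covariate scores. Spearman rank
#' correlation is the default; Pearson is used when both marginals pass a
#' Shapiro normality screen.
#'
#' @param metrics Per-participant x condition metrics (from
#'   [fit_participant_metrics()]); rows with `fit_ok = FALSE` are dropped.
#' @param covariates Participant covariate table.
#' @param scores Covariate columns to correlate against (default digit spans,
#'   matrix reasoning, MMSE).
#' @param normality_p Shapiro threshold for switching to Pearson.
#' @return Data.frame: metric, score, method, n, coefficient, p (pairs with
#'   fewer than 4 complete observations are skipped).
#' @export
exploratory_correlations <- function(metrics, covariates,
                                     scores = c("digit_span_forward",
                                                "digit_span_reverse",
                                                "wasi_matrices", "mmse"),
                                     normality_p = 0.05) {
  ok <- metrics[metrics$fit_ok %in% TRUE, , drop = FALSE]
  mean_bp <- tapply(ok$bp, ok$participant_id, mean)
  mean_wr <- tapply(ok$wr, ok$participant_id, mean)
  ids <- names(mean_bp)
  cov <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
  out <- list()
  for (metric in c("mean_bp", "mean_wr")) {
    x <- if (metric == "mean_bp") as.numeric(mean_bp) else as.numeric(mean_wr)
    for (sc in scores) {
      y <- cov[[sc]]
      cc <- stats::complete.cases(x, y)
      if (sum(cc) < 4L) {
        message(sprintf("skipping %s ~ %s: fewer than 4 complete pairs", metric, sc))
        next
      }
      xn <- x[cc]; yn <- y[cc]
      normal <- tryCatch(stats::shapiro.test(xn)$p.value > normality_p &&
                           stats::shapiro.test(yn)$p.value > normality_p,
                         error = function(e) FALSE)
      method <- if (normal) "pearson" else "spearman"
      ct <- suppressWarnings(stats::cor.test(xn, yn, method = method,
                                             exact = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, score = sc, method = method, n = sum(cc),
        coefficient = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
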