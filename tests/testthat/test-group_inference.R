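test_that("confound screening flags overwhelming effects and spares nulls", {
  set.seed(14)
  d <- data.frame(group = rep(c("controls", "AD", "svPPA"), each = 12),
                  null_score = rnorm(36),
                  shifted = rnorm(36) + ifelse(rep(c(TRUE, FALSE, FALSE),
                                                  each = 12), 3, 0),
                  constant = 1)
  rep_ <- screen_confounders(d, c("null_score", "shifted", "constant"))
  expect_true(rep_$include_as_covariate[rep_$candidate == "shifted"])
  expect_true(rep_$degenerate[rep_$candidate == "constant"])
  expect_false(rep_$include_as_covariate[rep_$candidate == "constant"])
  expect_error(screen_confounders(d[c(1, 13, 25), ], "null_score"), ">= 2")
})

test_that("confound screening holds its nominal type-I rate", {
  set.seed(99)
  flags <- vapply(1:120, function(i) {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 15),
                    x = rnorm(45))
    screen_confounders(d, "x")$include_as_covariate
  }, TRUE)
  # 5% nominal; binomial 3*SE band around 0.05 for 120 replicates
  expect_lt(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("mixed model recovers a planted semantic-category shift", {
  d <- make_long_metrics(seed = 2, category_effect = 0.8)
  m <- fit_mixed_model(d, "bp")
  expect_true(m$converged)
  expect_true(all(m$coefficients$p >= 0 & m$coefficients$p <= 1))
  expect_gte(m$ranef_var, 0)
  cz <- posthoc_contrasts(m, "category:valence")
  # no category term appears in this family; check via the coefficient
  cat_term <- m$coefficients[m$coefficients$term == "semantic_categoryhuman", ]
  expect_gt(cat_term$estimate, 0.4)
  expect_lt(cat_term$p, 0.05)
})

test_that("a 0.8 s category shift is detected at the study's group sizes", {
  ns <- c(AD = 11, bvFTD = 8, controls = 24, lvPPA = 8, nfvPPA = 8, svPPA = 11)
  set.seed(61)
  hits <- replicate(40, {
    pid <- 0
    d <- do.call(rbind, lapply(names(ns), function(g) {
      do.call(rbind, lapply(seq_len(ns[[g]]), function(i) {
        pid <<- pid + 1
        u <- rnorm(1, 0, 0.3)
        cells <- expand.grid(semantic_category = c("environmental", "human"),
                             valence = c("pleasant", "unpleasant"),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        cells$participant_id <- sprintf("P%03d", pid)
        cells$group <- g
        cells$bp <- 3.5 + u + 0.8 * (cells$semantic_category == "human") +
          rnorm(4, 0, 0.35)
        cells
      }))
    }))
    m <- fit_mixed_model(d, "bp")
    co <- m$coefficients
    co$p[co$term == "semantic_categoryhuman"] < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("mixed model estimates are invariant to row order and relabeling", {
  d <- make_long_metrics(seed = 3, category_effect = 0.4)
  m1 <- fit_mixed_model(d, "bp")
  set.seed(1)
  d2 <- d[sample.int(nrow(d)), ]
  m2 <- fit_mixed_model(d2, "bp")
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 1e-6)
  # relabel participants (ids permuted within group): same estimates
  d3 <- d
  d3$participant_id <- paste0("X", d3$participant_id)
  m3 <- fit_mixed_model(d3, "bp")
  expect_equal(m1$coefficients$estimate, m3$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("balanced-design fixed effects coincide with OLS", {
  d <- make_long_metrics(seed = 4, category_effect = 0.5)
  m <- fit_mixed_model(d, "bp")
  ols <- lm(bp ~ group * semantic_category * valence, data = d)
  expect_equal(m$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("single-participant groups are flagged unidentifiable", {
  d <- make_long_metrics(seed = 5, n_per_group = c(a = 1, b = 1, c = 1))
  m <- suppressWarnings(fit_mixed_model(d, "bp"))
  expect_false(m$converged)
})

test_that("post hoc contrasts carry signs that match construction", {
  d <- make_long_metrics(seed = 6, group_effect = 0, category_effect = 0)
  # push AD's bp up by 1 s in the human category only
  sel <- d$group == "AD" & d$semantic_category == "human"
  d$bp[sel] <- d$bp[sel] + 1
  m <- fit_mixed_model(d, "bp")
  cz <- posthoc_contrasts(m, "category:diagnosis")
  row <- cz[grepl("^AD - controls \\[human\\]", cz$description), ]
  expect_equal(nrow(row), 1L)
  expect_gt(row$estimate, 0.5)
  expect_lt(row$p, 0.05)
  env_row <- cz[grepl("^AD - controls \\[environmental\\]", cz$description), ]
  expect_gt(env_row$p, 0.05)
  # unknown family errors
  expect_error(posthoc_contrasts(m, "nonsense"))
})

test_that("log transform reduces residual skewness for wr-like responses", {
  d <- make_long_metrics(seed = 7)
  set.seed(7)
  d$wr <- exp(rnorm(nrow(d), log(0.22), 0.35))
  d$log_wr <- log(d$wr)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  m_log <- fit_mixed_model(d, "log_wr")
  ols_raw <- lm(wr ~ group * semantic_category * valence, data = d)
  expect_lt(abs(skew(resid(m_log$fit))), abs(skew(resid(ols_raw))))
})

test_that("deviation from the 3.5 s arithmetic mean is an exact affine map", {
  expect_equal(deviation_from_arithmetic_mean(3.5), 0)
  expect_equal(deviation_from_arithmetic_mean(4.3), 0.8)
  expect_equal(deviation_from_arithmetic_mean(2.9), -0.6)
  bp <- c(3.1, 3.9, 4.4, 2.8)
  expect_equal(sum(deviation_from_arithmetic_mean(bp)),
               length(bp) * (mean(bp) - 3.5))
})

test_that("exploratory correlations pick method and sign correctly", {
  ids <- sprintf("P%03d", 1:30)
  set.seed(11)
  bp <- rnorm(30, 3.7, 0.4)
  metrics <- do.call(rbind, lapply(1:4, function(k) {
    data.frame(participant_id = ids, group = "AD",
               semantic_category = "human", valence = "pleasant",
               bp = bp, wr = 0.2, log_wr = log(0.2), fit_ok = TRUE)
  }))
  cov <- data.frame(participant_id = ids, group = "AD",
                    digit_span_forward = -2 * bp + rnorm(30, 0, 0.3),
                    digit_span_reverse = rnorm(30, 4, 1),
                    wasi_matrices = rnorm(30, 20, 5),
                    mmse = round(rnorm(30, 21, 3)))
  res <- exploratory_correlations(metrics, cov)
  dsf <- res[res$metric == "mean_bp" & res$score == "digit_span_forward", ]
  expect_lt(dsf$coefficient, -0.8)
  expect_lt(dsf$p, 0.001)
  # a perfect antitone pair gives Spearman rho -1
  cov$wasi_matrices <- -bp
  res2 <- exploratory_correlations(metrics, cov, scores = "wasi_matrices",
                                   normality_p = 1) # force Spearman
  wm <- res2[res2$metric == "mean_bp" & res2$score == "wasi_matrices", ]
  expect_equal(unname(wm$coefficient), -1, tolerance = 1e-9)
  # too-few complete pairs are skipped with a log entry
  cov$mmse[1:28] <- NA
  expect_message(
    res3 <- exploratory_correlations(metrics, cov, scores = "mmse"),
    "fewer than 4")
  expect_true(is.null(res3) || !"mmse" %in% res3$score)
})
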