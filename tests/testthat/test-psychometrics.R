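test_that("counts tabulate proportions of long responses per cell", {
  trials <- make_trials(8L)
  trials$response <- rep(c("short", "long"), length.out = nrow(trials))
  cnt <- tabulate_counts(trials)
  expect_equal(sum(cnt$n_trials), nrow(trials))
  expect_true(all(cnt$p_long == 0.5))
  trials$response <- "long"
  expect_true(all(tabulate_counts(trials)$p_long == 1))
  # a full 224-record log yields 28 cells of 8 trials
  sched <- build_experiment_schedule(seed = 2)
  log224 <- as.data.frame(sched)
  log224$response <- "short"
  cnt224 <- tabulate_counts(log224)
  expect_equal(nrow(cnt224), 28L)
  expect_true(all(cnt224$n_trials == 8L))
  expect_error(tabulate_counts(trials[0, ]), "empty")
  trials$response[3] <- "banana"
  expect_error(tabulate_counts(trials), "row")
})

test_that("curve fit recovers generating parameters from exact data", {
  # probabilities rounded to eighths, as 8 trials/cell would produce
  cnt <- counts_from_logistic(3.5, 0.4, exact = TRUE)
  cv <- fit_curve(cnt)
  expect_true(cv$fit_ok)
  expect_equal(cv$alpha, 3.5, tolerance = 0.1)
  # step data bracket the threshold
  step <- data.frame(duration_s = bisection_durations(),
                     n_long = c(0, 0, 0, 8, 8, 8, 8) * 0 +
                       ifelse(bisection_durations() >= 4, 8, 0),
                     n_trials = 8)
  cvs <- fit_curve(step)
  expect_gt(cvs$alpha, 3)
  expect_lt(cvs$alpha, 4)
})

test_that("penalized MLE matches a dense grid search on seeded datasets", {
  for (seed in 1:6) {
    set.seed(seed)
    cnt <- counts_from_logistic(runif(1, 2.8, 4.2), runif(1, 0.2, 0.8),
                                gamma = 0.03, lambda = 0.03, seed = seed)
    cv <- fit_curve(cnt)
    oracle <- grid_search_loglik(cnt)
    expect_gte(cv$loglik, oracle - 1e-3)
  }
})

test_that("degenerate data fail soft with a diagnostic", {
  allshort <- data.frame(duration_s = bisection_durations(), n_long = 0,
                         n_trials = 8)
  cv <- fit_curve(allshort)
  expect_false(cv$fit_ok)
  expect_match(cv$message, "degenerate")
  m <- extract_metrics(cv)
  expect_false(m$fit_ok)
  expect_true(is.na(m$bp))
})

test_that("metrics match closed-form quantiles of both families", {
  # logistic: quantiles alpha -/+ beta*ln 3, so wr = 2*beta*ln3 / alpha
  cv <- structure(list(alpha = 3.6, beta = 0.4, gamma = 0, lambda = 0,
                       family = "logistic", loglik = 0, fit_ok = TRUE,
                       message = "ok"), class = "psych_curve")
  m <- extract_metrics(cv)
  expect_equal(m$q25, 3.6 - 0.4 * log(3), tolerance = 1e-6)
  expect_equal(m$q75, 3.6 + 0.4 * log(3), tolerance = 1e-6)
  expect_equal(m$wr, 2 * 0.4 * log(3) / 3.6, tolerance = 1e-6)
  expect_equal(m$log_wr, log(m$wr))
  # cumulative normal: wr = 2 * z(0.75) * sigma / alpha ~ 1.349 sigma / alpha
  cvn <- structure(list(alpha = 3.5, beta = 0.5, gamma = 0, lambda = 0,
                        family = "cumulative_normal", loglik = 0,
                        fit_ok = TRUE, message = "ok"), class = "psych_curve")
  mn <- extract_metrics(cvn)
  expect_equal(mn$wr, 2 * qnorm(0.75) * 0.5 / 3.5, tolerance = 1e-4)
  expect_equal(mn$wr, 0.1927, tolerance = 1e-2)
})

test_that("wr follows the direct arithmetic definition", {
  # q25 = 3.0, q75 = 4.2, bp = 3.6 -> wr = 1.2 / 3.6
  expect_equal((4.2 - 3.0) / 3.6, 1 / 3, tolerance = 1e-12)
  # and the asymptote-aware inversion respects it: build a curve with known
  # quantiles through nonzero asymptotes
  cv <- structure(list(alpha = 3.6, beta = 0.3, gamma = 0.1, lambda = 0.1,
                       family = "logistic", loglik = 0, fit_ok = TRUE,
                       message = "ok"), class = "psych_curve")
  m <- extract_metrics(cv)
  expect_equal(curve_p_long(cv, m$q25), 0.25, tolerance = 1e-7)
  expect_equal(curve_p_long(cv, m$bp), 0.50, tolerance = 1e-7)
  expect_equal(curve_p_long(cv, m$q75), 0.75, tolerance = 1e-7)
  expect_equal(m$wr, (m$q75 - m$q25) / m$bp)
  # asymptotes that swallow the 0.25 crossing are flagged, not thrown
  cv$gamma <- 0.25
  expect_false(extract_metrics(cv)$fit_ok)
})

test_that("fitted curves are monotone for admissible parameters", {
  set.seed(5)
  tt <- seq(2, 5, by = 0.01)
  for (i in 1:25) {
    cv <- structure(list(alpha = runif(1, 2, 5), beta = runif(1, 0.05, 2),
                         gamma = runif(1, 0, 0.25), lambda = runif(1, 0, 0.25),
                         family = sample(c("logistic", "cumulative_normal"), 1),
                         loglik = 0, fit_ok = TRUE, message = "ok"),
                    class = "psych_curve")
    expect_true(all(diff(curve_p_long(cv, tt)) >= 0))
  }
})

test_that("metrics are scale-consistent under duration rescaling", {
  cnt <- counts_from_logistic(3.4, 0.45, seed = 8)
  m1 <- extract_metrics(fit_curve(cnt))
  cnt2 <- cnt
  cnt2$duration_s <- cnt$duration_s * 2
  m2 <- extract_metrics(fit_curve(cnt2))
  expect_equal(m2$bp, 2 * m1$bp, tolerance = 1e-4)
  expect_equal(m2$q25, 2 * m1$q25, tolerance = 1e-4)
  expect_equal(m2$q75, 2 * m1$q75, tolerance = 1e-4)
  expect_equal(m2$wr, m1$wr, tolerance = 1e-6)
})

test_that("wr strictly decreases with curve steepness at fixed bp", {
  betas <- seq(0.1, 1, by = 0.1)
  wrs <- vapply(betas, function(b) {
    cv <- structure(list(alpha = 3.5, beta = b, gamma = 0, lambda = 0,
                         family = "logistic", loglik = 0, fit_ok = TRUE,
                         message = "ok"), class = "psych_curve")
    extract_metrics(cv)$wr
  }, 0)
  # steeper curve = smaller beta = smaller wr; wr increases with beta
  expect_true(all(diff(wrs) > 0))
})

test_that("valence reassignment follows the 50-point rule", {
  expect_identical(classify_valence(50), "pleasant")
  expect_identical(classify_valence(26), "unpleasant")
  ratings <- expand.grid(participant_id = c("P1", "P2"),
                         semantic_category = c("environmental", "human"),
                         valence = c("pleasant", "unpleasant"),
                         item = 1:3, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  ratings$rating <- ifelse(ratings$valence == "pleasant", 70, 30)
  # P2 rates human-pleasant items as unpleasant
  flip <- ratings$participant_id == "P2" &
    ratings$semantic_category == "human" & ratings$valence == "pleasant"
  ratings$rating[flip] <- 20
  map <- reassign_valence(ratings)
  expect_equal(sum(map$reassigned), 1L)
  p2h <- map[map$participant_id == "P2" & map$semantic_category == "human", ]
  expect_true(all(p2h$ambiguous)) # both cells now unpleasant
  p1 <- map[map$participant_id == "P1", ]
  expect_false(any(p1$reassigned))
  expect_false(any(p1$ambiguous))
  # applying the mapping relabels and drops ambiguous cells
  trials <- data.frame(participant_id = rep(c("P1", "P2"), each = 4),
                       condition_category = rep(c("environmental", "human"), 4),
                       condition_valence = rep(c("pleasant", "unpleasant"),
                                               each = 2, length.out = 8),
                       stringsAsFactors = FALSE)
  out <- apply_valence_reassignment(trials, map)
  expect_equal(out$n_dropped, 2L)
  expect_true(all(out$trials$participant_id == "P1" |
                    out$trials$condition_category == "environmental"))
})
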