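# Psychometric fitting: logistic MLE with 80% thresholds, bootstrap SEs,
# the logit transform, quadratic fits and the nested F test.

test_that("logit matches its closed form and antisymmetry", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(plogis(1)), 1, tolerance = 1e-9)
  p <- c(0.1, 0.37, 0.92)
  expect_equal(logit(p), -logit(1 - p))
  expect_error(logit(0), "continuity")
  expect_error(logit(1), "continuity")
  expect_equal(logit(1, squeeze = 0.01), logit(0.99))
})

test_that("logistic fit recovers a known generating observer", {
  obs <- logistic_observer(40, 8)
  set.seed(51)
  trials <- simulate_staircase_trials(obs, n_runs = 10)  # 1500 trials
  fit <- fit_logistic(trials)
  expect_s3_class(fit, "psychometric_fit")
  # fitted curve passes 0.75 at alpha by construction
  expect_equal(predict(fit, fit$alpha), 0.75)
  expect_equal(fit$alpha, 40, tolerance = 3)
  expect_equal(fit$threshold, observer_threshold(obs, 0.8), tolerance = 3)
  # curve monotone non-decreasing
  pcs <- predict(fit, seq(0, 100, 5))
  expect_true(all(diff(pcs) >= 0))
  # threshold sits exactly at 80% on the fitted curve
  expect_equal(predict(fit, fit$threshold), 0.8, tolerance = 1e-6)
})

test_that("near-step data put the threshold at the step", {
  trials <- data.frame(level = rep(c(43.75, 50, 56.25), each = 200),
                       correct = rep(c(FALSE, NA, TRUE), each = 200))
  set.seed(52)
  trials$correct[is.na(trials$correct)] <- runif(200) < 0.75
  fit <- fit_logistic(trials)
  expect_equal(fit$threshold, 50, tolerance = 3)
})

test_that("degenerate trial tables are rejected with a reason", {
  all_right <- data.frame(level = rep(c(10, 90), each = 20), correct = TRUE)
  expect_error(fit_logistic(all_right), "every response correct")
  all_wrong <- data.frame(level = rep(c(10, 90), each = 20), correct = FALSE)
  expect_error(fit_logistic(all_wrong), "every response incorrect")
  one_level <- data.frame(level = 50, correct = c(TRUE, FALSE))
  expect_error(fit_logistic(one_level), "distinct")
})

test_that("bootstrap SE is deterministic under a seed and shrinks with data", {
  obs <- logistic_observer(40, 8)
  set.seed(53)
  small <- simulate_staircase_trials(obs, n_runs = 3)
  b1 <- bootstrap_se(small, n_resamples = 300, seed = 7)
  b2 <- bootstrap_se(small, n_resamples = 300, seed = 7)
  expect_identical(b1$se, b2$se)
  expect_gt(b1$se, 0)

  # quadrupling the trial count should roughly halve the SE
  set.seed(54)
  ratios <- vapply(1:5, function(i) {
    s <- simulate_staircase_trials(obs, n_runs = 2)
    l <- simulate_staircase_trials(obs, n_runs = 8)
    bootstrap_se(s, 300)$se / bootstrap_se(l, 300)$se
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.35)
})

test_that("a saturated, noise-free observer yields a near-zero bootstrap SE", {
  hard_step <- function(level) level >= 50
  trials <- data.frame(level = rep(seq(0, 100, 6.25), each = 30))
  trials$correct <- hard_step(trials$level)
  # soften one interior level so the fit is identifiable
  trials$correct[trials$level == 43.75][1:6] <- TRUE
  b <- bootstrap_se(trials, n_resamples = 200, seed = 8)
  expect_lt(b$se, 2)
})

test_that("quadratic fits are exact on noiseless data", {
  x <- c(1 / 3, 0.5, 2 / 3, 1, 1, 1, 1.5, 2, 3)
  a <- -5.321; b <- -0.133; c0 <- 43.819
  y <- a * x^2 + b * x + c0
  fit <- fit_quadratic(x, y)
  expect_equal(fit$a, a, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-9)
  expect_equal(fit$c, c0, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$df, 6)

  flat <- fit_quadratic(x, rep(5, 9))
  expect_equal(flat$a, 0, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$c, 5, tolerance = 1e-12)

  expect_error(fit_quadratic(1:3, 1:3), "4 points")
  expect_error(fit_quadratic(rep(1, 5), 1:5), "rank-deficient")
})

test_that("least squares beats any perturbed quadratic", {
  set.seed(55)
  x <- seq(0.3, 3, length.out = 9)
  y <- -2 * x^2 + x + 40 + rnorm(9, sd = 0.5)
  fit <- fit_quadratic(x, y)
  rss_at <- function(a, b, c0) sum((y - (a * x^2 + b * x + c0))^2)
  for (i in 1:20) {
    pert <- rnorm(3, sd = 0.1)
    expect_gte(rss_at(fit$a + pert[1], fit$b + pert[2], fit$c + pert[3]),
               fit$rss)
  }
})

test_that("the nested F test separates distinct curves and not identical ones", {
  x <- c(1 / 3, 0.5, 2 / 3, 1, 1, 1, 1.5, 2, 3)
  set.seed(56)
  y1 <- -5.321 * x^2 - 0.133 * x + 43.819 + rnorm(9, sd = 0.8)
  d1 <- data.frame(x = x, y = y1)
  same <- compare_quadratic_fits(d1, d1)
  expect_equal(same$F, 0, tolerance = 1e-8)
  expect_gt(same$p, 0.999)

  y2 <- -1.808 * x^2 + 0.906 * x + 47.455 + rnorm(9, sd = 0.8)
  diffr <- compare_quadratic_fits(d1, data.frame(x = x, y = y2))
  expect_equal(diffr$df1, 3)
  expect_equal(diffr$df2, 12)   # 9 + 9 points
  expect_gt(diffr$F, 0)
  expect_lt(diffr$p, 0.05)
})
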