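# Psychometric fitting and curve-level statistics: maximum-likelihood
# logistic fits with thresholds read at 80% correct, bootstrap threshold
# errors, the logit transform, and quadratic fits with a nested-model F test.

logistic_pc <- function(level, alpha, beta, guess, lapse) {
  guess + (1 - guess - lapse) * stats::plogis((level - alpha) / beta)
}

# Aggregate a trial table to (level, n, k) counts.
aggregate_levels <- function(trials) {
  stopifnot(all(c("level", "correct") %in% names(trials)))
  correct <- as.logical(trials$correct)
  n <- tapply(correct, trials$level, length)
  k <- tapply(correct, trials$level, sum)
  data.frame(level = as.numeric(names(n)), n = as.vector(n), k = as.vector(k))
}

nll_logistic <- function(par, dat, guess, lapse_fixed, lapse_max) {
  alpha <- par[1]
  beta <- exp(par[2])
  lapse <- if (is.na(lapse_fixed)) lapse_max * stats::plogis(par[3]) else
    lapse_fixed
  p <- logistic_pc(dat$level, alpha, beta, guess, lapse)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(dat$k * log(p) + (dat$n - dat$k) * log(1 - p))
}

#' Maximum-likelihood logistic psychometric fit
#'
#' Fits `PC(x) = guess + (1 - guess - lapse) / (1 + exp(-(x - alpha)/beta))`
#' to a table of 2IFC trials by binomial maximum likelihood, and reads off the
#' threshold at 80% correct from the fitted curve.
#'
#' @param trials A data frame with columns `level` (% symmetry) and `correct`
#'   (logical or 0/1), or an already aggregated table with columns `level`,
#'   `n` (trials) and `k` (correct). Trials are pooled across staircase
#'   tracks and runs before fitting.
#' @param guess Guess rate (lower asymptote), `1/M`. Default 0.5.
#' @param lapse Fixed lapse rate. Default 0.
#' @param free_lapse If `TRUE`, estimate the lapse rate (bounded by
#'   `lapse_max`) instead of fixing it.
#' @param lapse_max Upper bound for a free lapse rate.
#' @param threshold_pc Accuracy at which the threshold is read. Default 0.80.
#' @return An object of class `"psychometric_fit"`: a list with `alpha`,
#'   `beta`, `guess`, `lapse`, `threshold` (% symmetry at `threshold_pc`, `NA`
#'   if the fitted curve never reaches it), `threshold_pc`, `loglik`,
#'   `n_trials` and the aggregated `data`.
#' @export
fit_logistic <- function(trials, guess = 0.5, lapse = 0, free_lapse = FALSE,
                         lapse_max = 0.06, threshold_pc = 0.80) {
  dat <- if (all(c("n", "k") %in% names(trials))) trials else
    aggregate_levels(trials)
  if (nrow(dat) < 2)
    stop("need trials at >= 2 distinct stimulus levels to fit")
  if (sum(dat$k) == sum(dat$n))
    stop("degenerate data: every response correct; slope unidentifiable")
  if (sum(dat$k) == 0)
    stop("degenerate data: every response incorrect; slope unidentifiable")

  lapse_fixed <- if (free_lapse) NA_real_ else lapse
  # crude start: midpoint from the level range, moderate slope
  spread <- diff(range(dat$level))
  starts <- list(c(stats::weighted.mean(dat$level, dat$n), log(max(spread / 8, 1))),
                 c(stats::median(rep(dat$level, dat$n)), log(max(spread / 4, 2))))
  if (free_lapse) starts <- lapply(starts, c, 0)
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, nll_logistic, dat = dat, guess = guess,
                          lapse_fixed = lapse_fixed, lapse_max = lapse_max,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0) stop("logistic fit failed from every start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  alpha <- best$par[1]
  beta <- exp(best$par[2])
  lapse_hat <- if (free_lapse) lapse_max * stats::plogis(best$par[3]) else lapse
  upper <- 1 - lapse_hat
  threshold <- if (threshold_pc > guess && threshold_pc < upper) {
    alpha + beta * stats::qlogis((threshold_pc - guess) / (upper - guess))
  } else NA_real_

  structure(list(alpha = alpha, beta = beta, guess = guess, lapse = lapse_hat,
                 threshold = threshold, threshold_pc = threshold_pc,
                 loglik = -best$value, n_trials = sum(dat$n), data = dat),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(paste0("Logistic psychometric fit (%d trials, %d levels)\n",
                     "  alpha = %.2f, beta = %.2f, guess = %.2f, lapse = %.3f\n",
                     "  threshold at %.0f%% correct: %.2f%% symmetry\n"),
              x$n_trials, nrow(x$data), x$alpha, x$beta, x$guess, x$lapse,
              100 * x$threshold_pc, x$threshold))
  invisible(x)
}

#' Fitted proportion correct at given stimulus levels
#'
#' @param object A `"psychometric_fit"`.
#' @param level Stimulus levels (% symmetry).
#' @param ... Unused.
#' @return Fitted PC values.
#' @export
predict.psychometric_fit <- function(object, level, ...) {
  logistic_pc(level, object$alpha, object$beta, object$guess, object$lapse)
}

#' Bootstrap standard error of the psychometric threshold
#'
#' Nonparametric bootstrap: trials are resampled with replacement, the
#' logistic fit repeated, and the SD of the resampled thresholds reported.
#' Because trials at one stimulus level are exchangeable Bernoulli draws,
#' resampling is carried out on the sufficient (level, correct) cell counts
#' via a multinomial draw, which is the same resampling distribution at a
#' fraction of the cost. Resamples on which the fit fails (or the threshold
#' is undefined) are excluded and counted.
#'
#' @param trials The trial table passed to [fit_logistic()].
#' @param n_resamples Number of bootstrap resamples. Default 1000.
#' @param seed Optional integer seed.
#' @param ... Further arguments passed on to [fit_logistic()].
#' @return A list with `se`, `thresholds` (the resampled estimates) and
#'   `n_failed`.
#' @export
bootstrap_se <- function(trials, n_resamples = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- if (all(c("n", "k") %in% names(trials))) trials else
    aggregate_levels(trials)
  n_total <- sum(dat$n)
  # cells: (level, correct) and (level, incorrect)
  cell_p <- c(dat$k, dat$n - dat$k) / n_total
  L <- nrow(dat)
  draws <- stats::rmultinom(n_resamples, n_total, cell_p)
  th <- vapply(seq_len(n_resamples), function(b) {
    k <- draws[1:L, b]
    n <- k + draws[(L + 1):(2 * L), b]
    keep <- n > 0
    res <- data.frame(level = dat$level[keep], n = n[keep], k = k[keep])
    tryCatch(fit_logistic(res, ...)$threshold, error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(th)
  list(se = stats::sd(th[ok]), thresholds = th[ok], n_failed = sum(!ok))
}

#' Log-odds transform
#'
#' @param p Proportion(s) in (0, 1).
#' @param squeeze Continuity correction: if positive, `p` is clamped to
#'   `[squeeze, 1 - squeeze]` before transforming. With the default of 0,
#'   proportions of exactly 0 or 1 are an error.
#' @return `log(p / (1 - p))`.
#' @examples
#' logit(0.5)        # 0
#' logit(plogis(1))  # 1
#' @export
logit <- function(p, squeeze = 0) {
  stopifnot(all(p >= 0), all(p <= 1), squeeze >= 0, squeeze < 0.5)
  if (squeeze > 0) p <- pmin(pmax(p, squeeze), 1 - squeeze)
  if (any(p == 0 | p == 1))
    stop("logit undefined at 0 or 1; set `squeeze` to apply a continuity correction")
  log(p / (1 - p))
}

#' Least-squares quadratic fit
#'
#' Fits `y = a*x^2 + b*x + c` (e.g. detection threshold against
#' signal-to-noise speed ratio) by ordinary least squares.
#'
#' @param x,y Numeric vectors, at least 4 points.
#' @return A list of class `"quadratic_fit"`: coefficients `a`, `b`, `c`,
#'   residual sum of squares `rss`, residual degrees of freedom `df` and the
#'   underlying `lm` fit.
#' @export
fit_quadratic <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 points for a quadratic fit")
  fit <- stats::lm(y ~ x + I(x^2))
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: x values do not identify a quadratic")
  co <- stats::coef(fit)
  structure(list(a = unname(co["I(x^2)"]), b = unname(co["x"]),
                 c = unname(co["(Intercept)"]),
                 rss = sum(stats::resid(fit)^2),
                 df = stats::df.residual(fit), lm = fit),
            class = "quadratic_fit")
}

#' Nested-model F test comparing two quadratic curves
#'
#' Extra-sum-of-squares test of a single shared quadratic against separate
#' quadratics for the two datasets. With 9 + 9 points the test has
#' (3, 12) degrees of freedom.
#'
#' @param data1,data2 Data frames with columns `x` and `y`.
#' @return A list with the `F` statistic, `df1` (always 3), `df2`
#'   (`n1 + n2 - 6`) and the p value.
#' @export
compare_quadratic_fits <- function(data1, data2) {
  stopifnot(all(c("x", "y") %in% names(data1)),
            all(c("x", "y") %in% names(data2)))
  n1 <- nrow(data1); n2 <- nrow(data2)
  if (n1 < 4 || n2 < 4)
    stop("need at least 4 points in each dataset")
  f1 <- fit_quadratic(data1$x, data1$y)
  f2 <- fit_quadratic(data2$x, data2$y)
  pooled <- rbind(data1[, c("x", "y")], data2[, c("x", "y")])
  fs <- fit_quadratic(pooled$x, pooled$y)
  rss_sep <- f1$rss + f2$rss
  df2 <- n1 + n2 - 6
  Fstat <- ((fs$rss - rss_sep) / 3) / (rss_sep / df2)
  list(F = Fstat, df1 = 3, df2 = df2,
       p = stats::pf(Fstat, 3, df2, lower.tail = FALSE),
       fit1 = f1, fit2 = f2, fit_shared = fs)
}
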