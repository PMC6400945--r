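# Signal-detection-theory probability summation across independent
# speed-selective symmetry channels, under the max decision rule.

#' Parameters of the probability-summation observer model
#'
#' @param g Gain converting stimulus level to d-prime (d' = g * SL^tau).
#' @param tau Transducer exponent relating physical to internal signal
#'   strength.
#' @param M Number of forced-choice alternatives (intervals), integer >= 2.
#' @param Q Number of monitored channels, integer >= 1.
#' @param n Number of activated channels (channels that carry signal in the
#'   target interval), 1 <= n <= Q.
#' @return A list of class `"ps_params"`.
#' @examples
#' ps_params()                 # g = tau = 1, M = 2, Q = 2, n = 1
#' ps_params(Q = 2, n = 2)     # both channels activated
#' @export
ps_params <- function(g = 1, tau = 1, M = 2, Q = 2, n = 1) {
  if (!(g > 0 && tau > 0)) stop("`g` and `tau` must be positive")
  if (M < 2 || M != round(M)) stop("`M` must be an integer >= 2")
  if (Q < 1 || Q != round(Q)) stop("`Q` must be an integer >= 1")
  if (n < 1 || n > Q || n != round(n))
    stop("`n` must be an integer with 1 <= n <= Q")
  structure(list(g = g, tau = tau, M = as.integer(M), Q = as.integer(Q),
                 n = as.integer(n)), class = "ps_params")
}

# Density of the maximum of the target interval's channel outputs: n channels
# ~ N(dprime, 1) and Q - n ~ N(0, 1), all independent.
target_max_density <- function(t, dprime, Q, n) {
  a <- n * stats::dnorm(t - dprime) *
    stats::pnorm(t - dprime)^(n - 1) * stats::pnorm(t)^(Q - n)
  if (Q > n) {
    a <- a + (Q - n) * stats::dnorm(t) * stats::pnorm(t)^(Q - n - 1) *
      stats::pnorm(t - dprime)^n
  }
  a
}

pc_ps_one <- function(SL, params) {
  if (SL < 0) stop("`SL` must be non-negative")
  dprime <- params$g * SL^params$tau
  Q <- params$Q; n <- params$n; M <- params$M
  # P(max of target interval exceeds the max of each of the M-1 noise-only
  # intervals); noise-interval max has CDF pnorm(t)^Q.
  f <- function(t) {
    target_max_density(t, dprime, Q, n) * stats::pnorm(t)^(Q * (M - 1))
  }
  lo <- -10
  hi <- dprime + 10
  stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 400L)$value
}

#' Proportion correct under max-rule probability summation
#'
#' The target interval contains `n` channels with mean d' = `g * SL^tau` and
#' `Q - n` with mean zero; each of the `M - 1` non-target intervals contains
#' `Q` zero-mean channels. All channel outputs are independent unit-variance
#' normal deviates and the observer picks the interval whose maximum channel
#' output is largest. The resulting order-statistic expression is integrated
#' numerically to absolute error well below 1e-6.
#'
#' @param SL Stimulus level (per-channel signal strength), non-negative;
#'   vectorized.
#' @param params A [ps_params()] object.
#' @return Proportion correct in `[1/M, 1)`.
#' @examples
#' pc_ps(0, ps_params())                         # chance, 0.5
#' pc_ps(1, ps_params(Q = 1, n = 1))             # pnorm(1 / sqrt(2))
#' @export
pc_ps <- function(SL, params = ps_params()) {
  stopifnot(inherits(params, "ps_params"))
  vapply(SL, pc_ps_one, numeric(1), params = params)
}

#' Stimulus level producing a given proportion correct
#'
#' Inverts [pc_ps()] by bracketed root finding: the bracket upper end is grown
#' geometrically until it exceeds the requested proportion correct, then the
#' root is polished so that `|pc_ps(SL) - PC| <= 1e-6`.
#'
#' @param PC Proportion correct, strictly between `1/M` and 1; vectorized.
#' @param params A [ps_params()] object.
#' @return The unique stimulus level `SL >= 0` with `pc_ps(SL) = PC`.
#' @export
sl_from_pc <- function(PC, params = ps_params()) {
  stopifnot(inherits(params, "ps_params"))
  vapply(PC, function(pc) {
    chance <- 1 / params$M
    if (pc <= chance)
      stop("`PC` is at or below chance (1/M); stimulus level undefined")
    if (pc >= 1) stop("`PC` is saturated (>= 1); stimulus level undefined")
    hi <- 1
    while (pc_ps_one(hi, params) < pc) {
      hi <- hi * 2
      if (hi > 1e9) stop("failed to bracket: `PC` too close to 1")
    }
    stats::uniroot(function(sl) pc_ps_one(sl, params) - pc,
                   lower = 0, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' Predict non-segregated from segregated performance
#'
#' Implements the probability-summation prediction for splitting a symmetry
#' signal across speed channels. The segregated proportion correct is first
#' converted to a stimulus level assuming one activated channel among
#' `n_speeds` monitored channels; that level is divided by the number of
#' speeds (the signal is split equally) and converted back to proportion
#' correct with all `n_speeds` channels activated.
#'
#' @param pc_segregated Proportion correct measured in the segregated
#'   condition (signal carried by a single speed); vectorized.
#' @param n_speeds Number of component speeds the signal is split across
#'   (>= 2); also the number of monitored channels.
#' @param params_base A [ps_params()] object supplying `g`, `tau` and `M`;
#'   its `Q` and `n` are overridden as described above.
#' @return Predicted proportion correct for the non-segregated condition.
#' @examples
#' predict_nonsegregated(0.85, n_speeds = 2)
#' @export
predict_nonsegregated <- function(pc_segregated, n_speeds = 2,
                                  params_base = ps_params()) {
  stopifnot(inherits(params_base, "ps_params"))
  if (n_speeds < 2 || n_speeds != round(n_speeds))
    stop("`n_speeds` must be an integer >= 2")
  p_seg <- ps_params(g = params_base$g, tau = params_base$tau,
                     M = params_base$M, Q = n_speeds, n = 1)
  p_non <- ps_params(g = params_base$g, tau = params_base$tau,
                     M = params_base$M, Q = n_speeds, n = n_speeds)
  vapply(pc_segregated, function(pc) {
    SL <- sl_from_pc(pc, p_seg)
    pc_ps_one(SL / n_speeds, p_non)
  }, numeric(1))
}

#' Monte-Carlo oracle for the max-rule decision model
#'
#' Simulates the decision model trial by trial: one unit-variance normal
#' deviate per channel per interval, signal mean added to the activated
#' channels of the target interval, response to the interval holding the
#' largest deviate. Serves as an independent check on the numerical
#' integration in [pc_ps()].
#'
#' @param SL Stimulus level.
#' @param params A [ps_params()] object.
#' @param n_trials Number of simulated trials (>= 1e4 recommended).
#' @param seed Optional integer seed.
#' @return A list with `pc` (empirical proportion correct), `se` (binomial
#'   standard error) and `n_trials`.
#' @export
mc_oracle_pc <- function(SL, params = ps_params(), n_trials = 1e5,
                         seed = NULL) {
  stopifnot(inherits(params, "ps_params"), SL >= 0, n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  dprime <- params$g * SL^params$tau
  Q <- params$Q; M <- params$M; n <- params$n
  # target interval: max over Q channels, n of them signal-bearing
  z <- matrix(stats::rnorm(n_trials * Q), n_trials, Q)
  z[, seq_len(n)] <- z[, seq_len(n)] + dprime
  target_max <- do.call(pmax, as.data.frame(z))
  foil_max <- rep(-Inf, n_trials)
  for (m in seq_len(M - 1)) {
    zm <- matrix(stats::rnorm(n_trials * Q), n_trials, Q)
    foil_max <- pmax(foil_max, do.call(pmax, as.data.frame(zm)))
  }
  pc <- mean(target_max > foil_max)
  list(pc = pc, se = sqrt(pc * (1 - pc) / n_trials), n_trials = n_trials)
}
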