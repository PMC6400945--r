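# Simulated 2IFC observers. Two stand-ins for human participants:
#  * channel_observer — a mechanistic observer built from speed-selective
#    symmetry channels combined by a max rule, the same process the
#    probability-summation analysis assumes;
#  * logistic_observer — a descriptive observer with a known psychometric
#    function, used as the ground-truth oracle when testing staircases and
#    psychometric fitting.

#' Channel-based simulated observer
#'
#' An observer whose sensitivity arises from speed-selective symmetry
#' channels. On each trial one unit-variance (optionally noise-masked) normal
#' deviate is drawn per channel per interval; channels carrying symmetry in
#' the target interval have their mean raised to `gain * SL^tau`, where the
#' per-channel stimulus level SL is the proportion of all dots that are
#' symmetric and fall within the channel's speed band. The observer responds
#' to the interval whose maximum channel output is largest.
#'
#' With `bandwidth = 0` and `masking = 0` (the defaults) the channels are
#' ideal delta functions on speed and the observer's long-run performance is
#' exactly the analytic probability-summation model [pc_ps()]. A positive
#' `bandwidth` gives channels Gaussian tuning on log speed, and a positive
#' `masking` makes noise dots that fall within a channel's band inflate that
#' channel's variance — together these produce graded speed tuning of
#' detection thresholds.
#'
#' @param gain Gain from per-channel stimulus level (proportion of dots) to
#'   d-prime.
#' @param tau Transducer exponent.
#' @param bandwidth Channel tuning bandwidth, SD in log-speed units; 0 means
#'   delta tuning (a dot drives a channel only at exactly the channel speed).
#' @param masking Variance added per unit noise-dot proportion within a
#'   channel's band: channel SD is `sqrt(1 + masking * noise_weight)`.
#' @param flicker_gain Gain applied in the dynamic-flicker condition, where
#'   the observer pools over a single temporal channel (symmetry mechanisms
#'   are modelled as untuned to element lifetime).
#' @param static_gain Gain applied in the static condition (single channel,
#'   single pattern).
#' @param M Number of forced-choice intervals.
#' @return A list of class `"channel_observer"`.
#' @export
channel_observer <- function(gain = 3, tau = 1, bandwidth = 0, masking = 0,
                             flicker_gain = gain, static_gain = gain, M = 2) {
  stopifnot(gain > 0, tau > 0, bandwidth >= 0, masking >= 0,
            flicker_gain > 0, static_gain > 0, M >= 2)
  structure(list(gain = gain, tau = tau, bandwidth = bandwidth,
                 masking = masking, flicker_gain = flicker_gain,
                 static_gain = static_gain, M = as.integer(M)),
            class = "channel_observer")
}

#' Describe one 2IFC trial by its per-speed dot counts
#'
#' A trial descriptor carries everything a channel observer needs: the
#' condition, the distinct speeds present, and how many symmetric and noise
#' dots drift at each. The foil interval contains the same per-speed counts
#' with zero symmetry, so it needs no separate description.
#'
#' @param condition One of `"speed"`, `"flicker"`, `"static"`,
#'   `"segregated"`, `"non_segregated"`.
#' @param speeds Distinct dot speeds present (deg/s).
#' @param sym_counts Symmetric-dot count at each speed (same length as
#'   `speeds`).
#' @param noise_counts Noise-dot count at each speed.
#' @return A list of class `"trial_descriptor"` with an `n_dots` total.
#' @examples
#' # segregated: 16 symmetric dots at 3.33 deg/s, 16 noise dots at 10 deg/s
#' trial_descriptor("segregated", c(3.33, 10), c(16, 0), c(0, 16))
#' # non-segregated: the same symmetry split equally across the two speeds
#' trial_descriptor("non_segregated", c(3.33, 10), c(8, 8), c(8, 8))
#' @export
trial_descriptor <- function(condition, speeds, sym_counts, noise_counts) {
  condition <- match.arg(condition, STIM_CONDITIONS)
  stopifnot(length(speeds) == length(sym_counts),
            length(speeds) == length(noise_counts),
            all(sym_counts >= 0), all(noise_counts >= 0),
            !anyDuplicated(speeds))
  structure(list(condition = condition, speeds = speeds,
                 sym_counts = sym_counts, noise_counts = noise_counts,
                 n_dots = sum(sym_counts) + sum(noise_counts)),
            class = "trial_descriptor")
}

#' Extract a trial descriptor from a generated stimulus trial
#'
#' @param trial A list with `target` and `foil` frame sequences, as returned
#'   by [make_trial()].
#' @return A [trial_descriptor()] built from the target's first frame.
#' @export
describe_trial <- function(trial) {
  fr <- trial$target$frames[[1]]
  speeds <- sort(unique(fr$speed))
  trial_descriptor(trial$target$params$condition, speeds,
                   sym_counts = vapply(speeds, function(s)
                     sum(fr$is_symmetric & fr$speed == s), numeric(1)),
                   noise_counts = vapply(speeds, function(s)
                     sum(!fr$is_symmetric & fr$speed == s), numeric(1)))
}

# Per-channel signal and masking weights for a descriptor. Channels are
# centred on the distinct speeds present; tuning is Gaussian on log speed.
# Flicker and static collapse to a single pooled channel.
channel_layout <- function(observer, trial) {
  if (trial$condition %in% c("flicker", "static")) {
    gain <- if (trial$condition == "flicker") observer$flicker_gain else
      observer$static_gain
    return(list(
      mean = gain * (sum(trial$sym_counts) / trial$n_dots)^observer$tau *
        (sum(trial$sym_counts) > 0),
      sd = sqrt(1 + observer$masking * sum(trial$noise_counts) / trial$n_dots)))
  }
  speeds <- trial$speeds
  w <- if (observer$bandwidth > 0) {
    outer(speeds, speeds,
          function(c, v) exp(-log(v / c)^2 / (2 * observer$bandwidth^2)))
  } else {
    diag(length(speeds))
  }
  sl <- as.vector(w %*% (trial$sym_counts / trial$n_dots))
  nz <- as.vector(w %*% (trial$noise_counts / trial$n_dots))
  list(mean = observer$gain * ifelse(sl > 0, sl^observer$tau, 0),
       sd = sqrt(1 + observer$masking * nz))
}

#' Simulate channel-observer responses to repeated presentations of a trial
#'
#' @param observer A [channel_observer()].
#' @param trial A [trial_descriptor()] (or a [make_trial()] result, which is
#'   converted with [describe_trial()]).
#' @param n_trials Number of independent simulated trials.
#' @param seed Optional integer seed.
#' @return Logical vector: was the target interval chosen on each trial?
#' @export
respond_trials <- function(observer, trial, n_trials = 1, seed = NULL) {
  stopifnot(inherits(observer, "channel_observer"))
  if (!inherits(trial, "trial_descriptor")) trial <- describe_trial(trial)
  if (!is.null(seed)) set.seed(seed)
  ch <- channel_layout(observer, trial)
  Q <- length(ch$mean)
  draw_max <- function(means) {
    z <- matrix(stats::rnorm(n_trials * Q, mean = rep(means, each = n_trials),
                             sd = rep(ch$sd, each = n_trials)), n_trials, Q)
    do.call(pmax, as.data.frame(z))
  }
  target_max <- draw_max(ch$mean)
  foil_max <- rep(-Inf, n_trials)
  for (m in seq_len(observer$M - 1)) foil_max <- pmax(foil_max, draw_max(0))
  target_max > foil_max
}

#' @rdname respond_trials
#' @return `respond_trial()` returns a single logical.
#' @export
respond_trial <- function(observer, trial, seed = NULL) {
  respond_trials(observer, trial, n_trials = 1, seed = seed)
}

#' Logistic simulated observer
#'
#' A descriptive observer whose probability of a correct response follows a
#' logistic psychometric function of stimulus level (here, percent positional
#' symmetry): `PC(x) = guess + (1 - guess - lapse) / (1 + exp(-(x - alpha) /
#' beta))`. It has no internal mechanism; it exists as a ground-truth oracle
#' for the adaptive staircase and psychometric-fitting machinery.
#'
#' @param alpha Location parameter (% symmetry at the curve's midpoint).
#' @param beta Slope parameter (% symmetry).
#' @param guess Guess rate, `1/M` for an M-interval forced choice.
#' @param lapse Lapse rate (stimulus-independent error probability).
#' @return A list of class `"logistic_observer"`.
#' @export
logistic_observer <- function(alpha, beta, guess = 0.5, lapse = 0) {
  stopifnot(beta > 0, guess >= 0, guess < 1, lapse >= 0, guess + lapse < 1)
  structure(list(alpha = alpha, beta = beta, guess = guess, lapse = lapse),
            class = "logistic_observer")
}

#' True proportion correct of a logistic observer at a stimulus level
#'
#' @param observer A [logistic_observer()].
#' @param level Stimulus level (% symmetry); vectorized.
#' @return Probability of a correct response.
#' @export
observer_pc <- function(observer, level) {
  stopifnot(inherits(observer, "logistic_observer"))
  observer$guess + (1 - observer$guess - observer$lapse) *
    stats::plogis((level - observer$alpha) / observer$beta)
}

#' Stimulus level at which a logistic observer reaches a given accuracy
#'
#' @param observer A [logistic_observer()].
#' @param pc Target proportion correct, strictly between `guess` and
#'   `1 - lapse`.
#' @return The stimulus level with `observer_pc(observer, level) = pc`.
#' @export
observer_threshold <- function(observer, pc = 0.8) {
  stopifnot(inherits(observer, "logistic_observer"),
            pc > observer$guess, pc < 1 - observer$lapse)
  observer$alpha + observer$beta *
    stats::qlogis((pc - observer$guess) / (1 - observer$guess - observer$lapse))
}

#' Simulate logistic-observer responses at a stimulus level
#'
#' @param observer A [logistic_observer()].
#' @param level Stimulus level (% symmetry), in `[0, 100]`.
#' @param n_trials Number of Bernoulli draws.
#' @param seed Optional integer seed.
#' @return Logical vector of correct/incorrect responses.
#' @export
respond_level <- function(observer, level, n_trials = 1, seed = NULL) {
  stopifnot(inherits(observer, "logistic_observer"),
            level >= 0, level <= 100)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n_trials) < observer_pc(observer, level)
}
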