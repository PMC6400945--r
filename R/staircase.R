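# One-up, three-down adaptive staircase with two interleaved tracks.
# The staircase controls the number of symmetric dots in the target, so
# levels are quantized to whole mirrored pairs: with 32 dots one pair is
# 2/32 = 6.25% symmetry.

#' Initialise an adaptive staircase track
#'
#' @param start_level Starting stimulus level (% symmetry).
#' @param step Step size in % symmetry; the default of 6.25 is one mirrored
#'   pair out of 32 dots.
#' @param down_rule Consecutive correct responses required before the level
#'   is lowered (1-up, `down_rule`-down). Default 3.
#' @param n_trials_max Trials after which the track terminates. Default 75.
#' @return A list of class `"staircase"` holding the current level, the
#'   consecutive-correct counter and the trial history.
#' @export
staircase_init <- function(start_level = 100, step = 6.25, down_rule = 3,
                           n_trials_max = 75) {
  stopifnot(start_level >= 0, start_level <= 100, step > 0,
            down_rule >= 1, n_trials_max >= 1)
  structure(list(level = start_level, step = step,
                 down_rule = as.integer(down_rule),
                 n_trials_max = as.integer(n_trials_max),
                 consecutive_correct = 0L, n_trials = 0L,
                 history = list(level = numeric(0), correct = logical(0))),
            class = "staircase")
}

#' Has a staircase track finished its trial budget?
#' @param state A `"staircase"` object.
#' @return Logical.
#' @export
staircase_terminated <- function(state) state$n_trials >= state$n_trials_max

#' Record one response and update the staircase level
#'
#' One-up, `down_rule`-down: an incorrect response raises the level by one
#' step and resets the consecutive-correct counter; a correct response
#' increments the counter, and when it reaches `down_rule` the level drops by
#' one step and the counter resets. Levels are clipped to `[0, 100]`.
#'
#' @param state A `"staircase"` object.
#' @param correct Logical: was the response correct?
#' @return The updated state, with the trial appended to the history at the
#'   level at which it was run.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase"), is.logical(correct),
            length(correct) == 1)
  if (staircase_terminated(state))
    stop("staircase track already terminated at ",
         state$n_trials_max, " trials")
  state$history$level <- c(state$history$level, state$level)
  state$history$correct <- c(state$history$correct, correct)
  state$n_trials <- state$n_trials + 1L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$down_rule) {
      state$level <- max(0, state$level - state$step)
      state$consecutive_correct <- 0L
    }
  } else {
    state$level <- min(100, state$level + state$step)
    state$consecutive_correct <- 0L
  }
  state
}

#' Accuracy at which a 1-up, k-down staircase converges
#'
#' The level drifts neither up nor down when the probability of `down_rule`
#' consecutive correct responses equals the probability of an error sequence,
#' i.e. at the proportion correct p solving `p^down_rule = 1/2`.
#'
#' @param down_rule Number of consecutive correct responses per down step.
#' @return The convergence proportion correct, `0.5^(1/down_rule)`.
#' @examples
#' convergence_pc(3)  # 0.7937
#' @export
convergence_pc <- function(down_rule) {
  if (down_rule < 1 || down_rule != round(down_rule))
    stop("`down_rule` must be a positive integer")
  0.5^(1 / down_rule)
}

#' Run two interleaved staircase tracks against a simulated observer
#'
#' One track starts at 100% symmetry and descends; the other starts at 0% and
#' ascends. Tracks alternate strictly by default (or in random order), each
#' terminating after its own trial budget.
#'
#' @param observer A [logistic_observer()], or any function taking a level
#'   (% symmetry) and returning a logical response (e.g. a closure wrapping a
#'   [channel_observer()] and a stimulus condition).
#' @param n_trials_per_track Trials per track (default 75, so 150 in total).
#' @param starts Starting levels of the two tracks.
#' @param step Step size in % symmetry.
#' @param down_rule Consecutive-correct rule.
#' @param interleave `"alternate"` for strict alternation, `"random"` to pick
#'   an unfinished track at random each trial.
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `trial`, `track` (1 = high start,
#'   2 = low start), `level`, `correct`.
#' @export
run_interleaved <- function(observer, n_trials_per_track = 75,
                            starts = c(100, 0), step = 6.25, down_rule = 3,
                            interleave = c("alternate", "random"),
                            seed = NULL) {
  interleave <- match.arg(interleave)
  if (!is.null(seed)) set.seed(seed)
  respond <- if (is.function(observer)) {
    observer
  } else if (inherits(observer, "logistic_observer")) {
    function(level) respond_level(observer, level)
  } else {
    stop("`observer` must be a logistic_observer or a function(level)")
  }
  tracks <- lapply(starts, staircase_init, step = step, down_rule = down_rule,
                   n_trials_max = n_trials_per_track)
  total <- n_trials_per_track * length(starts)
  track_v <- integer(total); level_v <- numeric(total); corr_v <- logical(total)
  for (t in seq_len(total)) {
    open <- which(!vapply(tracks, staircase_terminated, logical(1)))
    k <- if (interleave == "alternate") open[1 + (t - 1) %% length(open)]
         else open[sample.int(length(open), 1)]
    lvl <- tracks[[k]]$level
    correct <- isTRUE(respond(lvl))
    tracks[[k]] <- staircase_update(tracks[[k]], correct)
    track_v[t] <- k; level_v[t] <- lvl; corr_v[t] <- correct
  }
  tibble::tibble(trial = seq_len(total), track = track_v, level = level_v,
                 correct = corr_v)
}
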