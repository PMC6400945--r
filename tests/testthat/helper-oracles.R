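# Shared fixtures and small oracle helpers, all built in code.

# Worst-case mirror-symmetry violation among the symmetric pairs of a frame:
# max over pairs of |x_L + x_R| and |y_L - y_R|.
pair_mirror_error <- function(frame) {
  sym <- frame[frame$is_symmetric, ]
  if (nrow(sym) == 0) return(0)
  err <- 0
  for (pid in unique(sym$pair_id)) {
    pr <- sym[sym$pair_id == pid, ]
    err <- max(err, abs(sum(pr$x)), abs(diff(pr$y)))
  }
  err
}

# Per-speed dot counts of a frame, as a named vector keyed by speed.
speed_counts <- function(frame) {
  tab <- table(frame$speed)
  stats::setNames(as.integer(tab), names(tab))
}

# Pool several staircase runs of a logistic observer into one trial table.
simulate_staircase_trials <- function(observer, n_runs = 5) {
  dplyr::bind_rows(lapply(seq_len(n_runs), function(r)
    run_interleaved(observer)))
}
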