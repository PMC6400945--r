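# Stimulus generation: limited-lifetime dynamic dot patterns with mirror
# symmetry about the vertical axis.
#
# Coordinate convention: origin at the window centre, x positive rightward,
# y positive upward, mirror axis x = 0. Angles in radians, 0 = rightward,
# counter-clockwise positive.

STIM_CONDITIONS <- c("speed", "flicker", "static", "segregated", "non_segregated")

#' Stimulus parameters for dynamic symmetric dot patterns
#'
#' Bundles the geometry and timing of a dot-pattern stimulus: a square window
#' viewed at fixation, a fixed number of circular dots, a refresh-locked
#' presentation, and a constant travel distance that ties element lifetime to
#' element speed.
#'
#' @param window_size Width of the square stimulus window, degrees of visual
#'   angle. Default 13.74.
#' @param n_dots Total number of dots (must be even; dots come in mirrored
#'   pairs). Default 32.
#' @param dot_diameter Dot diameter in degrees. Default 0.24.
#' @param refresh_rate Display refresh rate in Hz. Default 85.
#' @param duration_ms Presentation duration of one interval, ms. Default 400.
#' @param travel_distance Distance (degrees) a drifting dot travels before it
#'   dies and is relocated. Default 1.18.
#' @param speeds Numeric vector of one or two nominal dot speeds (deg/s).
#'   The first entry is the symmetric-element speed, the second the noise
#'   speed; a single value is used for both.
#' @param condition One of `"speed"`, `"flicker"`, `"static"`, `"segregated"`,
#'   `"non_segregated"`.
#' @return A list of class `"stim_params"`.
#' @examples
#' p <- stim_params(speeds = c(3.33, 10), condition = "speed")
#' dot_density(p)  # ~0.17 dots per square degree
#' @export
stim_params <- function(window_size = 13.74, n_dots = 32, dot_diameter = 0.24,
                        refresh_rate = 85, duration_ms = 400,
                        travel_distance = 1.18, speeds = c(3.33, 3.33),
                        condition = "speed") {
  condition <- match.arg(condition, STIM_CONDITIONS)
  stopifnot(window_size > 0, dot_diameter > 0, refresh_rate > 0,
            duration_ms > 0, travel_distance > 0, length(speeds) %in% 1:2,
            all(speeds > 0))
  if (n_dots < 2 || n_dots %% 2 != 0)
    stop("`n_dots` must be a positive even number (dots come in mirrored pairs)")
  if (length(speeds) == 1) speeds <- rep(speeds, 2)
  structure(list(window_size = window_size, n_dots = n_dots,
                 dot_diameter = dot_diameter, refresh_rate = refresh_rate,
                 duration_ms = duration_ms, travel_distance = travel_distance,
                 speeds = speeds, condition = condition,
                 n_frames = as.integer(round(duration_ms / 1000 * refresh_rate))),
            class = "stim_params")
}

#' Dot density of a stimulus configuration
#'
#' @param params A [stim_params()] object.
#' @return Dots per square degree.
#' @export
dot_density <- function(params) params$n_dots / params$window_size^2

#' Frame-quantized element lifetime for a given speed
#'
#' With a constant travel distance, faster elements live shorter lives.
#' Lifetimes are quantized to whole display frames, so the realized
#' (effective) speed differs slightly from the nominal one.
#'
#' @param speed Nominal dot speed, deg/s (vectorized).
#' @param travel_distance Distance travelled before relocation, degrees.
#' @param refresh_rate Display refresh rate, Hz.
#' @return A data.frame with one row per speed: `speed`, `frames` (lifetime in
#'   whole frames), `ms` (lifetime duration), `hz` (relocation temporal
#'   frequency, 1000/ms), and `effective_speed` (travel_distance divided by the
#'   quantized lifetime).
#' @examples
#' compute_lifetime(c(3.33, 6.67, 10))
#' @export
compute_lifetime <- function(speed, travel_distance = 1.18, refresh_rate = 85) {
  if (any(speed <= 0) || travel_distance <= 0 || refresh_rate <= 0)
    stop("`speed`, `travel_distance` and `refresh_rate` must all be positive")
  frames <- as.integer(round(travel_distance / speed * refresh_rate))
  ms <- frames / refresh_rate * 1000
  data.frame(speed = speed, frames = frames, ms = ms, hz = 1000 / ms,
             effective_speed = travel_distance / (ms / 1000))
}

# Sample n left-half positions; symmetric seeds keep a half-diameter margin
# from the axis so a mirrored partner can never coincide with its twin.
sample_left_positions <- function(n, params, symmetric) {
  half <- params$window_size / 2
  r <- params$dot_diameter / 2
  x_hi <- if (symmetric) -r else 0
  data.frame(x = stats::runif(n, -half + r, x_hi),
             y = stats::runif(n, -half + r, half - r))
}

#' Construct a dot pattern with a given number of symmetric dots
#'
#' Symmetric dots are placed by sampling positions uniformly in the left half
#' of the window and mirroring them about the vertical axis; the remaining
#' noise dots are placed uniformly with equal counts in each half. Each pair
#' (and each noise dot) receives a random lifetime phase so that elements die
#' asynchronously once speeds and lifetimes are assigned.
#'
#' @param params A [stim_params()] object.
#' @param n_symmetric Number of symmetric dots (even, between 0 and `n_dots`).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A tibble with one row per dot: `dot_id`, `pair_id` (`NA` for noise
#'   dots), `is_symmetric`, `half` (birth half, `"L"`/`"R"`), `x`, `y`,
#'   `speed`, `direction`, `age`, `lifetime`, `phase`.
#' @export
make_symmetric_pattern <- function(params, n_symmetric, seed = NULL) {
  stopifnot(inherits(params, "stim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (n_symmetric < 0 || n_symmetric > params$n_dots)
    stop("`n_symmetric` must lie between 0 and `n_dots`")
  if (n_symmetric %% 2 != 0)
    stop("`n_symmetric` must be even: symmetric dots come in mirrored pairs")
  n_pairs <- n_symmetric / 2
  n_noise <- params$n_dots - n_symmetric

  rows <- list()
  if (n_pairs > 0) {
    pos <- sample_left_positions(n_pairs, params, symmetric = TRUE)
    phase <- stats::runif(n_pairs)
    rows$sym <- tibble::tibble(
      pair_id = rep(seq_len(n_pairs), each = 2),
      is_symmetric = TRUE,
      half = rep(c("L", "R"), n_pairs),
      x = as.vector(rbind(pos$x, -pos$x)),
      y = rep(pos$y, each = 2),
      phase = rep(phase, each = 2))
  }
  if (n_noise > 0) {
    nl <- n_noise / 2
    pos <- sample_left_positions(n_noise, params, symmetric = FALSE)
    x <- pos$x
    x[(nl + 1):n_noise] <- -x[(nl + 1):n_noise]  # reflect half into the right
    rows$noise <- tibble::tibble(
      pair_id = NA_integer_, is_symmetric = FALSE,
      half = rep(c("L", "R"), each = nl),
      x = x, y = pos$y, phase = stats::runif(n_noise))
  }
  pat <- dplyr::bind_rows(rows)
  pat$dot_id <- seq_len(nrow(pat))
  pat$speed <- NA_real_
  pat$direction <- NA_real_
  pat$age <- NA_integer_
  pat$lifetime <- NA_real_
  pat[, c("dot_id", "pair_id", "is_symmetric", "half", "x", "y",
          "speed", "direction", "age", "lifetime", "phase")]
}

# Uniform direction on [0, 2*pi)
runif_angle <- function(n) stats::runif(n, 0, 2 * pi)

#' Assign drift directions to a dot pattern
#'
#' Each symmetric pair receives a uniform random direction on its left member
#' and the mirror image (pi - theta) on its right member, so the pair drifts
#' in symmetrical directions. Noise directions are drawn uniformly for the
#' left-half dots; the mirrored multiset of those directions is then randomly
#' permuted over the right-half noise dots, so the direction distribution is
#' the same in both stimulus halves without introducing extra pairwise
#' symmetry.
#'
#' @param pattern A dot-pattern tibble from [make_symmetric_pattern()].
#' @param seed Optional integer seed.
#' @return The pattern with `direction` filled in.
#' @export
assign_directions <- function(pattern, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sym <- which(pattern$is_symmetric)
  if (length(sym) > 0) {
    for (pid in unique(pattern$pair_id[sym])) {
      idx <- which(pattern$pair_id %in% pid)
      th <- runif_angle(1)
      left_first <- pattern$half[idx] == "L"
      pattern$direction[idx[left_first]] <- th
      pattern$direction[idx[!left_first]] <- (pi - th) %% (2 * pi)
    }
  }
  nl <- which(!pattern$is_symmetric & pattern$half == "L")
  nr <- which(!pattern$is_symmetric & pattern$half == "R")
  if (length(nl) > 0) {
    th <- runif_angle(length(nl))
    pattern$direction[nl] <- th
    mirrored <- (pi - th) %% (2 * pi)
    pattern$direction[nr] <- if (length(nr) > 1) sample(mirrored) else mirrored
  }
  pattern
}

#' Assign speeds (and hence lifetimes) to a dot pattern
#'
#' @param pattern A dot-pattern tibble with positions assigned.
#' @param condition Stimulus condition. `"speed"` (and `"flicker"`/`"static"`,
#'   which reuse the same assignment rule): all symmetric dots at `S1`, all
#'   noise dots at `S2`. `"segregated"`: symmetric dots all at one speed picked
#'   at random from the pair, noise dots at the other, so the observer cannot
#'   know in advance which speed carries the symmetry signal.
#'   `"non_segregated"`: half of the symmetric pairs and half of the noise
#'   dots (per half) at each speed, pair members always sharing one speed.
#' @param speed_pair Numeric `c(S1, S2)` in deg/s.
#' @param params A [stim_params()] object (for lifetime computation).
#' @param seed Optional integer seed.
#' @return The pattern with `speed`, `lifetime` (frames; `Inf` for static) and
#'   `age` (frames, uniform in `[0, lifetime)` via the stored phase) filled in.
#' @export
assign_speeds <- function(pattern, condition, speed_pair, params, seed = NULL) {
  condition <- match.arg(condition, STIM_CONDITIONS)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(speed_pair) == 2, all(speed_pair > 0))
  s1 <- speed_pair[1]; s2 <- speed_pair[2]
  sym <- pattern$is_symmetric

  if (condition %in% c("speed", "flicker", "static")) {
    pattern$speed <- ifelse(sym, s1, s2)
  } else if (condition == "segregated") {
    sym_speed <- sample(c(s1, s2), 1)
    pattern$speed <- ifelse(sym, sym_speed, setdiff(c(s1, s2), sym_speed)[1])
    if (s1 == s2) pattern$speed <- s1
  } else { # non_segregated
    pids <- unique(pattern$pair_id[sym])
    k <- floor(length(pids) / 2)
    fast_pairs <- if (length(pids) > 0) sample(pids, k) else integer(0)
    pattern$speed[sym] <- ifelse(pattern$pair_id[sym] %in% fast_pairs, s2, s1)
    for (h in c("L", "R")) {
      idx <- which(!sym & pattern$half == h)
      k <- floor(length(idx) / 2)
      fast <- if (length(idx) > 0) sample(idx, k) else integer(0)
      pattern$speed[idx] <- ifelse(idx %in% fast, s2, s1)
    }
  }

  if (condition == "static") {
    pattern$lifetime <- Inf
    pattern$age <- 0L
  } else {
    lt <- compute_lifetime(pattern$speed, params$travel_distance,
                           params$refresh_rate)$frames
    pattern$lifetime <- as.numeric(lt)
    pattern$age <- as.integer(floor(pattern$phase * lt))
  }
  pattern
}

# Relocate the dots flagged in `dying`: symmetric pairs jump simultaneously to
# fresh mirrored positions with a fresh mirrored direction; noise dots jump
# individually within their birth half (keeping half counts balanced). Ages
# reset to zero.
relocate_dots <- function(pattern, dying, params) {
  dead_pairs <- unique(pattern$pair_id[dying & pattern$is_symmetric])
  dead_pairs <- dead_pairs[!is.na(dead_pairs)]
  for (pid in dead_pairs) {
    idx <- which(pattern$pair_id %in% pid)
    pos <- sample_left_positions(1, params, symmetric = TRUE)
    th <- runif_angle(1)
    left_first <- pattern$half[idx] == "L"
    pattern$x[idx[left_first]] <- pos$x;  pattern$y[idx[left_first]] <- pos$y
    pattern$x[idx[!left_first]] <- -pos$x; pattern$y[idx[!left_first]] <- pos$y
    pattern$direction[idx[left_first]] <- th
    pattern$direction[idx[!left_first]] <- (pi - th) %% (2 * pi)
    pattern$age[idx] <- 0L
  }
  noise_dead <- which(dying & !pattern$is_symmetric)
  if (length(noise_dead) > 0) {
    pos <- sample_left_positions(length(noise_dead), params, symmetric = FALSE)
    sgn <- ifelse(pattern$half[noise_dead] == "L", 1, -1)
    pattern$x[noise_dead] <- sgn * pos$x
    pattern$y[noise_dead] <- pos$y
    pattern$direction[noise_dead] <- runif_angle(length(noise_dead))
    pattern$age[noise_dead] <- 0L
  }
  pattern
}

#' Advance a dot pattern by one display frame
#'
#' In motion conditions every dot steps `speed / refresh_rate` degrees along
#' its drift direction and ages by one frame; in the flicker condition dots
#' only age (relocation with no intervening motion); static patterns are
#' returned unchanged. Any dot reaching its lifetime — or drifting out of the
#' window, which is treated as death — is relocated: symmetric pairs jump
#' simultaneously to fresh mirrored positions (preserving the symmetry level),
#' noise dots jump individually within their birth half.
#'
#' @param pattern A fully initialised dot-pattern tibble.
#' @param params A [stim_params()] object.
#' @param condition Stimulus condition; defaults to `params$condition`.
#' @return The advanced pattern.
#' @export
advance_frame <- function(pattern, params, condition = params$condition) {
  condition <- match.arg(condition, STIM_CONDITIONS)
  if (condition == "static") return(pattern)

  pattern$age <- pattern$age + 1L
  dying <- pattern$age >= pattern$lifetime

  if (condition != "flicker") {
    alive <- !dying
    step <- pattern$speed[alive] / params$refresh_rate
    pattern$x[alive] <- pattern$x[alive] + step * cos(pattern$direction[alive])
    pattern$y[alive] <- pattern$y[alive] + step * sin(pattern$direction[alive])
    lim <- params$window_size / 2 - params$dot_diameter / 2
    out <- abs(pattern$x) > lim | abs(pattern$y) > lim
    out_pairs <- unique(pattern$pair_id[out & pattern$is_symmetric])
    dying <- dying | out | (pattern$pair_id %in% out_pairs)
  }
  if (any(dying)) pattern <- relocate_dots(pattern, dying, params)
  pattern
}

run_frames <- function(pattern, params) {
  frames <- vector("list", params$n_frames)
  frames[[1]] <- pattern
  if (params$n_frames > 1) {
    for (f in 2:params$n_frames)
      frames[[f]] <- advance_frame(frames[[f - 1]], params)
  }
  frames
}

# Foil pattern: all dots randomly positioned, but with per-half, per-speed dot
# counts copied from the target so the two intervals share the same speed and
# direction statistics.
make_foil_pattern <- function(target_pattern, params) {
  counts <- dplyr::count(target_pattern, .data$half, .data$speed)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    pos <- sample_left_positions(n, params, symmetric = FALSE)
    sgn <- if (counts$half[i] == "L") 1 else -1
    tibble::tibble(pair_id = NA_integer_, is_symmetric = FALSE,
                   half = counts$half[i], x = sgn * pos$x, y = pos$y,
                   speed = counts$speed[i], phase = stats::runif(n))
  })
  foil <- dplyr::bind_rows(rows)
  foil$dot_id <- seq_len(nrow(foil))
  foil$direction <- NA_real_
  foil <- assign_directions(foil)
  if (params$condition == "static") {
    foil$lifetime <- Inf; foil$age <- 0L
  } else {
    lt <- compute_lifetime(foil$speed, params$travel_distance,
                           params$refresh_rate)$frames
    foil$lifetime <- as.numeric(lt)
    foil$age <- as.integer(floor(foil$phase * lt))
  }
  foil[, c("dot_id", "pair_id", "is_symmetric", "half", "x", "y",
           "speed", "direction", "age", "lifetime", "phase")]
}

new_frame_sequence <- function(frames, params, n_symmetric, role) {
  structure(list(frames = frames, params = params, n_symmetric = n_symmetric,
                 n_frames = length(frames), role = role),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence: %s %s, %d frames, %d dots (%d symmetric)>\n",
              x$role, x$params$condition, x$n_frames,
              x$params$n_dots, x$n_symmetric))
  invisible(x)
}

#' Generate one 2IFC trial: a symmetric target and its matched foil
#'
#' The target is built by placing `n_symmetric` mirrored dots plus noise,
#' assigning directions and speeds for the condition, and advancing through
#' all display frames. The foil contains the same per-speed dot counts and the
#' same direction-distribution construction, but every dot is randomly
#' positioned, so the two intervals differ only in positional symmetry.
#'
#' @param params A [stim_params()] object.
#' @param n_symmetric Number of symmetric dots in the target.
#' @param seed Optional integer seed for the whole trial.
#' @return A list with `target` and `foil`, both `frame_sequence` objects.
#' @export
make_trial <- function(params, n_symmetric, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pat <- make_symmetric_pattern(params, n_symmetric)
  pat <- assign_directions(pat)
  pat <- assign_speeds(pat, params$condition, params$speeds, params)
  target <- run_frames(pat, params)
  foil_pat <- make_foil_pattern(pat, params)
  foil <- run_frames(foil_pat, params)
  list(target = new_frame_sequence(target, params, n_symmetric, "target"),
       foil = new_frame_sequence(foil, params, 0L, "foil"))
}

#' Flatten a frame sequence to a tidy per-dot table
#'
#' @param seq A `frame_sequence`.
#' @return A tibble with columns `frame`, `dot_id`, `pair_id`, `x_deg`,
#'   `y_deg`, `speed`, `direction`, `is_symmetric`.
#' @export
frames_to_table <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  out <- dplyr::bind_rows(lapply(seq_along(seq$frames), function(f) {
    fr <- seq$frames[[f]]
    tibble::tibble(frame = f, dot_id = fr$dot_id, pair_id = fr$pair_id,
                   x_deg = fr$x, y_deg = fr$y, speed = fr$speed,
                   direction = fr$direction, is_symmetric = fr$is_symmetric)
  }))
  out
}

#' Rasterize a frame sequence to an image stack
#'
#' White discs on a mid-grey background, one image per frame. Intended for
#' inspection and export; the analysis pipeline itself works on coordinates.
#'
#' @param seq A `frame_sequence`.
#' @param pixels_per_degree Raster resolution. Must be positive.
#' @return A numeric array `[rows, cols, frames]` with background 0.5 and dots
#'   1.0. Row 1 is the top of the window. Dots whose centre falls outside the
#'   canvas are clipped with a warning.
#' @export
render_frames <- function(seq, pixels_per_degree = 8) {
  stopifnot(inherits(seq, "frame_sequence"), pixels_per_degree > 0)
  w <- seq$params$window_size
  npx <- ceiling(w * pixels_per_degree)
  r <- seq$params$dot_diameter / 2
  centers <- ((seq_len(npx)) - 0.5) / pixels_per_degree - w / 2
  stack <- array(0.5, dim = c(npx, npx, seq$n_frames))
  n_clipped <- 0
  for (f in seq_len(seq$n_frames)) {
    fr <- seq$frames[[f]]
    img <- matrix(0.5, npx, npx)
    for (d in seq_len(nrow(fr))) {
      if (abs(fr$x[d]) > w / 2 || abs(fr$y[d]) > w / 2) {
        n_clipped <- n_clipped + 1
        next
      }
      cols <- which(abs(centers - fr$x[d]) <= r)
      rows <- which(abs(-centers - fr$y[d]) <= r)  # row 1 = top
      if (length(cols) == 0 || length(rows) == 0) next
      dx <- centers[cols] - fr$x[d]
      dy <- -centers[rows] - fr$y[d]
      hit <- outer(dy^2, dx^2, `+`) <= r^2
      img[rows, cols][hit] <- 1
    }
    stack[, , f] <- img
  }
  if (n_clipped > 0)
    warning(sprintf("%d dot(s) fell outside the canvas and were clipped",
                    n_clipped))
  stack
}
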