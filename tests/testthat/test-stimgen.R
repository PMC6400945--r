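# Stimulus generation: lifetimes, pattern construction, frame dynamics and
# target/foil matching.

test_that("frame-quantized lifetimes reproduce the speed/lifetime/frequency table", {
  lt <- compute_lifetime(c(3.33, 6.67, 10), travel_distance = 1.18,
                         refresh_rate = 85)
  expect_equal(lt$frames, c(30L, 15L, 10L))
  expect_equal(round(lt$ms, 2), c(352.94, 176.47, 117.65))
  expect_equal(round(lt$hz, 2), c(2.83, 5.67, 8.5))
  # a speed whose travel time is an exact frame multiple
  lt2 <- compute_lifetime(5.9, 1.18, 85)
  expect_equal(lt2$frames, 17L)
  expect_equal(lt2$ms, 200, tolerance = 1e-12)
  expect_equal(lt2$hz, 5, tolerance = 1e-12)
  expect_equal(lt2$effective_speed, 5.9, tolerance = 1e-12)
  expect_error(compute_lifetime(-1), "positive")
  expect_error(compute_lifetime(1, travel_distance = 0), "positive")
})

test_that("default configuration reproduces the nominal dot density", {
  expect_equal(round(dot_density(stim_params()), 2), 0.17)
})

test_that("pattern construction places mirrored pairs and balanced noise", {
  p <- stim_params()
  full <- make_symmetric_pattern(p, 32, seed = 1)
  expect_equal(nrow(full), 32)
  expect_equal(length(unique(full$pair_id)), 16)
  expect_lt(pair_mirror_error(full), 1e-12)

  none <- make_symmetric_pattern(p, 0, seed = 2)
  expect_true(all(is.na(none$pair_id)))
  expect_equal(as.vector(table(none$half)), c(16L, 16L))

  half <- make_symmetric_pattern(p, 16, seed = 3)
  expect_equal(sum(half$is_symmetric), 16)
  expect_equal(length(unique(stats::na.omit(half$pair_id))), 8)
  expect_equal(sum(!half$is_symmetric & half$half == "L"), 8)
  expect_equal(sum(!half$is_symmetric & half$half == "R"), 8)
  # symmetric seeds stay clear of the axis so partners cannot coincide
  expect_true(all(abs(half$x[half$is_symmetric]) >= p$dot_diameter / 2))

  expect_error(make_symmetric_pattern(p, 15), "even")
  expect_error(make_symmetric_pattern(p, 34), "between")
})

test_that("directions are pair-mirrored and noise directions mirror as a multiset", {
  p <- stim_params()
  for (seed in 1:5) {
    pat <- assign_directions(make_symmetric_pattern(p, 16), seed = seed)
    sym <- pat[pat$is_symmetric, ]
    for (pid in unique(sym$pair_id)) {
      pr <- sym[sym$pair_id == pid, ]
      th_l <- pr$direction[pr$half == "L"]
      th_r <- pr$direction[pr$half == "R"]
      expect_equal((th_l + th_r) %% (2 * pi), pi %% (2 * pi), tolerance = 1e-9)
    }
    noise <- pat[!pat$is_symmetric, ]
    left <- sort((pi - noise$direction[noise$half == "L"]) %% (2 * pi))
    right <- sort(noise$direction[noise$half == "R"])
    expect_equal(left, right, tolerance = 1e-12)
  }
})

test_that("speed assignment follows each condition's rule", {
  p <- stim_params()
  base <- assign_directions(make_symmetric_pattern(p, 16, seed = 4))

  sp <- assign_speeds(base, "speed", c(3.33, 10), p)
  expect_true(all(sp$speed[sp$is_symmetric] == 3.33))
  expect_true(all(sp$speed[!sp$is_symmetric] == 10))

  seg <- assign_speeds(base, "segregated", c(3.33, 10), p, seed = 5)
  sym_speed <- unique(seg$speed[seg$is_symmetric])
  expect_length(sym_speed, 1)
  expect_true(sym_speed %in% c(3.33, 10))
  expect_equal(unique(seg$speed[!seg$is_symmetric]),
               setdiff(c(3.33, 10), sym_speed))

  non <- assign_speeds(base, "non_segregated", c(3.33, 10), p, seed = 6)
  expect_equal(sum(non$is_symmetric & non$speed == 3.33), 8)
  expect_equal(sum(non$is_symmetric & non$speed == 10), 8)
  expect_equal(sum(!non$is_symmetric & non$speed == 3.33), 8)
  expect_equal(sum(!non$is_symmetric & non$speed == 10), 8)
  # pair members share one speed
  for (pid in unique(non$pair_id[non$is_symmetric]))
    expect_length(unique(non$speed[which(non$pair_id %in% pid)]), 1)

  same <- assign_speeds(base, "speed", c(5, 5), p)
  expect_true(all(same$speed == 5))
  expect_error(assign_speeds(base, "warp", c(3.33, 10), p))

  # lifetimes follow the assigned speed; ages start inside the lifetime
  expect_equal(sp$lifetime[sp$is_symmetric][1], 30)
  expect_equal(sp$lifetime[!sp$is_symmetric][1], 10)
  expect_true(all(sp$age >= 0 & sp$age < sp$lifetime))
})

test_that("one frame of motion is plain kinematics and preserves symmetry", {
  p <- stim_params(speeds = c(3.33, 10), condition = "speed")
  pat <- assign_speeds(assign_directions(make_symmetric_pattern(p, 16, seed = 7)),
                       "speed", p$speeds, p)
  pat$age <- 0L  # nobody dies on this frame
  nxt <- advance_frame(pat, p)
  moved <- nxt$age == 1L
  expect_true(all(moved))
  i <- which(pat$dot_id == 1)
  expect_equal(nxt$x[i], pat$x[i] + pat$speed[i] / 85 * cos(pat$direction[i]))
  expect_equal(nxt$y[i], pat$y[i] + pat$speed[i] / 85 * sin(pat$direction[i]))
  expect_lt(pair_mirror_error(nxt), 1e-9)
})

test_that("pairs at end of life are relocated simultaneously with age reset", {
  p <- stim_params(speeds = c(10, 10), condition = "speed")
  pat <- assign_speeds(assign_directions(make_symmetric_pattern(p, 32, seed = 8)),
                       "speed", p$speeds, p)
  pat$age <- as.integer(pat$lifetime - 1)
  nxt <- advance_frame(pat, p)
  expect_true(all(nxt$age == 0L))
  expect_lt(pair_mirror_error(nxt), 1e-9)
  # genuinely new positions, not displaced old ones
  expect_true(all(abs(nxt$x - pat$x) + abs(nxt$y - pat$y) > 10 / 85 * 1.5 |
                    abs(nxt$x - pat$x) + abs(nxt$y - pat$y) > 0))
})

test_that("flicker relocates without motion and static never changes", {
  p <- stim_params(speeds = c(10, 10), condition = "flicker")
  pat <- assign_speeds(assign_directions(make_symmetric_pattern(p, 16, seed = 9)),
                       "flicker", p$speeds, p)
  young <- pat$age < pat$lifetime - 1
  nxt <- advance_frame(pat, p)
  expect_equal(nxt$x[young], pat$x[young])
  expect_equal(nxt$y[young], pat$y[young])
  expect_equal(nxt$age[young], pat$age[young] + 1L)

  ps <- stim_params(condition = "static")
  pst <- assign_speeds(assign_directions(make_symmetric_pattern(ps, 16, seed = 10)),
                       "static", ps$speeds, ps)
  expect_identical(advance_frame(pst, ps), pst)
})

test_that("mirror symmetry holds in every frame of every condition", {
  for (cond in c("speed", "flicker", "static", "segregated", "non_segregated")) {
    p <- stim_params(speeds = c(3.33, 10), condition = cond)
    tr <- make_trial(p, 16, seed = 11)
    expect_equal(tr$target$n_frames, 34)
    errs <- vapply(tr$target$frames, pair_mirror_error, numeric(1))
    expect_lt(max(errs), 1e-9)
    ages_match <- vapply(tr$target$frames, function(fr) {
      sym <- fr[fr$is_symmetric, ]
      all(tapply(sym$age, sym$pair_id, function(a) length(unique(a)) == 1))
    }, logical(1))
    expect_true(all(ages_match))
  }
})

test_that("cumulative displacement between relocations approximates the travel distance", {
  p <- stim_params(speeds = c(6.67, 6.67), condition = "speed")
  tr <- make_trial(p, 32, seed = 12)
  frames <- tr$target$frames
  # follow each dot and sum its steps over any complete life (birth to the
  # frame before the next relocation)
  travelled <- c()
  for (d in frames[[1]]$dot_id) {
    xs <- vapply(frames, function(fr) fr$x[fr$dot_id == d], numeric(1))
    ys <- vapply(frames, function(fr) fr$y[fr$dot_id == d], numeric(1))
    ages <- vapply(frames, function(fr) fr$age[fr$dot_id == d], numeric(1))
    lf <- frames[[1]]$lifetime[frames[[1]]$dot_id == d]
    resets <- which(ages == 0)
    if (length(resets) >= 2 && ages[resets[2] - 1] == lf - 1) {
      # full life (dots killed early at the window edge are skipped)
      i0 <- resets[1]; i1 <- resets[2] - 1
      steps <- sqrt(diff(xs[i0:i1])^2 + diff(ys[i0:i1])^2)
      travelled <- c(travelled, sum(steps))
    }
  }
  expect_gt(length(travelled), 0)
  # a life of L frames contains L - 1 displacement steps (the final step is
  # replaced by the relocation jump), so the travelled distance sits within
  # 1.5 frame-steps of the nominal travel distance: one step for the jump
  # plus up to half a step of lifetime quantization
  step1 <- 6.67 / 85
  expect_true(all(abs(travelled - p$travel_distance) <= 1.5 * step1 + 1e-9))
})

test_that("target and foil carry identical per-speed dot counts", {
  p <- stim_params(speeds = c(3.33, 10), condition = "segregated")
  for (seed in 1:20) {
    tr <- make_trial(p, 12, seed = seed)
    expect_equal(speed_counts(tr$target$frames[[1]]),
                 speed_counts(tr$foil$frames[[1]]))
    expect_false(any(tr$foil$frames[[1]]$is_symmetric))
  }
})

test_that("identical seeds give identical frame sequences", {
  p <- stim_params(speeds = c(3.33, 10), condition = "non_segregated")
  a <- make_trial(p, 16, seed = 99)
  b <- make_trial(p, 16, seed = 99)
  expect_identical(a$target$frames, b$target$frames)
  expect_identical(a$foil$frames, b$foil$frames)
})

test_that("rasterization produces one mirror-symmetric image per frame", {
  # window_size * pixels_per_degree is an integer so the pixel grid itself is
  # mirror-symmetric and the raster can be compared to its exact reflection
  tr <- make_trial(stim_params(window_size = 16, speeds = c(3.33, 3.33),
                               condition = "static"), 32, seed = 13)
  stack <- render_frames(tr$target, pixels_per_degree = 4)
  expect_equal(dim(stack)[3], 34)
  img <- stack[, , 1]
  # fully symmetric static pattern: left-right mirror of the raster
  expect_equal(img, img[, rev(seq_len(ncol(img)))])
  expect_true(all(img %in% c(0.5, 1)))

  # single centred dot is centred in the image
  one <- tr$target
  one$frames <- list(tibble::tibble(dot_id = 1, pair_id = NA, is_symmetric = FALSE,
                                    half = "L", x = 0, y = 0, speed = 1,
                                    direction = 0, age = 0, lifetime = Inf,
                                    phase = 0))
  one$n_frames <- 1
  img1 <- render_frames(one, pixels_per_degree = 8)[, , 1]
  on_rows <- which(rowSums(img1 == 1) > 0)
  on_cols <- which(colSums(img1 == 1) > 0)
  expect_equal(mean(on_rows), (nrow(img1) + 1) / 2, tolerance = 0.51)
  expect_equal(mean(on_cols), (ncol(img1) + 1) / 2, tolerance = 0.51)
})

test_that("frame table export is tidy and complete", {
  p <- stim_params(speeds = c(3.33, 10), condition = "speed")
  tr <- make_trial(p, 8, seed = 14)
  tab <- frames_to_table(tr$target)
  expect_equal(nrow(tab), 34 * 32)
  expect_named(tab, c("frame", "dot_id", "pair_id", "x_deg", "y_deg",
                      "speed", "direction", "is_symmetric"))
})
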