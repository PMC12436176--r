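test_that("neutral template yields zero rigid-segment angles", {
  a <- compute_angles_frame(tmpl_R$markers)
  rigid <- hffm_angle_names[1:9]
  expect_equal(unname(a[rigid]), rep(0, 9), tolerance = 1e-9)
  expect_equal(unname(a[c("hallux_flexion", "hallux_abduction")]), c(0, 0),
               tolerance = 1e-9)
  expect_true(a["medial_arch"] > 0 && a["medial_arch"] <= 180)
})

test_that("a pre-rotated hindfoot reproduces the prescribed angle", {
  # forward kinematics: rotate the hindfoot (and everything distal) about the
  # AJC by a pure sagittal rotation in the shank-aligned Cardan basis
  m0 <- tmpl_R$markers
  seg0 <- hffm_segments(m0)
  R_sh <- cbind(drop(seg0$shank$x), drop(seg0$shank$y), drop(seg0$shank$z))
  Q <- cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1))
  ajc <- drop(seg0$joints$AJC)
  for (angles in list(c(10, 0, 0), c(0, -7, 0), c(0, 0, 12), c(8, 4, -5))) {
    A <- R_sh %*% Q %*% euler_xyz_compose(angles) %*% t(Q) %*% t(R_sh)
    m <- m0
    for (lab in names(m)) {
      if (hffm_segment_map[[lab]] %in% c("hindfoot", "forefoot", "hallux"))
        m[[lab]] <- drop(A %*% (m0[[lab]] - ajc)) + ajc
    }
    a <- compute_angles_frame(m)
    expect_equal(unname(a[1:3]), angles, tolerance = 1e-6)
    # the forefoot moved rigidly with the hindfoot: no midfoot motion
    expect_equal(unname(a[4:6]), c(0, 0, 0), tolerance = 0.2)
  }
})

test_that("dorsiflexion, varus and internal rotation are positive", {
  # rotate the whole foot into dorsiflexion: the toes rise relative to the
  # shank, which must read as positive sagittal angles
  m0 <- tmpl_R$markers
  seg0 <- hffm_segments(m0)
  ajc <- drop(seg0$joints$AJC)
  rot_about <- function(axis, deg) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    th <- deg * pi / 180
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  foot_rotated <- function(R) {
    m <- m0
    for (lab in names(m)) {
      if (hffm_segment_map[[lab]] != "shank")
        m[[lab]] <- drop(R %*% (m0[[lab]] - ajc)) + ajc
    }
    m
  }
  # toes up about the mediolateral axis (lab -y is lateral on this template):
  # rotation about +y lab by -10 lifts the toes
  a <- compute_angles_frame(foot_rotated(rot_about(c(0, 1, 0), -10)))
  expect_gt(a["hindfoot_shank_flexion"], 5)
  # varus: foot rolls onto its lateral border, medial side (+y lab on this
  # template) rising; rotation about the anterior axis by +10
  a <- compute_angles_frame(foot_rotated(rot_about(c(1, 0, 0), 10)))
  expect_gt(a["hindfoot_shank_varus"], 5)
  # internal rotation: toes swing medially (+y lab)
  a <- compute_angles_frame(foot_rotated(rot_about(c(0, 0, 1), 10)))
  expect_gt(a["hindfoot_shank_rotation"], 5)
})

test_that("flat collinear arch markers give a 180-degree medial arch", {
  m <- tmpl_R$markers
  m$NAV <- midpoint(m$MCL, m$DMT1)
  a <- compute_angles_frame(m)
  expect_equal(unname(a["medial_arch"]), 180)
})

test_that("missing markers null only the affected channels", {
  m <- tmpl_R$markers
  m$HLX <- NULL
  a <- compute_angles_frame(m)
  expect_true(all(is.na(a[c("hallux_flexion", "hallux_abduction")])))
  expect_true(all(is.finite(a[hffm_angle_names[1:9]])))
  expect_true(is.finite(a["medial_arch"]))
})

test_that("full-pipeline angles are invariant under global rigid transforms", {
  cfg <- gait_waveform_config(noise_sd = 0, n_cycles = 1)
  tr <- generate_trial(tmpl_R, cfg)
  a0 <- compute_angles(tr$traj$markers)
  set.seed(23)
  for (i in 1:5) {
    R <- random_rotation(); t3 <- rnorm(3, 0, 500)
    a1 <- compute_angles(transform_markers(tr$traj$markers, R, t3),
                         vertical = drop(R %*% c(0, 0, 1)))
    expect_lt(max(abs(a1 - a0)), 1e-6)
  }
})

test_that("mirrored left-foot trials reproduce right-foot angle curves", {
  cfgR <- gait_waveform_config(noise_sd = 0, n_cycles = 2)
  trR <- generate_trial(make_template_foot("R"), cfgR)
  trL <- generate_trial(make_template_foot("L"), cfgR)
  aR <- compute_angles(trR$traj$markers, side = "R")
  aL <- compute_angles(trL$traj$markers, side = "L")
  expect_lt(max(abs(aR - aL)), 1e-6)
})

test_that("smoothing preserves signal, kills spikes, keeps constants", {
  t <- seq(0, 3, by = 0.01)
  mk <- function(y) list(CCL = cbind(y, y, y), DMT1 = cbind(y, y, y),
                         DMT5 = cbind(y, y, y))
  # noiseless sine passes through nearly untouched
  y <- 30 * sin(2 * pi * t)
  tr <- hffm_traj(mk(y), rate = 100)
  sm <- smooth_trajectories(tr)
  expect_lt(max(abs(sm$markers$CCL[, 1] - y)), 0.01)
  # constants are preserved exactly
  tr <- hffm_traj(mk(rep(5, length(t))), rate = 100)
  expect_equal(smooth_trajectories(tr)$markers$CCL[, 1], rep(5, length(t)))
  # a 10 mm single-sample spike is attenuated below 1 mm
  y2 <- rep(0, length(t)); y2[150] <- 10
  tr <- hffm_traj(mk(y2), rate = 100)
  expect_lt(max(abs(smooth_trajectories(tr)$markers$CCL[, 1])), 1)
  # short gaps are interpolated; long gaps reject the trial
  y3 <- 30 * sin(2 * pi * t); y3[100:104] <- NA
  sm <- smooth_trajectories(hffm_traj(mk(y3), rate = 100))
  expect_lt(max(abs(sm$markers$CCL[, 1] - 30 * sin(2 * pi * t))), 0.05)
  y4 <- y3; y4[200:230] <- NA
  expect_error(smooth_trajectories(hffm_traj(mk(y4), rate = 100)), "gap")
})

test_that("gait events match generator ground truth within 2 samples", {
  cfg <- gait_waveform_config(noise_sd = 0, n_cycles = 3)
  tr <- generate_trial(tmpl_R, cfg)
  traj <- tr$traj; traj$events <- NULL
  ev <- detect_gait_events(traj)
  expect_equal(length(ev$ic), length(tr$events$ic))
  expect_true(all(abs(ev$ic - tr$events$ic) <= 2))
  expect_equal(length(ev$to), length(tr$events$to))
  expect_true(all(abs(ev$to - tr$events$to) <= 2))
  # two-cycle trial: exactly 3 ICs bounding 2 cycles, ordered with TOs
  cfg2 <- gait_waveform_config(noise_sd = 0, n_cycles = 2)
  tr2 <- generate_trial(tmpl_R, cfg2)
  traj2 <- tr2$traj; traj2$events <- NULL
  ev2 <- detect_gait_events(traj2)
  expect_equal(length(ev2$ic), 3L)
  expect_equal(length(ev2$to), 2L)
  expect_true(all(ev2$ic[1:2] < ev2$to & ev2$to < ev2$ic[2:3]))
})

test_that("standing trials raise a no-cycle error", {
  m <- lapply(tmpl_R$markers, function(p) matrix(p, 100, 3, byrow = TRUE))
  expect_error(detect_gait_events(hffm_traj(m, rate = 100)), "no detectable")
})

test_that("attached events override detection", {
  cfg <- gait_waveform_config(noise_sd = 0, n_cycles = 2)
  tr <- generate_trial(tmpl_R, cfg)
  ev <- gait_events(ic = c(5L, 50L), to = 20L, side = "R")
  traj <- tr$traj; traj$events <- ev
  expect_identical(detect_gait_events(traj), ev)
})

test_that("cycle normalization interpolates, averages and skips bad cycles", {
  ev <- gait_events(ic = c(1L, 101L), side = "R")
  ramp <- seq(0, 50, length.out = 101)
  cv <- normalize_to_cycle(ramp, ev)
  expect_length(cv$values, 101L)
  expect_equal(cv$values, seq(0, 50, length.out = 101), tolerance = 1e-9)
  # identical repeated cycles have zero SD everywhere
  ev2 <- gait_events(ic = c(1L, 101L, 201L), side = "R")
  x <- c(sin(seq(0, 2 * pi, length.out = 101)),
         sin(seq(0, 2 * pi, length.out = 101))[-1])
  cv2 <- normalize_to_cycle(x, ev2)
  expect_equal(cv2$n_cycles, 2L)
  expect_equal(max(cv2$sd), 0, tolerance = 1e-9)
  # two cycles offset by d average to base + d/2 (interior points; the
  # shared initial-contact sample belongs to the first cycle)
  d <- 6
  x3 <- c(sin(seq(0, 2 * pi, length.out = 101)),
          (sin(seq(0, 2 * pi, length.out = 101)) + d)[-1])
  cv3 <- normalize_to_cycle(x3, ev2)
  expect_equal(cv3$values[-1],
               (sin(seq(0, 2 * pi, length.out = 101)) + d / 2)[-1],
               tolerance = 1e-6)
  # a cycle containing NA is skipped with a log message
  x4 <- x3; x4[50] <- NA
  expect_message(cv4 <- normalize_to_cycle(x4, ev2), "skipped")
  expect_equal(cv4$n_cycles, 1L)
})

test_that("curve summaries compute mean, max and ROM", {
  s <- summarize_curve(rep(5, 101))
  expect_equal(c(s$mean, s$max, s$rom), c(5, 5, 0))
  v <- 10 * sin(2 * pi * seq(0, 1, length.out = 101))
  s2 <- summarize_curve(v)
  expect_equal(s2$mean, 0, tolerance = 0.11)
  expect_equal(s2$max, 10, tolerance = 0.05)
  expect_equal(s2$rom, 20, tolerance = 0.1)
  # rom = max - min definitionally on random curves
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(101)
    s3 <- summarize_curve(v)
    expect_equal(s3$rom, max(v) - min(v))
  }
})

test_that("classification follows the early flexion slope", {
  rising <- structure(list(values = c(seq(0, 5, length.out = 6),
                                      rep(5, 95))), class = "gait_curve")
  falling <- structure(list(values = c(seq(15, 10, length.out = 6),
                                       rep(10, 95))), class = "gait_curve")
  expect_identical(classify_foot_type(rising)$type, "EV")
  expect_identical(classify_foot_type(falling)$type, "non-EV")
  expect_gt(classify_foot_type(rising)$slope, 0)
  expect_error(classify_foot_type(rising, window = 0.5), "window")
})
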