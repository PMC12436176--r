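# ---- template foot -----------------------------------------------------------

# base marker geometry (mm) of a canonical right foot, before the alignment
# solve; marked entries are adjusted so that the neutral segment frames
# coincide exactly (all rigid-segment angles zero in neutral). A cavus arch
# raise lifts only the navicular: the apex of the medial arch rises relative
# to the unchanged medial chord (MCL to DMT1), and the lateral fifth
# metatarsal base absorbs the midfoot-height constraint.
.template_base <- function(scale, nav_raise_mm) {
  s <- scale
  list(
    CCL = c(0, 0, 40) * s,
    LCL = c(30, -22, 36) * s,
    MCL = c(30, 22, 36) * s,          # y, z solved
    LML = c(15, -27, 72) * s,
    MML = c(15, 27, 72) * s,
    LEP = c(15, -45, 470) * s,
    MEP = c(15, 45, 470) * s,
    TTU = c(45, 0, 390) * s,
    SH1 = c(20, 25, 330) * s,
    SH2 = c(15, 28, 210) * s,
    NAV = c(115, 15, 40) * s + c(0, 0, nav_raise_mm),
    PMT1 = c(128, 33, 28) * s,
    PMT5 = c(115, -32, 8) * s,        # y, z solved
    DMT1 = c(185, 42, 34) * s,
    DMT5 = c(172, -42, 34) * s,
    DMT2 = c(195, -2.5, 34) * s,      # y solved
    HLX = c(245, 0, 23) * s)          # re-anchored to the forefoot axis below
  }

# residuals that must vanish for all neutral segment frames to align:
# HRC and MFJC on the y = 0 midline at the height of the metatarsal rotation
# axis, and FFC on the midline too
.template_residual <- function(par, base, target_z) {
  m <- base
  m$MCL[2] <- par[1L]
  m$LCL[3] <- m$MCL[3] <- par[2L]
  m$PMT5[2] <- par[3L]
  m$PMT5[3] <- par[4L]
  m$DMT2[2] <- par[5L]
  hrc <- compute_hrc(m)
  mfjc <- compute_mfjc(m)
  ffc <- compute_mra_ffc(m)$FFC
  c(hrc[2], hrc[3] - target_z, mfjc[2], mfjc[3] - target_z, ffc[2])
}

#' Build a synthetic template foot
#'
#' Constructs a deterministic, anatomically plausible 17-marker template of
#' an adult foot plus shank. Five marker coordinates (medial calcaneus
#' y, the heel marker height, fifth metatarsal base y and height, second
#' metatarsal head y) are solved numerically (Newton iteration on exact
#' residuals) so that in the neutral pose the shank, hindfoot and forefoot
#' coordinate systems coincide and the hallux axis lies along the forefoot
#' x-axis: all rigid-segment angle channels are exactly zero by construction,
#' which makes prescribed joint waveforms exactly recoverable.
#'
#' @param side `"R"` or `"L"` (left templates are mirror images).
#' @param scale Global size factor in `[0.7, 1.3]` (1 = ~245 mm foot).
#' @param nav_raise_mm Raise of the navicular marker (mm) emulating a cavus
#'   arch; the alignment solve restores neutral frame alignment so only the
#'   phenomenological arch channels are affected.
#' @return A `foot_template`: list with `markers` (named length-3 vectors),
#'   `side`, `scale`, `foot_length_mm`, `segment_map`.
#' @export
make_template_foot <- function(side = "R", scale = 1, nav_raise_mm = 0) {
  side <- match.arg(side, c("R", "L"))
  if (scale < 0.7 || scale > 1.3)
    stop("'scale' must be in [0.7, 1.3]", call. = FALSE)
  base <- .template_base(scale, nav_raise_mm)
  # metatarsal head marker height minus the axis shift = neutral height of
  # the FFC, which the HRC and MFJC must share for aligned neutral frames
  target_z <- 34 * scale - 11
  par <- c(base$MCL[2], base$MCL[3], base$PMT5[2], base$PMT5[3], base$DMT2[2])
  for (iter in 1:30) {
    r <- .template_residual(par, base, target_z)
    if (max(abs(r)) < 1e-10) break
    J <- matrix(0, 5L, 5L)
    for (j in 1:5) {
      dp <- par; dp[j] <- dp[j] + 1e-6
      J[, j] <- (.template_residual(dp, base, target_z) - r) / 1e-6
    }
    par <- par - solve(J, r)
  }
  if (max(abs(.template_residual(par, base, target_z))) > 1e-8)
    stop("template alignment solve did not converge", call. = FALSE)
  m <- base
  m$MCL[2] <- par[1L]
  m$LCL[3] <- m$MCL[3] <- par[2L]
  m$PMT5[2] <- par[3L]
  m$PMT5[3] <- par[4L]
  m$DMT2[2] <- par[5L]
  ffc <- drop(compute_mra_ffc(m)$FFC)
  m$HLX <- ffc + c(60 * scale, 0, 0)   # hallux along the neutral forefoot axis
  if (side == "L") m <- lapply(m, function(p) p * c(1, -1, 1))
  structure(list(markers = m, side = side, scale = scale,
                 nav_raise_mm = nav_raise_mm,
                 foot_length_mm = m$HLX[1L] - m$CCL[1L],
                 segment_map = hffm_segment_map),
            class = "foot_template")
}

#' @export
print.foot_template <- function(x, ...) {
  cat(sprintf("Synthetic template foot: side %s, scale %.2f, length %.0f mm\n",
              x$side, x$scale, x$foot_length_mm))
  invisible(x)
}

# ---- waveform configuration --------------------------------------------------

.waveform <- function(offset, amp = numeric(0), freq = numeric(0),
                      phase = numeric(0)) {
  list(offset = offset, amp = amp, freq = freq, phase = phase)
}

#' Evaluate a joint waveform at gait-cycle phases
#'
#' A waveform is an offset plus up to three sinusoids,
#' `offset + sum(amp_i * cos(2 * pi * freq_i * phase + phase_i))`, with
#' `phase` in cycle fractions and amplitudes in degrees.
#'
#' @param wf Waveform (list with `offset`, `amp`, `freq`, `phase`).
#' @param phase Numeric vector of cycle fractions.
#' @return Waveform values in degrees.
#' @export
eval_waveform <- function(wf, phase) {
  y <- rep(wf$offset, length(phase))
  for (i in seq_along(wf$amp))
    y <- y + wf$amp[i] * cos(2 * pi * wf$freq[i] * phase + wf$phase[i])
  y
}

.waveform_peak <- function(wf) abs(wf$offset) + sum(abs(wf$amp))

.default_waveforms <- function() {
  list(
    # hindfoot vs shank: dorsiflexed at contact, plantarflexing through the
    # first rocker (negative early slope = heel-first contact)
    hs_flexion = .waveform(2, c(6, 2), c(1, 2), c(0, 0)),
    hs_varus = .waveform(1, 3, 1, pi),
    hs_rotation = .waveform(-3, 4, 1, pi),
    # forefoot vs hindfoot
    fh_flexion = .waveform(-4, 4, 1, 0),
    fh_supination = .waveform(4, 3, 1, pi),
    fh_adduction = .waveform(-1, 3, 1, 0),
    # hallux vs forefoot
    hallux_flexion = .waveform(18, 14, 1, pi),
    hallux_abduction = .waveform(-14, 3, 1, 0))
}

#' Gait waveform configuration for the synthetic generator
#'
#' @param waveforms Named list of per-channel waveforms (see
#'   [eval_waveform()]); defaults emulate typically developing gait with zero
#'   slope at initial contact for all channels (cosine terms only).
#' @param cadence Steps per minute (cycle duration = 120/cadence s).
#' @param n_cycles Number of gait cycles.
#' @param rate Sampling rate, Hz.
#' @param noise_sd Isotropic Gaussian marker noise SD in mm.
#' @param seed Random seed (same config = identical output).
#' @param preset Deformity preset label (`"TD"`, `"CV"`, `"EV"`).
#' @param stride_mm Forward progression per cycle.
#' @param lift_mm Peak swing-phase foot lift.
#' @param bob_mm Vertical body oscillation amplitude (minimum at initial
#'   contact, which anchors event detection).
#' @param stance_fraction Fraction of the cycle in stance (toe-off instant).
#' @param nav_raise_mm Navicular raise passed to the template (cavus arch).
#' @return Object of class `gait_config`.
#' @export
gait_waveform_config <- function(waveforms = .default_waveforms(),
                                 cadence = 110, n_cycles = 5, rate = 100,
                                 noise_sd = 0.5, seed = 1L, preset = "TD",
                                 stride_mm = 1150, lift_mm = 55, bob_mm = 10,
                                 stance_fraction = 0.6, nav_raise_mm = 0) {
  stopifnot(rate > 0, noise_sd >= 0, cadence > 0, n_cycles >= 1,
            stance_fraction > 0.2, stance_fraction < 0.9)
  peaks <- vapply(waveforms, .waveform_peak, 1)
  if (any(peaks > 80))
    stop("waveform amplitude exceeds 80 degrees (gimbal safety): ",
         paste(names(peaks)[peaks > 80], collapse = ", "), call. = FALSE)
  structure(list(waveforms = waveforms, cadence = cadence,
                 n_cycles = n_cycles, rate = rate, noise_sd = noise_sd,
                 seed = seed, preset = preset, stride_mm = stride_mm,
                 lift_mm = lift_mm, bob_mm = bob_mm,
                 stance_fraction = stance_fraction,
                 nav_raise_mm = nav_raise_mm),
            class = "gait_config")
}

#' Apply a deformity preset to a gait configuration
#'
#' `TD` is the typically-developing baseline. `CV` (cavovarus) adds a
#' dorsiflexion and hindfoot varus offset, plantarflexes the forefoot
#' relative to the hindfoot and raises the navicular (higher arch). `EV`
#' (equinovarus) replaces the hindfoot/shank flexion waveform with a
#' plantarflexed pattern whose slope right after initial contact is positive
#' (forefoot-first contact), with stronger varus, forefoot adduction and
#' navicular raise. The offsets are preset constants of the generator, not
#' estimates of any cohort.
#'
#' @param cfg A [gait_waveform_config()].
#' @param preset `"TD"`, `"CV"` or `"EV"`.
#' @return The modified configuration.
#' @export
apply_deformity_preset <- function(cfg, preset = c("TD", "CV", "EV")) {
  preset <- match.arg(preset)
  cfg$preset <- preset
  if (preset == "CV") {
    cfg$waveforms$hs_flexion$offset <- cfg$waveforms$hs_flexion$offset + 4
    cfg$waveforms$hs_varus$offset <- cfg$waveforms$hs_varus$offset + 5
    cfg$waveforms$fh_flexion$offset <- cfg$waveforms$fh_flexion$offset - 4
    cfg$nav_raise_mm <- 8
  } else if (preset == "EV") {
    # plantarflexed throughout, rising right after initial contact
    cfg$waveforms$hs_flexion <- .waveform(-8, c(6, 2), c(1, 2), c(pi, pi))
    cfg$waveforms$hs_varus$offset <- cfg$waveforms$hs_varus$offset + 7
    cfg$waveforms$fh_adduction$offset <- cfg$waveforms$fh_adduction$offset + 6
    cfg$nav_raise_mm <- 14
  }
  cfg
}

# ---- trial generation --------------------------------------------------------

# quintic smoothstep: C2, zero first/second derivative at both ends
.smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic gait trial
#'
#' Drives the rigid four-segment template through prescribed joint-angle
#' waveforms by forward kinematics: the shank translates along a gait-like
#' path (forward progression during swing, vertical body bob with its
#' minimum at initial contact, swing-phase foot lift); the hindfoot rotates
#' about the ankle joint center relative to the shank, the forefoot about
#' the midfoot joint center relative to the hindfoot, and the hallux axis
#' about the forefoot center, all in the sagittal/frontal/transverse Cardan
#' sequence used by the analysis. Markers ride rigidly on their segments;
#' seeded isotropic Gaussian noise is added last.
#'
#' @param template A [make_template_foot()] template (its `nav_raise_mm` is
#'   overridden by the configuration's).
#' @param cfg A [gait_waveform_config()].
#' @return List with `traj` (an [hffm_traj()] with exact events attached),
#'   `ground_truth` (n x 11 matrix of the prescribed rigid-segment and hallux
#'   channels per frame, named as in [hffm_angle_names]), `events`, and
#'   `config`.
#' @export
generate_trial <- function(template, cfg = gait_waveform_config()) {
  stopifnot(inherits(template, "foot_template"), inherits(cfg, "gait_config"))
  if (cfg$nav_raise_mm != template$nav_raise_mm)
    template <- make_template_foot(template$side, template$scale,
                                   nav_raise_mm = cfg$nav_raise_mm)
  side <- template$side
  m0 <- template$markers
  if (side == "L") m0 <- lapply(m0, function(p) p * c(1, -1, 1))

  cycle_s <- 120 / cfg$cadence
  n <- round(cfg$n_cycles * cycle_s * cfg$rate) + 1L
  t <- (seq_len(n) - 1L) / cfg$rate
  phi_tot <- t / cycle_s
  k <- pmin(floor(phi_tot), cfg$n_cycles - 1L)
  phi <- phi_tot - k
  sf <- cfg$stance_fraction

  # prescribed channel values per frame (degrees)
  wf <- cfg$waveforms
  ank <- cbind(eval_waveform(wf$hs_flexion, phi),
               eval_waveform(wf$hs_varus, phi),
               eval_waveform(wf$hs_rotation, phi))
  mid <- cbind(eval_waveform(wf$fh_flexion, phi),
               eval_waveform(wf$fh_supination, phi),
               eval_waveform(wf$fh_adduction, phi))
  hal <- cbind(eval_waveform(wf$hallux_flexion, phi),
               eval_waveform(wf$hallux_abduction, phi))

  # neutral joint parameters of the canonical template
  j0 <- hffm_joints(m0)
  seg0 <- hffm_segments(m0)
  R_sh0 <- cbind(drop(seg0$shank$x), drop(seg0$shank$y), drop(seg0$shank$z))
  Q <- cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1))
  AJC0 <- drop(j0$AJC); MFJC0 <- drop(j0$MFJC); FFC0 <- drop(j0$FFC)

  # global shank path
  u <- (phi - sf) / (1 - sf)
  prog <- cfg$stride_mm * (k + .smoothstep(u))
  liftv <- cfg$lift_mm * ifelse(phi > sf, sin(pi * pmin(1, pmax(0, u)))^2, 0)
  bob <- cfg$bob_mm * (1 - cos(2 * pi * phi)) / 2
  trans <- cbind(prog, 0, bob + liftv)

  labs <- names(m0)
  segs <- hffm_segment_map[labs]
  out <- lapply(labs, function(l) matrix(0, n, 3L))
  names(out) <- labs
  gt <- matrix(0, n, 11L)
  colnames(gt) <- c(hffm_angle_names[1:9], "hallux_flexion", "hallux_abduction")
  gt[, 1:3] <- ank
  gt[, 4:6] <- mid
  gt[, 10:11] <- hal
  L_hal <- sqrt(sum((m0$HLX - FFC0)^2))

  QR <- function(w) Q %*% euler_xyz_compose(w) %*% t(Q)
  for (i in seq_len(n)) {
    Ra <- QR(ank[i, ])
    Rm <- QR(mid[i, ])
    A <- R_sh0 %*% Ra %*% t(R_sh0)
    B <- R_sh0 %*% Ra %*% Rm %*% t(R_sh0)
    gt[i, 7:9] <- euler_xyz_decompose(
      t(Q) %*% (Ra %*% Rm) %*% Q, check = FALSE)
    ajc_t <- AJC0 + trans[i, ]
    mfjc_t <- ajc_t + drop(A %*% (MFJC0 - AJC0))
    ffc_t <- mfjc_t + drop(B %*% (FFC0 - MFJC0))
    for (l in labs) {
      p <- switch(segs[[l]],
        shank = m0[[l]] + trans[i, ],
        hindfoot = ajc_t + drop(A %*% (m0[[l]] - AJC0)),
        forefoot = mfjc_t + drop(B %*% (m0[[l]] - MFJC0)),
        hallux = {
          h_seg <- c(1, -tan(.rad(hal[i, 2L])), -tan(.rad(hal[i, 1L])))
          h_seg <- h_seg / sqrt(sum(h_seg^2))
          ffc_t + L_hal * drop(B %*% R_sh0 %*% h_seg)
        })
      out[[l]][i, ] <- p
    }
  }

  if (side == "L") out <- lapply(out, function(p) p %*% diag(c(1, -1, 1)))
  if (cfg$noise_sd > 0) {
    out <- .with_seed(cfg$seed, lapply(out, function(p)
      p + matrix(stats::rnorm(length(p), 0, cfg$noise_sd), nrow(p))))
  }

  ic <- 1L + round((0:cfg$n_cycles) * cycle_s * cfg$rate)
  ic <- ic[ic <= n]
  to <- 1L + round(((seq_len(cfg$n_cycles) - 1L) + sf) * cycle_s * cfg$rate)
  to <- to[to <= n]
  ev <- gait_events(ic = ic, to = to, side = side)

  traj <- hffm_traj(out, rate = cfg$rate, side = side, events = ev)
  list(traj = traj, ground_truth = gt, events = ev, config = cfg)
}
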