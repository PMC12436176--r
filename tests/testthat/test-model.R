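test_that("primary centers are marker midpoints and KJA points laterally", {
  m <- list(LEP = c(0, 50, 400), MEP = c(0, -50, 400),
            LML = c(10, 40, 60), MML = c(10, -30, 70))
  pc <- compute_primary_centers(m)
  expect_equal(pc$KJC, c(0, 0, 400))
  expect_equal(pc$AJC, c(10, 5, 65))
  expect_equal(pc$KJA_dir, c(0, 1, 0))
  m$MEP <- m$LEP
  expect_error(compute_primary_centers(m), "coincide")
  expect_error(compute_primary_centers(list(LEP = c(0, 0, 0))), "missing marker")
})

test_that("HRC regression applies the published coefficients exactly", {
  expect_equal(hrc_regression(c(-10, 0, 5), c(0, 20, 3), c(0, -20, 3)),
               c(-5.4, 0.2, 6.745), tolerance = 1e-12)
  expect_equal(hrc_regression(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
})

test_that("MFJC regression applies the published coefficients exactly", {
  # hand evaluation: x = .16*100+.25*120+.30*110, y = .52*10-.17*20+.26*(-25),
  # z = .5*30+.5*15
  expect_equal(mfjc_regression(c(100, 10, 30), c(120, 20, 20), c(110, -25, 15)),
               c(79, -4.7, 22.5), tolerance = 1e-12)
  expect_equal(mfjc_regression(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  # z is the plain average when both heights agree
  expect_equal(mfjc_regression(c(0, 0, 7), c(5, 5, 99), c(0, 0, 7))[3], 7)
})

test_that("regressed joint centers are rigid-transform equivariant", {
  set.seed(11)
  m <- jittered_markers()
  hrc0 <- compute_hrc(m)
  mfjc0 <- compute_mfjc(m)
  for (i in 1:20) {
    R <- random_rotation(); tr <- rnorm(3, 0, 200)
    mt <- transform_markers(m, R, tr)
    expect_equal(compute_hrc(mt), drop(R %*% hrc0) + tr, tolerance = 1e-9)
    expect_equal(compute_mfjc(mt), drop(R %*% mfjc0) + tr, tolerance = 1e-9)
  }
})

test_that("HRC lies in the heel, posterior to the mid heel markers", {
  set.seed(5)
  for (i in 1:25) {
    m <- jittered_markers()
    lf <- local_foot_frame(m)
    hrc_x <- drop((compute_hrc(m) - drop(lf$origin)) %*% drop(lf$x))
    mid_x <- drop((midpoint(m$MCL, m$LCL) - drop(lf$origin)) %*% drop(lf$x))
    expect_lt(hrc_x, mid_x)
  }
})

test_that("MRA is the metatarsal axis shifted 11 mm down; FFC lies on it", {
  m <- list(DMT1 = c(150, 30, 20), DMT5 = c(140, -40, 20),
            DMT2 = c(160, 0, 25))
  mra <- compute_mra_ffc(m)
  expect_equal(mra$MRA_dir,
               (m$DMT1 - m$DMT5) / sqrt(sum((m$DMT1 - m$DMT5)^2)))
  expect_equal(mra$MRA_point, c(150, 30, 9))
  # FFC equals an independently computed projection
  d <- mra$MRA_dir
  want <- mra$MRA_point + sum((m$DMT2 - mra$MRA_point) * d) * d
  expect_equal(mra$FFC, want, tolerance = 1e-12)
  # incidence: FFC on the MRA line
  expect_lt(sqrt(sum(v_cross(matrix(mra$FFC - mra$MRA_point, 1),
                             matrix(d, 1))^2)), 1e-6)
  # DMT2 already on the axis projects to itself
  m2 <- m; m2$DMT2 <- m$DMT1 - 11 * c(0, 0, 1) + 5 * d
  expect_equal(compute_mra_ffc(m2)$FFC, m2$DMT2, tolerance = 1e-9)
  m$DMT5 <- m$DMT1
  expect_error(compute_mra_ffc(m), "degenerate")
})

test_that("shank frame matches a hand Gram-Schmidt construction", {
  j <- list(KJC = c(0, 0, 400), AJC = c(0, 0, 0), KJA_dir = c(0, 1, 0))
  fr <- build_shank_frame(j)
  expect_equal(drop(fr$z), c(0, 0, -1))
  expect_equal(drop(fr$x), c(-1, 0, 0))
  expect_gt(drop(fr$y)[2], 0) # y in the +lab-y half space, toward LEP
  expect_lt(frame_orthonormality_error(fr), 1e-9)
  j$KJA_dir <- c(0, 0, 1) # parallel to the long axis
  expect_error(build_shank_frame(j), "degenerate")
})

test_that("hindfoot frame follows the cross-product construction", {
  j <- list(HRC = c(0, 0, 10), MFJC = c(120, 0, 25), AJC = c(10, 0, 70))
  fr <- build_hindfoot_frame(j)
  expect_equal(drop(fr$x), c(120, 0, 15) / sqrt(120^2 + 15^2), tolerance = 1e-12)
  # y is the sagittal-plane normal; z completes the right-handed triad
  expect_equal(abs(drop(fr$y)), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(drop(fr$z), drop(v_cross(fr$x, fr$y)), tolerance = 1e-12)
  expect_lt(frame_orthonormality_error(fr), 1e-9)
  j$AJC <- j$HRC + 2 * (j$MFJC - j$HRC) # collinear
  expect_error(build_hindfoot_frame(j), "degenerate")
})

test_that("forefoot frame is orthonormal with x along MFJC to FFC", {
  j <- list(MFJC = c(80, 0, 22), FFC = c(150, 0, 10),
            MRA_dir = c(0.141, -0.99, 0) / sqrt(0.141^2 + 0.99^2))
  fr <- build_forefoot_frame(j)
  expect_equal(drop(fr$x), c(70, 0, -12) / sqrt(70^2 + 144), tolerance = 1e-9)
  expect_lt(frame_orthonormality_error(fr), 1e-9)
  j$MRA_dir <- drop(fr$x)
  expect_error(build_forefoot_frame(j), "degenerate")
})

test_that("hallux axis is the unit FFC-to-HLX direction", {
  j <- list(FFC = c(150, 0, 10))
  expect_equal(build_hallux_axis(list(HLX = c(180, 0, 10)), j), c(1, 0, 0))
  set.seed(2)
  h <- c(190, 8, 20)
  expect_equal(build_hallux_axis(list(HLX = h), j),
               (h - j$FFC) / sqrt(sum((h - j$FFC)^2)))
  expect_error(build_hallux_axis(list(HLX = j$FFC), j), "degenerate")
})

test_that("segment frames are orthonormal for random valid geometry", {
  set.seed(13)
  for (i in 1:100) {
    m <- jittered_markers(sd = 4)
    seg <- hffm_segments(m)
    expect_lt(frame_orthonormality_error(seg$shank), 1e-9)
    expect_lt(frame_orthonormality_error(seg$hindfoot), 1e-9)
    expect_lt(frame_orthonormality_error(seg$forefoot), 1e-9)
    j <- seg$joints
    expect_lt(sqrt(sum(v_cross(.row1(j$FFC) - .row1(j$MRA_point),
                               .row1(j$MRA_dir))^2)), 1e-6)
  }
})

test_that("whole-leg rigid transforms move every frame rigidly", {
  set.seed(17)
  m <- jittered_markers()
  seg0 <- hffm_segments(m)
  for (i in 1:20) {
    R <- random_rotation(); tr <- rnorm(3, 0, 100)
    # the vertical reference co-rotates with the lab
    seg1 <- hffm_segments(transform_markers(m, R, tr),
                          vertical = drop(R %*% c(0, 0, 1)))
    for (f in c("shank", "hindfoot", "forefoot")) {
      expect_equal(drop(seg1[[f]]$origin),
                   drop(R %*% drop(seg0[[f]]$origin)) + tr, tolerance = 1e-8)
      for (ax in c("x", "y", "z"))
        expect_equal(drop(seg1[[f]][[ax]]), drop(R %*% drop(seg0[[f]][[ax]])),
                     tolerance = 1e-9)
    }
  }
})

test_that("local foot frame is anchored at CCL and rejects vertical feet", {
  m <- list(CCL = c(0, 0, 40), DMT1 = c(185, 40, 30), DMT5 = c(165, -40, 30))
  lf <- local_foot_frame(m)
  expect_equal(drop(lf$origin), m$CCL)
  expect_equal(drop(lf$z), c(0, 0, 1))
  expect_equal(drop(lf$x), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(drop(lf$y), c(0, 1, 0), tolerance = 1e-12)
  # left feet flip the mediolateral axis
  expect_equal(drop(local_foot_frame(m, side = "L")$y), c(0, -1, 0),
               tolerance = 1e-12)
  m$DMT1 <- c(2, 1, 200); m$DMT5 <- c(-2, -1, 200)
  expect_error(local_foot_frame(m), "vertical")
})
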