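# ---- marker handling ---------------------------------------------------------

# coerce a named collection of marker positions into a list of n x 3 matrices,
# checking presence and equal frame counts
.get_markers <- function(markers, labels) {
  if (is.null(names(markers)))
    stop("'markers' must be a named list of positions", call. = FALSE)
  missing <- setdiff(labels, names(markers))
  if (length(missing))
    stop("missing marker(s): ", paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(markers[labels], .as_v3, arg = "marker")
  n <- vapply(out, nrow, 1L)
  if (length(unique(n)) != 1L)
    stop("markers have differing numbers of frames", call. = FALSE)
  for (lab in labels) .check_finite(out[[lab]], lab)
  out
}

# normal of the mirroring plane for left feet: lab y orthogonalized to the
# vertical, so the reflection maps a left foot onto a right-equivalent foot
# while preserving heights
.mirror_normal <- function(vertical) {
  v <- v_unit(.as_v3(vertical), what = "vertical axis")
  n <- c(0, 1, 0) - drop(v) * sum(drop(v) * c(0, 1, 0))
  if (sqrt(sum(n^2)) < 1e-6)
    stop("vertical axis is (near) parallel to lab y; cannot mirror left-foot data",
         call. = FALSE)
  n / sqrt(sum(n^2))
}

#' Mirror marker positions across a vertical plane
#'
#' Reflects positions across the plane through the origin that contains the
#' vertical axis and the lab x direction. Left-foot data mirrored this way can
#' be processed with the right-foot segment definitions, which gives all angle
#' channels one shared clinical sign convention.
#'
#' @param markers Named list of length-3 vectors or n x 3 matrices.
#' @param vertical Lab vertical direction (default `c(0, 0, 1)`).
#' @return The mirrored markers, same structure.
#' @export
mirror_markers <- function(markers, vertical = c(0, 0, 1)) {
  n <- .mirror_normal(vertical)
  lapply(markers, function(p) {
    pm <- .as_v3(p)
    out <- pm - 2 * (pm %*% n) %*% t(n)
    .v3_shape(out, p)
  })
}

.canonical_markers <- function(markers, side, vertical) {
  side <- match.arg(side, c("R", "L"))
  if (side == "L") mirror_markers(markers, vertical) else markers
}

# ---- frames ------------------------------------------------------------------

.frame <- function(origin, x, y, z) {
  structure(list(origin = origin, x = x, y = y, z = z), class = "hffm_frames")
}

#' Orthonormality error of a segment frame
#'
#' Largest absolute deviation of the frame's axis matrix from a proper
#' rotation (RtR = I and det = +1), across all time samples. Used to verify
#' the segment coordinate system invariants.
#'
#' @param frame A frame as returned by the `build_*_frame` functions.
#' @return Maximum absolute deviation (unitless).
#' @export
frame_orthonormality_error <- function(frame) {
  x <- frame$x; y <- frame$y; z <- frame$z
  err <- cbind(abs(v_dot(x, x) - 1), abs(v_dot(y, y) - 1), abs(v_dot(z, z) - 1),
               abs(v_dot(x, y)), abs(v_dot(x, z)), abs(v_dot(y, z)),
               abs(v_dot(v_cross(x, y), z) - 1))
  max(err)
}

# local coordinates of points in a (possibly vectorized) frame
.to_local <- function(p, frame) {
  rel <- p - frame$origin
  cbind(v_dot(rel, frame$x), v_dot(rel, frame$y), v_dot(rel, frame$z))
}

.from_local <- function(q, frame) {
  frame$origin + frame$x * q[, 1L] + frame$y * q[, 2L] + frame$z * q[, 3L]
}

#' Foot-anchored reference frame
#'
#' A coarse whole-foot frame used by the phenomenological angle channels:
#' origin at the dorsal calcaneus marker (CCL), x along the horizontal
#' projection of the heel-to-forefoot direction (CCL to the midpoint of DMT1
#' and DMT5), z along the lab vertical, y completing the triad (negated for
#' left feet so conventions mirror).
#'
#' @param markers Named list of marker positions (needs CCL, DMT1, DMT5).
#' @param side `"R"` or `"L"`.
#' @param vertical Lab vertical direction.
#' @return A frame (list with `origin`, `x`, `y`, `z`, each n x 3).
#' @export
local_foot_frame <- function(markers, side = "R", vertical = c(0, 0, 1)) {
  side <- match.arg(side, c("R", "L"))
  m <- .get_markers(markers, c("CCL", "DMT1", "DMT5"))
  v <- v_unit(.as_v3(vertical), what = "vertical axis")
  n <- nrow(m$CCL)
  v <- v[rep(1L, n), , drop = FALSE]
  ax <- midpoint(m$DMT1, m$DMT5) - m$CCL
  horiz <- ax - v * v_dot(ax, v)
  # reject feet pitched to within 5 degrees of vertical: x would be undefined
  if (any(v_norm(horiz) < sin(.rad(5)) * v_norm(ax)))
    stop("degenerate foot axis: heel-to-forefoot direction within 5 degrees of vertical",
         call. = FALSE)
  x <- v_unit(horiz, what = "foot axis")
  y <- v_cross(v, x)
  if (side == "L") y <- -y
  .frame(m$CCL, x, y, v)
}

# ---- joint centers and axes --------------------------------------------------

#' Knee and ankle joint centers and knee joint axis
#'
#' Knee joint center = midpoint of the femoral epicondyle markers, ankle
#' joint center = midpoint of the malleolar markers, knee joint axis from the
#' medial to the lateral epicondyle.
#'
#' @param markers Named list with LEP, MEP, LML, MML.
#' @return List with `KJC`, `AJC` (mm) and unit `KJA_dir`.
#' @export
compute_primary_centers <- function(markers) {
  m <- .get_markers(markers, c("LEP", "MEP", "LML", "MML"))
  kja <- m$LEP - m$MEP
  if (any(v_norm(kja) <= 1e-6))
    stop("degenerate geometry: LEP and MEP coincide", call. = FALSE)
  if (any(v_norm(m$LML - m$MML) <= 1e-6))
    stop("degenerate geometry: LML and MML coincide", call. = FALSE)
  list(KJC = .v3_shape(midpoint(m$LEP, m$MEP), markers$LEP),
       AJC = .v3_shape(midpoint(m$LML, m$MML), markers$LML),
       KJA_dir = .v3_shape(v_unit(kja, what = "knee joint axis"), markers$LEP))
}

#' Heel rotation center regression (local coordinates)
#'
#' Applies the published linear regression to calcaneus marker positions
#' expressed in a foot-anchored local frame:
#' `HRC_x = 0.54 CCL_x - 0.15 LCL_x + 0.15 MCL_x`,
#' `HRC_y = 0.28 CCL_y + 0.43 LCL_y + 0.42 MCL_y`,
#' `HRC_z = 0.29 CCL_z + 0.025 LCL_z + 1.74 MCL_z`.
#'
#' @param ccl,lcl,mcl Local coordinates (length-3 vectors or n x 3 matrices).
#' @return The heel rotation center in the same local coordinates.
#' @export
hrc_regression <- function(ccl, lcl, mcl) {
  c3 <- .as_v3(ccl); l3 <- .as_v3(lcl); m3 <- .as_v3(mcl)
  out <- cbind(0.54 * c3[, 1L] - 0.15 * l3[, 1L] + 0.15 * m3[, 1L],
               0.28 * c3[, 2L] + 0.43 * l3[, 2L] + 0.42 * m3[, 2L],
               0.29 * c3[, 3L] + 0.025 * l3[, 3L] + 1.74 * m3[, 3L])
  .v3_shape(out, ccl)
}

#' Midfoot joint center regression (local coordinates)
#'
#' Applies the published linear regression to navicular and proximal
#' metatarsal marker positions in a foot-anchored local frame:
#' `MFJC_x = 0.16 NAV_x + 0.25 PMT1_x + 0.30 PMT5_x`,
#' `MFJC_y = 0.52 NAV_y - 0.17 PMT1_y + 0.26 PMT5_y`,
#' `MFJC_z = 0.5 NAV_z + 0.5 PMT5_z`.
#'
#' @param nav,pmt1,pmt5 Local coordinates (length-3 vectors or n x 3 matrices).
#' @return The midfoot joint center in the same local coordinates.
#' @export
mfjc_regression <- function(nav, pmt1, pmt5) {
  n3 <- .as_v3(nav); p1 <- .as_v3(pmt1); p5 <- .as_v3(pmt5)
  out <- cbind(0.16 * n3[, 1L] + 0.25 * p1[, 1L] + 0.30 * p5[, 1L],
               0.52 * n3[, 2L] - 0.17 * p1[, 2L] + 0.26 * p5[, 2L],
               0.50 * n3[, 3L] + 0.50 * p5[, 3L])
  .v3_shape(out, nav)
}

# technical frame rigidly attached to the hindfoot, in which the HRC
# regression is evaluated: origin CCL, z from the mid heel markers up toward
# the ankle joint center (the ankle pivot is rigid with respect to the
# hindfoot), x the heel-to-midheel direction orthogonalized to z, y = z
# cross x. Using the ankle center provides the out-of-plane reference the
# three calcaneus markers alone cannot (they would confine the regressed
# point to their own plane).
.hindfoot_technical_frame <- function(m) {
  ajc <- midpoint(m$LML, m$MML)
  heelmid <- midpoint(m$LCL, m$MCL)
  z <- v_unit(ajc - heelmid, what = "heel-to-ankle direction")
  u <- heelmid - m$CCL
  ux <- u - z * v_dot(u, z)
  if (any(v_norm(ux) <= 1e-6))
    stop("degenerate calcaneus geometry: CCL on the heel-ankle axis",
         call. = FALSE)
  x <- v_unit(ux, what = "hindfoot technical x")
  .frame(m$CCL, x, v_cross(z, x), z)
}

# technical frame rigidly attached to the forefoot markers, for the MFJC
# regression: origin NAV, x toward the mid metatarsal heads, z normal to the
# forefoot marker plane, y = z cross x
.forefoot_technical_frame <- function(m) {
  u <- midpoint(m$DMT1, m$DMT5) - m$NAV
  w <- m$DMT1 - m$DMT5
  zr <- v_cross(u, w)
  if (any(v_norm(zr) <= 1e-6 * pmax(v_norm(u) * v_norm(w), 1e-12)))
    stop("degenerate forefoot marker triad (collinear)", call. = FALSE)
  x <- v_unit(u, what = "forefoot technical x")
  z <- v_unit(zr, what = "forefoot technical z")
  .frame(m$NAV, x, v_cross(z, x), z)
}

#' Heel rotation center from calcaneus markers
#'
#' Expresses CCL, LCL and MCL in a technical frame rigidly attached to the
#' calcaneus markers, applies [hrc_regression()], and maps the result back to
#' lab coordinates. Because the technical frame is marker-only the regressed
#' point moves rigidly with the hindfoot and is equivariant under rigid
#' transforms of the marker set.
#'
#' @param markers Named list with CCL, LCL, MCL and the malleolar markers
#'   LML, MML (their midpoint, the ankle pivot, anchors the frame's vertical
#'   sense).
#' @param side `"R"` or `"L"`; left feet are mirrored internally so one set of
#'   regression coefficients serves both sides.
#' @param vertical Lab vertical direction (used only to mirror left feet).
#' @return Heel rotation center(s) in lab coordinates (mm).
#' @export
compute_hrc <- function(markers, side = "R", vertical = c(0, 0, 1)) {
  side <- match.arg(side, c("R", "L"))
  m <- .get_markers(.canonical_markers(markers, side, vertical),
                    c("CCL", "LCL", "MCL", "LML", "MML"))
  fr <- .hindfoot_technical_frame(m)
  loc <- hrc_regression(.to_local(m$CCL, fr), .to_local(m$LCL, fr),
                        .to_local(m$MCL, fr))
  out <- .from_local(.as_v3(loc), fr)
  if (side == "L") out <- mirror_markers(list(p = out), vertical)$p
  .v3_shape(out, markers$CCL)
}

#' Midfoot joint center from forefoot markers
#'
#' Expresses NAV, PMT1 and PMT5 in a technical frame rigidly attached to the
#' forefoot markers, applies [mfjc_regression()], and maps the result back to
#' lab coordinates.
#'
#' @inheritParams compute_hrc
#' @param markers Named list with NAV, PMT1, PMT5, DMT1, DMT5.
#' @return Midfoot joint center(s) in lab coordinates (mm).
#' @export
compute_mfjc <- function(markers, side = "R", vertical = c(0, 0, 1)) {
  side <- match.arg(side, c("R", "L"))
  m <- .get_markers(.canonical_markers(markers, side, vertical),
                    c("NAV", "PMT1", "PMT5", "DMT1", "DMT5"))
  fr <- .forefoot_technical_frame(m)
  loc <- mfjc_regression(.to_local(m$NAV, fr), .to_local(m$PMT1, fr),
                         .to_local(m$PMT5, fr))
  out <- .from_local(.as_v3(loc), fr)
  if (side == "L") out <- mirror_markers(list(p = out), vertical)$p
  .v3_shape(out, markers$NAV)
}

#' Metatarsal rotation axis and forefoot center
#'
#' The metatarsal rotation axis (MRA) runs parallel to the line between the
#' first and fifth metatarsal head markers (DMT1, DMT5) shifted 11 mm
#' downwards along the lab vertical (8 mm metatarsal head radius plus 3 mm
#' marker radius). The forefoot center (FFC) is the orthogonal projection of
#' the second metatarsal head marker (DMT2) onto this axis.
#'
#' @param markers Named list with DMT1, DMT2, DMT5.
#' @param vertical Lab vertical direction (gravity reference of the shift).
#' @param shift_mm Downward shift of the axis in mm (default 11).
#' @return List with `MRA_point`, unit `MRA_dir`, and `FFC` (lab mm).
#' @export
compute_mra_ffc <- function(markers, vertical = c(0, 0, 1), shift_mm = 11) {
  m <- .get_markers(markers, c("DMT1", "DMT2", "DMT5"))
  v <- v_unit(.as_v3(vertical), what = "vertical axis")
  axis <- m$DMT1 - m$DMT5
  if (any(v_norm(axis) <= 1e-6))
    stop("degenerate geometry: DMT1 and DMT5 coincide", call. = FALSE)
  dir <- v_unit(axis, what = "metatarsal axis")
  point <- m$DMT1 - v[rep(1L, nrow(m$DMT1)), , drop = FALSE] * shift_mm
  ffc <- project_point_onto_line(m$DMT2, point, dir)
  out <- list(MRA_point = .v3_shape(point, markers$DMT1),
              MRA_dir = .v3_shape(dir, markers$DMT1),
              FFC = .v3_shape(ffc, markers$DMT1))
  out
}

#' All joint centers and axes of the foot model
#'
#' Convenience wrapper computing KJC, AJC, KJA, HRC, MFJC, MRA and FFC for a
#' marker set. For left feet the markers are mirrored across a vertical plane
#' first and all outputs are returned in those analysis coordinates (set
#' `mirror_back = TRUE` to report points in the original lab frame).
#'
#' @param markers Named list of marker positions (14 construction markers).
#' @param side `"R"` or `"L"`.
#' @param vertical Lab vertical direction.
#' @param mirror_back Mirror left-foot results back to original lab
#'   coordinates (directions are mirrored too; default `FALSE` because the
#'   segment frames are built in analysis coordinates).
#' @return List with `KJC`, `AJC`, `KJA_dir`, `HRC`, `MFJC`, `MRA_point`,
#'   `MRA_dir`, `FFC`, plus `side`.
#' @export
hffm_joints <- function(markers, side = "R", vertical = c(0, 0, 1),
                        mirror_back = FALSE) {
  side <- match.arg(side, c("R", "L"))
  can <- .canonical_markers(markers, side, vertical)
  prim <- compute_primary_centers(can)
  hrc <- compute_hrc(can, side = "R")
  mfjc <- compute_mfjc(can, side = "R")
  mra <- compute_mra_ffc(can, vertical = vertical)
  j <- list(KJC = prim$KJC, AJC = prim$AJC, KJA_dir = prim$KJA_dir,
            HRC = hrc, MFJC = mfjc,
            MRA_point = mra$MRA_point, MRA_dir = mra$MRA_dir, FFC = mra$FFC,
            side = side)
  if (side == "L" && mirror_back) {
    pts <- c("KJC", "AJC", "HRC", "MFJC", "MRA_point", "FFC",
             "KJA_dir", "MRA_dir")
    j[pts] <- mirror_markers(j[pts], vertical)
  }
  j
}

# ---- segment coordinate systems ----------------------------------------------

.check_separation <- function(u, w, what, min_deg = 1) {
  # u, w unit vectors; error when within min_deg of (anti)parallel
  if (any(v_norm(v_cross(u, w)) < sin(.rad(min_deg))))
    stop("degenerate segment frame: construction vectors of the ", what,
         " within ", min_deg, " degree(s) of parallel", call. = FALSE)
}

#' Shank segment frame
#'
#' Origin at the knee joint center; z along KJC to AJC (pointing distally),
#' y raw direction along the knee joint axis (toward the lateral epicondyle),
#' x = y x z (anterior), y recomputed as z x x. Expects joints of a
#' right-equivalent (canonical) foot.
#'
#' @param j Joint set from [hffm_joints()].
#' @return A frame (list with `origin`, `x`, `y`, `z`).
#' @export
build_shank_frame <- function(j) {
  kjc <- .as_v3(j$KJC); ajc <- .as_v3(j$AJC)
  z <- v_unit(ajc - kjc, what = "shank long axis (KJC = AJC?)")
  yr <- .as_v3(j$KJA_dir)
  yr <- .v3_recycle(yr, z)[[1L]]
  .check_separation(yr, z, "shank")
  x <- v_unit(v_cross(yr, z), what = "shank x")
  .frame(kjc, x, v_cross(z, x), z)
}

#' Hindfoot segment frame
#'
#' Origin at the heel rotation center; x from HRC to MFJC (anterior),
#' y = x cross (HRC to AJC), z = x cross y. With the ankle center above the
#' HRC-MFJC line this yields z pointing distally, matching the shank frame in
#' a neutral posture.
#'
#' @inheritParams build_shank_frame
#' @export
build_hindfoot_frame <- function(j) {
  hrc <- .as_v3(j$HRC); mfjc <- .as_v3(j$MFJC); ajc <- .as_v3(j$AJC)
  x <- v_unit(mfjc - hrc, what = "hindfoot long axis (HRC = MFJC?)")
  up <- v_unit(ajc - hrc, what = "HRC to AJC")
  .check_separation(x, up, "hindfoot")
  y <- v_unit(v_cross(x, up), what = "hindfoot y")
  .frame(hrc, x, y, v_cross(x, y))
}

#' Forefoot segment frame
#'
#' Origin at the midfoot joint center; x from MFJC to FFC (anterior),
#' z = MRA direction cross x (pointing distally for a canonical foot),
#' y = z cross x.
#'
#' @inheritParams build_shank_frame
#' @export
build_forefoot_frame <- function(j) {
  mfjc <- .as_v3(j$MFJC); ffc <- .as_v3(j$FFC)
  x <- v_unit(ffc - mfjc, what = "forefoot long axis (MFJC = FFC?)")
  d <- .v3_recycle(.as_v3(j$MRA_dir), x)[[1L]]
  .check_separation(x, d, "forefoot")
  z <- v_unit(v_cross(d, x), what = "forefoot z")
  .frame(mfjc, x, v_cross(z, x), z)
}

#' Hallux axis
#'
#' Unit direction from the forefoot center to the hallux marker; the hallux
#' is not a full 3D segment since it carries a single marker.
#'
#' @param markers Named list with HLX.
#' @param j Joint set from [hffm_joints()] (provides FFC).
#' @return Unit vector(s), n x 3 or length 3.
#' @export
build_hallux_axis <- function(markers, j) {
  m <- .get_markers(markers, "HLX")
  p <- .v3_recycle(m$HLX, .as_v3(j$FFC))
  d <- p[[1L]] - p[[2L]]
  if (any(v_norm(d) <= 1e-6))
    stop("degenerate geometry: HLX coincides with FFC", call. = FALSE)
  .v3_shape(v_unit(d, what = "hallux axis"), markers$HLX)
}

#' Segment poses of the four-segment foot model
#'
#' Computes joint parameters and the shank, hindfoot and forefoot coordinate
#' systems plus the hallux axis for one marker set (single frame or whole
#' trajectory). Left feet are mirrored into right-equivalent analysis
#' coordinates first; all returned frames live in that space.
#'
#' @inheritParams hffm_joints
#' @return List with frames `shank`, `hindfoot`, `forefoot`, matrix
#'   `hallux_dir`, the `joints` list, and `side`.
#' @export
hffm_segments <- function(markers, side = "R", vertical = c(0, 0, 1)) {
  side <- match.arg(side, c("R", "L"))
  can <- .canonical_markers(markers, side, vertical)
  j <- hffm_joints(can, side = "R", vertical = vertical)
  # the hallux is optional: a missing HLX marker nulls only its channels
  hal <- if ("HLX" %in% names(can)) .as_v3(build_hallux_axis(can, j)) else NULL
  list(shank = build_shank_frame(j),
       hindfoot = build_hindfoot_frame(j),
       forefoot = build_forefoot_frame(j),
       hallux_dir = hal,
       joints = j, side = side)
}
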