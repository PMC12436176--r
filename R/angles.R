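# Cardan XYZ angles between a proximal and a distal segment frame, evaluated
# in the permuted basis X' = mediolateral (segment y), Y' = anterior (segment
# x), Z' = vertical (segment -z), so that the intrinsic X-Y-Z sequence reads
# sagittal / frontal / transverse and dorsiflexion, varus/supination and
# internal rotation/adduction all come out positive. The permutation matrix
# Q = [e2, e1, -e3] is proper (det +1); angles are decomposed from
# R' = t(Q) %*% (t(Rp) %*% Rd) %*% Q, whose entries are row-wise dot products
# of the frame axes, so the whole trajectory is vectorized.
.cardan_channels <- function(p, d) {
  r13 <- -v_dot(p$y, d$z)               # sin(frontal)
  alpha <- atan2(v_dot(p$x, d$z), v_dot(p$z, d$z))
  beta <- asin(pmin(1, pmax(-1, r13)))
  gamma <- atan2(-v_dot(p$y, d$x), v_dot(p$y, d$y))
  cbind(.deg(alpha), .deg(beta), .deg(gamma))
}

#' Compute the 15 angle channels for a marker set
#'
#' Evaluates the full angle set for one time sample or a whole trajectory:
#' nine rigid-segment Euler-Cardan channels (hindfoot/shank,
#' forefoot/hindfoot, forefoot/shank in the sagittal-frontal-transverse
#' sequence), hallux flexion and abduction (projected angles of the hallux
#' axis in the forefoot frame), and the phenomenological channels: medial
#' longitudinal arch (apex angle of MCL-NAV-DMT1), medial arch inclination
#' (sagittal inclination of MCL to DMT1 against the horizontal), metatarsal
#' I-V splay (first vs fifth metatarsal direction projected onto the
#' horizontal plane) and subtalar eversion (calcaneal vs malleolar
#' mediolateral line in the frontal plane of the foot).
#'
#' Sign conventions (both sides, after left-foot mirroring): dorsiflexion,
#' varus/supination/inversion, internal rotation and adduction positive.
#' Missing markers set only the affected channels to `NA`.
#'
#' @param markers Named list of marker positions (length-3 vectors or
#'   n x 3 matrices).
#' @param side `"R"` or `"L"`.
#' @param vertical Lab vertical direction.
#' @return An n x 15 matrix (class `hffm_angles`) with columns
#'   [hffm_angle_names], in degrees.
#' @export
compute_angles <- function(markers, side = "R", vertical = c(0, 0, 1)) {
  side <- match.arg(side, c("R", "L"))
  can <- .canonical_markers(markers, side, vertical)
  n <- max(vapply(can, function(p) nrow(.as_v3(p)), 1L))
  out <- matrix(NA_real_, n, length(hffm_angle_names),
                dimnames = list(NULL, hffm_angle_names))
  v <- v_unit(.as_v3(vertical), what = "vertical axis")[rep(1L, n), , drop = FALSE]

  seg <- tryCatch(hffm_segments(can, side = "R", vertical = vertical),
                  error = function(e) e)
  if (!inherits(seg, "error")) {
    out[, 1:3] <- .cardan_channels(seg$shank, seg$hindfoot)
    out[, 4:6] <- .cardan_channels(seg$hindfoot, seg$forefoot)
    out[, 7:9] <- .cardan_channels(seg$shank, seg$forefoot)
    if (!is.null(seg$hallux_dir)) {
      h <- seg$hallux_dir
      ff <- seg$forefoot
      hx <- v_dot(h, ff$x); hy <- v_dot(h, ff$y); hz <- v_dot(h, ff$z)
      out[, "hallux_flexion"] <- .deg(atan2(-hz, hx))
      out[, "hallux_abduction"] <- .deg(atan2(-hy, hx))
    }
  }

  m <- tryCatch(.get_markers(can, c("MCL", "NAV", "DMT1")),
                error = function(e) NULL)
  if (!is.null(m))
    out[, "medial_arch"] <- apex_angle(m$MCL, m$NAV, m$DMT1)

  lf <- tryCatch(local_foot_frame(can, side = "R", vertical = vertical),
                 error = function(e) NULL)
  if (!is.null(lf)) {
    m <- tryCatch(.get_markers(can, c("MCL", "DMT1")), error = function(e) NULL)
    if (!is.null(m)) {
      ray <- m$DMT1 - m$MCL
      out[, "medial_arch_inclination"] <-
        .deg(atan2(v_dot(ray, v), v_dot(ray, lf$x)))
    }
    m <- tryCatch(.get_markers(can, c("PMT1", "DMT1", "PMT5", "DMT5")),
                  error = function(e) NULL)
    if (!is.null(m))
      out[, "metatarsal_I_V"] <- signed_projected_angle(
        m$DMT5 - m$PMT5, m$DMT1 - m$PMT1, v)
    m <- tryCatch(.get_markers(can, c("LML", "MML", "LCL", "MCL")),
                  error = function(e) NULL)
    if (!is.null(m))
      out[, "subtalar_eversion"] <- signed_projected_angle(
        m$LML - m$MML, m$LCL - m$MCL, -lf$x)
  }
  structure(out, class = c("hffm_angles", class(out)))
}

#' Angle set for a single marker frame
#'
#' Single-sample convenience wrapper around [compute_angles()].
#'
#' @inheritParams compute_angles
#' @return Named numeric vector of the 15 angles in degrees.
#' @export
compute_angles_frame <- function(markers, side = "R", vertical = c(0, 0, 1)) {
  a <- compute_angles(markers, side = side, vertical = vertical)
  if (nrow(a) != 1L)
    stop("'markers' contains more than one time sample; use compute_angles()",
         call. = FALSE)
  a[1L, ]
}
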