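# ---- internal vector helpers -------------------------------------------------
# All geometric primitives accept either a length-3 numeric vector or an
# n x 3 matrix (rows = time samples) and return a value of matching shape,
# so the whole kinematic pipeline can run vectorized over a trajectory.

.as_v3 <- function(x, arg = deparse(substitute(x))) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L)
      stop(sprintf("'%s' must have 3 columns, got %d", arg, ncol(x)),
           call. = FALSE)
    return(x)
  }
  if (!is.numeric(x) || length(x) != 3L)
    stop(sprintf("'%s' must be a length-3 numeric vector or an n x 3 matrix", arg),
         call. = FALSE)
  matrix(x, nrow = 1L)
}

.v3_shape <- function(out, like) {
  if (!is.matrix(like) && nrow(out) == 1L) drop(out) else out
}

# recycle a 1-row matrix to n rows so pairwise row ops broadcast
.v3_recycle <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a, b))
  if (na == 1L) return(list(a[rep(1L, nb), , drop = FALSE], b))
  if (nb == 1L) return(list(a, b[rep(1L, na), , drop = FALSE]))
  stop("incompatible numbers of rows: ", na, " vs ", nb, call. = FALSE)
}

.check_finite <- function(x, arg) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite coordinates in '%s'", arg), call. = FALSE)
  invisible(x)
}

#' Row-wise vector algebra on n x 3 matrices
#'
#' Small building blocks used throughout the kinematic pipeline: dot and
#' cross products, Euclidean norms and normalization, each applied row by
#' row so that whole trajectories are processed in one call.
#'
#' @param a,b n x 3 matrices (or 1 x 3 for a single vector).
#' @param tol Norm below which normalization is considered degenerate.
#' @param what Label used in the error message for degenerate input.
#' @return `v_dot`/`v_norm`: numeric vector of length n; `v_cross`/`v_unit`:
#'   n x 3 matrix.
#' @name vector-ops
NULL

#' @rdname vector-ops
#' @export
v_dot <- function(a, b) rowSums(a * b)

#' @rdname vector-ops
#' @export
v_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' @rdname vector-ops
#' @export
v_norm <- function(a) sqrt(rowSums(a * a))

#' @rdname vector-ops
#' @export
v_unit <- function(a, tol = 1e-9, what = "vector") {
  n <- v_norm(a)
  if (any(n <= tol))
    stop(sprintf("degenerate geometry: cannot normalize %s (norm <= %g)", what, tol),
         call. = FALSE)
  a / n
}

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# ---- exported primitives -----------------------------------------------------

#' Midpoint of two 3D points
#'
#' Component-wise mean of two points, e.g. the knee joint center from the
#' femoral epicondyle markers or the ankle joint center from the malleolar
#' markers.
#'
#' @param a,b Length-3 numeric vectors (mm) or n x 3 matrices of positions.
#' @return Point(s) of the same shape as the inputs.
#' @export
#' @examples
#' midpoint(c(0, 0, 0), c(2, 4, 6))
midpoint <- function(a, b) {
  am <- .as_v3(a); bm <- .as_v3(b)
  .check_finite(am, "a"); .check_finite(bm, "b")
  p <- .v3_recycle(am, bm)
  .v3_shape((p[[1L]] + p[[2L]]) / 2, if (is.matrix(a)) a else b)
}

#' Compose a rotation matrix from Cardan angles (intrinsic X-Y-Z)
#'
#' Builds `R = Rx(alpha) %*% Ry(beta) %*% Rz(gamma)` from right-handed
#' elementary rotations, the matrix form of the sagittal-frontal-transverse
#' Cardan sequence used for all inter-segment joint angles.
#'
#' @param angles Numeric length-3, `c(alpha, beta, gamma)` in degrees
#'   (sagittal, frontal, transverse).
#' @return A 3 x 3 rotation matrix.
#' @seealso [euler_xyz_decompose()]
#' @export
euler_xyz_compose <- function(angles) {
  if (length(angles) != 3L || !all(is.finite(angles)))
    stop("'angles' must be 3 finite Cardan angles in degrees", call. = FALSE)
  a <- .rad(angles[[1L]]); b <- .rad(angles[[2L]]); g <- .rad(angles[[3L]])
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cg <- cos(g); sg <- sin(g)
  matrix(c(cb * cg,                -cb * sg,                 sb,
           ca * sg + sa * sb * cg,  ca * cg - sa * sb * sg, -sa * cb,
           sa * sg - ca * sb * cg,  sa * cg + ca * sb * sg,  ca * cb),
         nrow = 3L, byrow = TRUE)
}

#' Decompose a rotation matrix into Cardan angles (intrinsic X-Y-Z)
#'
#' Inverse of [euler_xyz_compose()]. Near gimbal lock (|beta| >= 89 degrees)
#' the sagittal and transverse rotations are no longer separable; the
#' transverse angle is then set to zero, the sagittal angle carries the
#' combined rotation, and a warning is emitted.
#'
#' @param R A 3 x 3 rotation matrix (orthonormal, det +1).
#' @param check Verify orthonormality of `R` (default `TRUE`).
#' @return Named numeric vector `c(alpha, beta, gamma)` in degrees.
#' @export
euler_xyz_decompose <- function(R, check = TRUE) {
  if (!is.matrix(R) || any(dim(R) != 3L))
    stop("'R' must be a 3 x 3 matrix", call. = FALSE)
  if (check) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop("'R' is not a proper rotation matrix", call. = FALSE)
  }
  sb <- min(1, max(-1, R[1L, 3L]))
  beta <- asin(sb)
  if (abs(beta) >= .rad(89)) {
    warning("Cardan decomposition near gimbal lock (|beta| >= 89 deg); ",
            "transverse angle set to 0", call. = FALSE)
    alpha <- atan2(sign(sb) * R[2L, 1L], R[2L, 2L])
    gamma <- 0
  } else {
    alpha <- atan2(-R[2L, 3L], R[3L, 3L])
    gamma <- atan2(-R[1L, 2L], R[1L, 1L])
  }
  c(alpha = .deg(alpha), beta = .deg(beta), gamma = .deg(gamma))
}

#' Apex angle at a vertex of a marker triangle
#'
#' Angle (degrees, in `[0, 180]`) subtended at `apex` by the segments to `a`
#' and `c`. With the medial calcaneus, navicular and first metatarsal head
#' markers this is the medial longitudinal arch angle: 180 degrees for a flat
#' collinear arrangement, smaller for a higher (more cavus) arch.
#'
#' @param a,apex,c Length-3 vectors (mm) or n x 3 matrices.
#' @return Angle(s) in degrees.
#' @export
apex_angle <- function(a, apex, c) {
  am <- .as_v3(a); pm <- .as_v3(apex); cm <- .as_v3(c)
  .check_finite(am, "a"); .check_finite(pm, "apex"); .check_finite(cm, "c")
  p1 <- .v3_recycle(am, pm); p2 <- .v3_recycle(cm, pm)
  u <- v_unit(p1[[1L]] - p1[[2L]], tol = 1e-6, what = "limb a - apex")
  w <- v_unit(p2[[1L]] - p2[[2L]], tol = 1e-6, what = "limb c - apex")
  ang <- .deg(acos(pmin(1, pmax(-1, v_dot(u, w)))))
  if (is.matrix(a) || is.matrix(apex) || is.matrix(c)) ang else ang[[1L]]
}

#' Orthogonal projection of a point onto a line
#'
#' @param p Point(s) to project, length-3 vector or n x 3 matrix (mm).
#' @param line_point A point on the line.
#' @param line_dir Direction of the line (need not be unit length).
#' @return The foot of the perpendicular from `p`, same shape as `p`.
#' @export
project_point_onto_line <- function(p, line_point, line_dir) {
  pm <- .as_v3(p); lp <- .as_v3(line_point); ld <- .as_v3(line_dir)
  .check_finite(pm, "p"); .check_finite(lp, "line_point"); .check_finite(ld, "line_dir")
  d <- v_unit(ld, what = "line direction")
  pr <- .v3_recycle(pm, lp); d <- .v3_recycle(pr[[1L]], d)[[2L]]
  rel <- pr[[1L]] - pr[[2L]]
  .v3_shape(pr[[2L]] + d * v_dot(rel, d), p)
}

#' Signed angle between two vectors projected onto a plane
#'
#' Projects `u` and `v` onto the plane with normal `plane_normal` and returns
#' the angle from the projection of `u` to the projection of `v`, signed by
#' the right-hand rule about the normal, in `(-180, 180]`. Antisymmetric in
#' `u` and `v`.
#'
#' @param u,v Vectors, length-3 or n x 3 matrices.
#' @param plane_normal Normal of the projection plane.
#' @return Signed angle(s) in degrees.
#' @export
signed_projected_angle <- function(u, v, plane_normal) {
  um <- .as_v3(u); vm <- .as_v3(v); nm <- .as_v3(plane_normal)
  .check_finite(um, "u"); .check_finite(vm, "v"); .check_finite(nm, "plane_normal")
  n <- v_unit(nm, what = "plane normal")
  p <- .v3_recycle(um, vm)
  um <- p[[1L]]; vm <- p[[2L]]
  n <- .v3_recycle(um, n)[[2L]]
  pu <- um - n * v_dot(um, n)
  pv <- vm - n * v_dot(vm, n)
  if (any(v_norm(pu) <= 1e-9) || any(v_norm(pv) <= 1e-9))
    stop("degenerate geometry: input projects to (near) zero in the plane",
         call. = FALSE)
  ang <- .deg(atan2(v_dot(v_cross(pu, pv), n), v_dot(pu, pv)))
  ang[ang <= -180] <- 180
  if (is.matrix(u) || is.matrix(v)) ang else ang[[1L]]
}
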