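#' Gait event container
#'
#' @param ic Integer sample indices of initial contacts (strictly increasing).
#' @param to Integer sample indices of toe-offs, interleaved so that
#'   `ic[k] < to[k] < ic[k+1]`.
#' @param side Foot side.
#' @return Object of class `gait_events`.
#' @export
gait_events <- function(ic, to = integer(0), side = "R") {
  ic <- as.integer(ic); to <- as.integer(to)
  if (length(ic) && any(diff(ic) <= 0))
    stop("initial contacts must be strictly increasing", call. = FALSE)
  if (length(to)) {
    if (any(diff(to) <= 0))
      stop("toe-offs must be strictly increasing", call. = FALSE)
    for (k in seq_along(to)) {
      if (k > length(ic) || to[k] <= ic[k] ||
          (k < length(ic) && to[k] >= ic[k + 1L]))
        stop("events must satisfy ic[k] < to[k] < ic[k+1]", call. = FALSE)
    }
  }
  structure(list(ic = ic, to = to, side = side), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events (%s): IC at %s; TO at %s\n", x$side,
              paste(x$ic, collapse = ", "),
              if (length(x$to)) paste(x$to, collapse = ", ") else "-"))
  invisible(x)
}

# indices of local minima of y (including boundary minima) lying close to
# the global minimum, separated by at least min_sep samples; the height
# gate is a fraction of the spread between the median and the minimum, which
# rejects shallow mid-swing dips while tolerating marker noise
.local_minima <- function(y, min_sep, keep_frac = 0.25) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) > 0) + 1L
  if (y[1L] < y[2L]) cand <- c(1L, cand)
  if (y[n] < y[n - 1L]) cand <- c(cand, n)
  thr <- min(y) + keep_frac * (stats::median(y) - min(y))
  cand <- cand[y[cand] <= thr]
  if (!length(cand)) return(integer(0))
  # greedy: keep the lowest, drop neighbours closer than min_sep
  cand <- cand[order(y[cand])]
  keep <- integer(0)
  for (i in cand) if (!length(keep) || min(abs(keep - i)) >= min_sep)
    keep <- c(keep, i)
  sort(keep)
}

#' Detect gait events from marker coordinates
#'
#' Initial contact is taken at local minima of the vertical position of the
#' dorsal heel marker (CCL); toe-off at the onset of forward motion of the
#' second metatarsal head marker (DMT2) within each cycle (first sustained
#' rise of its forward velocity above `to_threshold` of the cycle's peak,
#' sustained for 3 samples).
#' Events already attached to the trajectory override detection.
#'
#' @param traj An [hffm_traj()] containing at least CCL and DMT2.
#' @param min_cycle_s Minimum credible cycle duration in seconds.
#' @param to_threshold Fraction of peak forward velocity treated as movement
#'   onset (default 0.05).
#' @return A [gait_events()] object.
#' @export
detect_gait_events <- function(traj, min_cycle_s = 0.5, to_threshold = 0.02) {
  stopifnot(inherits(traj, "hffm_traj"))
  if (!is.null(traj$events)) return(traj$events)
  m <- .get_markers(traj$markers, c("CCL", "DMT2"))
  v <- drop(v_unit(.as_v3(traj$vertical), what = "vertical axis"))
  heel <- drop(m$CCL %*% v)
  if (max(heel) - min(heel) < 1) # < 1 mm of heel excursion: standing trial
    stop("no detectable gait cycle: heel height is (near) constant",
         call. = FALSE)
  ic <- .local_minima(heel, min_sep = ceiling(min_cycle_s * traj$rate))
  if (length(ic) < 2L)
    stop("no detectable gait cycle: need at least two initial contacts",
         call. = FALSE)

  # forward direction: net horizontal displacement of DMT2
  disp <- m$DMT2[nrow(m$DMT2), ] - m$DMT2[1L, ]
  disp <- disp - sum(disp * v) * v
  to <- integer(0)
  if (sqrt(sum(disp^2)) > 50) { # needs > 5 cm of progression to define TO
    fw <- disp / sqrt(sum(disp^2))
    vel <- c(0, diff(drop(m$DMT2 %*% fw))) * traj$rate
    for (k in seq_len(length(ic) - 1L)) {
      i0 <- ic[k]; i1 <- ic[k + 1L]
      seg <- vel[i0:i1]
      thr <- to_threshold * max(seg)
      # earliest sample (past 15% of the cycle) with 3 consecutive samples
      # above threshold
      start <- i0 + ceiling(0.15 * (i1 - i0))
      hit <- NA_integer_
      for (j in start:(i1 - 3L)) {
        if (all(vel[j:(j + 2L)] > thr)) { hit <- j; break }
      }
      # vel[j] spans (j-1, j]; movement onset is the sample before
      if (!is.na(hit) && hit - 1L > i0 && hit - 1L < i1) to <- c(to, hit - 1L)
    }
  }
  gait_events(ic = ic, to = to, side = traj$side)
}
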