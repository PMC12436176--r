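#' Normalize a time series to the gait cycle
#'
#' Resamples each complete initial-contact-to-initial-contact cycle of a
#' series to 101 points (0 to 100% of the cycle) by cubic interpolation and
#' averages across cycles.
#'
#' @param x Numeric vector, one value per trajectory frame (e.g. one angle
#'   channel).
#' @param events A [gait_events()] object with at least two initial contacts.
#' @param angle_name Optional channel name stored with the curve.
#' @param n_points Number of points per normalized cycle (101 = every 1%).
#' @return A `gait_curve`: list with `values` (cycle mean), `sd` (per-point SD
#'   across cycles), `n_cycles`, `cycles` (matrix of individual cycles) and
#'   `angle_name`.
#' @export
normalize_to_cycle <- function(x, events, angle_name = NULL, n_points = 101L) {
  ic <- events$ic
  if (length(ic) < 2L)
    stop("need at least one complete initial-contact to initial-contact cycle",
         call. = FALSE)
  phase_out <- seq(0, 1, length.out = n_points)
  rows <- list()
  for (k in seq_len(length(ic) - 1L)) {
    idx <- ic[k]:ic[k + 1L]
    y <- x[idx]
    if (any(!is.finite(y))) {
      message(sprintf("cycle %d skipped: non-finite samples", k))
      next
    }
    phase <- (idx - idx[1L]) / (idx[length(idx)] - idx[1L])
    rows[[length(rows) + 1L]] <- stats::spline(phase, y, xout = phase_out)$y
  }
  if (!length(rows))
    stop("no complete usable gait cycle", call. = FALSE)
  cyc <- do.call(rbind, rows)
  structure(list(angle_name = angle_name,
                 values = colMeans(cyc),
                 sd = if (nrow(cyc) > 1L) apply(cyc, 2L, stats::sd) else
                   rep(0, n_points),
                 n_cycles = nrow(cyc),
                 cycles = cyc),
            class = "gait_curve")
}

#' @export
print.gait_curve <- function(x, ...) {
  cat(sprintf("Gait cycle curve%s: %d points, %d cycle(s); mean %.1f, range [%.1f, %.1f] deg\n",
              if (!is.null(x$angle_name)) paste0(" '", x$angle_name, "'") else "",
              length(x$values), x$n_cycles, mean(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Normalize all angle channels of a trajectory
#'
#' @param angles An angle matrix from [compute_angles()].
#' @param events A [gait_events()] object.
#' @param n_points Points per cycle.
#' @return Named list of `gait_curve` objects (class `gait_curves`), one per
#'   channel with any finite data.
#' @export
normalize_angles <- function(angles, events, n_points = 101L) {
  out <- list()
  for (ch in colnames(angles)) {
    if (all(!is.finite(angles[, ch]))) next
    out[[ch]] <- normalize_to_cycle(angles[, ch], events, angle_name = ch,
                                    n_points = n_points)
  }
  structure(out, class = "gait_curves")
}

#' Mean, maximum and range of motion of a gait curve
#'
#' @param curve A `gait_curve` or a plain numeric vector of cycle-normalized
#'   values.
#' @return Named list with `angle_name`, `mean`, `max` and `rom`
#'   (max minus min), in degrees.
#' @export
summarize_curve <- function(curve) {
  v <- if (inherits(curve, "gait_curve")) curve$values else as.numeric(curve)
  list(angle_name = if (inherits(curve, "gait_curve")) curve$angle_name else NULL,
       mean = mean(v), max = max(v), rom = max(v) - min(v))
}

#' Summary table for one foot
#'
#' @param curves A `gait_curves` list from [normalize_angles()].
#' @return `data.frame` with columns `angle`, `mean`, `max`, `rom` (degrees).
#' @export
summarize_curves <- function(curves) {
  rows <- lapply(names(curves), function(ch) {
    s <- summarize_curve(curves[[ch]])
    data.frame(angle = ch, mean = s$mean, max = s$max, rom = s$rom)
  })
  do.call(rbind, rows)
}

#' Group summary table (mean +/- SD across feet)
#'
#' Aggregates per-foot summaries into a per-group table: each foot
#' contributes one value per angle and outcome (its cycle-averaged curve
#' summarized), and groups are described by the across-feet mean and SD.
#'
#' @param summaries `data.frame` with columns `group`, `foot`, `angle`,
#'   `mean`, `max`, `rom` (one row per foot per angle), e.g. stacked results
#'   of [summarize_curves()].
#' @return `data.frame` with one row per group x angle and columns
#'   `mean`/`mean_sd`/`max`/`max_sd`/`rom`/`rom_sd`.
#' @export
group_summary_table <- function(summaries) {
  stopifnot(all(c("group", "foot", "angle", "mean", "max", "rom") %in%
                  names(summaries)))
  agg <- function(v) c(mean(v), stats::sd(v))
  out <- list()
  for (g in unique(summaries$group)) {
    for (a in unique(summaries$angle)) {
      s <- summaries[summaries$group == g & summaries$angle == a, ]
      if (!nrow(s)) next
      m <- agg(s$mean); mx <- agg(s$max); r <- agg(s$rom)
      out[[length(out) + 1L]] <- data.frame(
        group = g, angle = a, n_feet = nrow(s),
        mean = m[1L], mean_sd = m[2L], max = mx[1L], max_sd = mx[2L],
        rom = r[1L], rom_sd = r[2L])
    }
  }
  do.call(rbind, out)
}

#' Equinovarus classification from early hindfoot/shank flexion slope
#'
#' A foot is classified equinovarus (EV) when the least-squares slope of the
#' hindfoot/shank flexion curve over the first `window` percent of the gait
#' cycle is positive: flexion rising right after initial contact indicates
#' forefoot-first contact, i.e. a functional equinus. Other feet are
#' `non-EV`.
#'
#' @param curve A `gait_curve` of hindfoot/shank flexion starting at initial
#'   contact (0% cycle).
#' @param window Slope window in percent of the gait cycle (default 5).
#' @return List with `type` (`"EV"` or `"non-EV"`) and the fitted `slope`
#'   (degrees per percent cycle).
#' @export
classify_foot_type <- function(curve, window = 5) {
  v <- if (inherits(curve, "gait_curve")) curve$values else as.numeric(curve)
  n_pts <- length(v)
  idx <- seq_len(floor(window * (n_pts - 1L) / 100) + 1L)
  if (length(idx) < 2L)
    stop("classification window must span at least 2 points", call. = FALSE)
  phase <- (idx - 1L) * 100 / (n_pts - 1L)
  slope <- stats::cov(phase, v[idx]) / stats::var(phase)
  list(type = if (slope > 0) "EV" else "non-EV", slope = slope)
}
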