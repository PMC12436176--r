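#' Full analysis of one walking trial
#'
#' Runs the standard pipeline on a labeled marker trajectory: trajectory
#' smoothing, per-frame angle computation, gait event detection (attached
#' events take precedence), gait-cycle normalization, per-foot summary
#' statistics and the equinovarus classification from the early
#' hindfoot/shank flexion slope.
#'
#' @param traj An [hffm_traj()].
#' @param smooth Smooth trajectories first (default `TRUE`).
#' @param cutoff_hz Smoothing cutoff in Hz.
#' @param max_gap Longest tolerated marker gap in samples.
#' @param classify_window Classification slope window in percent of cycle.
#' @return List of class `hffm_analysis` with `angles` (n x 15), `events`,
#'   `curves` (101-point gait curves), `summary` (per-angle mean/max/rom),
#'   `classification` (list with `type` and `slope`), and `side`.
#' @export
analyze_trial <- function(traj, smooth = TRUE, cutoff_hz = 4.5, max_gap = 10,
                          classify_window = 5) {
  stopifnot(inherits(traj, "hffm_traj"))
  if (smooth) traj <- smooth_trajectories(traj, cutoff_hz = cutoff_hz,
                                          max_gap = max_gap)
  angles <- compute_angles(traj$markers, side = traj$side,
                           vertical = traj$vertical)
  events <- detect_gait_events(traj)
  curves <- normalize_angles(angles, events)
  summary <- summarize_curves(curves)
  classification <- if ("hindfoot_shank_flexion" %in% names(curves))
    classify_foot_type(curves$hindfoot_shank_flexion, window = classify_window)
  else NULL
  structure(list(angles = angles, events = events, curves = curves,
                 summary = summary, classification = classification,
                 side = traj$side),
            class = "hffm_analysis")
}

#' @export
print.hffm_analysis <- function(x, ...) {
  cat(sprintf("Foot model analysis (side %s): %d frames, %d gait cycle(s)\n",
              x$side, nrow(x$angles), length(x$events$ic) - 1L))
  if (!is.null(x$classification))
    cat(sprintf("Classification: %s (early flexion slope %.3f deg/%%)\n",
                x$classification$type, x$classification$slope))
  print(x$summary, digits = 3)
  invisible(x)
}
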