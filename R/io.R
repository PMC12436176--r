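# ---- trajectory CSV dialect --------------------------------------------------
# wide table: time,<LABEL>_x,<LABEL>_y,<LABEL>_z,... positions in mm

#' Write a marker trajectory to CSV
#'
#' @param traj An [hffm_traj()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(traj, path) {
  stopifnot(inherits(traj, "hffm_traj"))
  cols <- list(time = traj$time)
  for (lab in names(traj$markers)) {
    p <- traj$markers[[lab]]
    cols[[paste0(lab, "_x")]] <- p[, 1L]
    cols[[paste0(lab, "_y")]] <- p[, 2L]
    cols[[paste0(lab, "_z")]] <- p[, 3L]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' Read a marker trajectory
#'
#' Reads the wide CSV trajectory dialect
#' (`time,<LABEL>_x,<LABEL>_y,<LABEL>_z,...`). Positions are interpreted in
#' the declared `units` and converted to mm. C3D files are not supported by
#' this implementation; convert to the CSV dialect first.
#'
#' @param path Input file.
#' @param side Foot side `"R"` or `"L"`.
#' @param label_map Optional named character vector renaming file labels to
#'   model labels (`c(model_label = "file_label", ...)`).
#' @param units `"mm"` (default) or `"m"`.
#' @param rate Optional sampling rate; inferred from the time column when
#'   absent.
#' @param vertical Lab vertical direction.
#' @param events Optional [gait_events()] to attach.
#' @return An [hffm_traj()].
#' @export
read_trial <- function(path, side = "R", label_map = NULL, units = "mm",
                       rate = NULL, vertical = c(0, 0, 1), events = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (tolower(tools::file_ext(path)) == "c3d")
    stop("C3D input is not supported; export the trial to the CSV dialect ",
         "(time,<LABEL>_x,<LABEL>_y,<LABEL>_z,...)", call. = FALSE)
  units <- match.arg(units, c("mm", "m"))
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(d))
    stop("trajectory CSV must contain a 'time' column", call. = FALSE)
  cn <- setdiff(names(d), "time")
  base <- unique(sub("_[xyz]$", "", cn))
  complete <- base[vapply(base, function(b)
    all(paste0(b, c("_x", "_y", "_z")) %in% cn), TRUE)]
  scale <- if (units == "m") 1000 else 1
  markers <- lapply(complete, function(b)
    as.matrix(d[, paste0(b, c("_x", "_y", "_z"))]) * scale)
  names(markers) <- complete
  if (!is.null(label_map)) {
    unresolved <- setdiff(unname(label_map), complete)
    if (length(unresolved))
      stop("label map refers to columns not in the file: ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    mapped <- markers[unname(label_map)]
    names(mapped) <- names(label_map)
    markers <- c(mapped, markers[setdiff(complete, unname(label_map))])
  }
  if (is.null(rate)) {
    dt <- diff(d$time)
    if (length(dt) < 1L || any(dt <= 0) ||
        (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
      stop("non-uniform or invalid time base; pass 'rate' explicitly",
           call. = FALSE)
    rate <- 1 / stats::median(dt)
  }
  hffm_traj(markers, rate = rate, side = side, time = d$time,
            vertical = vertical, events = events)
}

# ---- curve / summary outputs -------------------------------------------------

#' Write gait-cycle curves to CSV
#'
#' Long format: one row per angle per cycle percent, columns
#' `angle,percent,mean,sd,n_cycles`.
#'
#' @param curves A `gait_curves` list from [normalize_angles()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- lapply(names(curves), function(ch) {
    cv <- curves[[ch]]
    data.frame(angle = ch,
               percent = seq(0, 100, length.out = length(cv$values)),
               mean = cv$values, sd = cv$sd, n_cycles = cv$n_cycles)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read gait-cycle curves written by [write_curves_csv()]
#'
#' @param path Input file.
#' @return A `gait_curves` list.
#' @export
read_curves_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- list()
  for (ch in unique(d$angle)) {
    s <- d[d$angle == ch, ]
    s <- s[order(s$percent), ]
    out[[ch]] <- structure(list(angle_name = ch, values = s$mean, sd = s$sd,
                                n_cycles = s$n_cycles[1L], cycles = NULL),
                           class = "gait_curve")
  }
  structure(out, class = "gait_curves")
}

# ---- run configuration -------------------------------------------------------

#' Run configuration
#'
#' @param side Foot side.
#' @param vertical Lab vertical direction.
#' @param cutoff_hz Smoothing cutoff (Hz).
#' @param max_gap Longest tolerated marker gap (samples).
#' @param classify_window Classification slope window (% cycle).
#' @param seed Seed recorded with every run.
#' @param label_map Optional marker label mapping.
#' @param output_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(side = "R", vertical = c(0, 0, 1), cutoff_hz = 4.5,
                       max_gap = 10, classify_window = 5, seed = 1L,
                       label_map = NULL, output_dir = ".") {
  structure(list(side = side, vertical = vertical, cutoff_hz = cutoff_hz,
                 max_gap = max_gap, classify_window = classify_window,
                 seed = seed, label_map = label_map, output_dir = output_dir),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param cfg A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$label_map)) out$label_map <- as.list(out$label_map)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Input file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  keep <- intersect(names(raw), names(cfg))
  cfg[keep] <- raw[keep]
  if (!is.null(cfg$label_map)) cfg$label_map <- unlist(cfg$label_map)
  cfg$vertical <- as.numeric(cfg$vertical)
  cfg
}
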