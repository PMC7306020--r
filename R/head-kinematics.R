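#' Fetal-head descent trajectory configuration
#'
#' Station-indexed piecewise-linear parameterization of the fetal-head pose
#' (position + orientation) in the birth canal. Stations follow the obstetric
#' convention: centimeters relative to the plane of the ischial spines,
#' negative above and positive below. Coordinate convention: anterior = +x
#' (mm), caudal = +z (mm); rotations in degrees.
#'
#' Linear progression between waypoints is deliberate: homogeneous head
#' progress is the standard simplification in numerical childbirth models,
#' so the module's contract is exact interpolation through the waypoints,
#' not anatomical truth between them.
#'
#' @param presentation `"OP"` (occiput posterior) or `"OA"` (occiput
#'   anterior).
#' @param waypoints Data frame with columns `station_cm`, `anterior_mm`,
#'   `caudal_mm`, `internal_rotation_deg`, `flexion_deg`; stations strictly
#'   increasing, first <= -3 and last >= +8 so the full reported descent
#'   range is covered.
#' @param rotation_complete_station Station (cm) at which internal rotation
#'   must have reached 0 degrees. For OP the default configuration starts at
#'   45 degrees and completes rotation at station +3.
#' @return Object of class `trajectory_config`.
#' @export
trajectory_config <- function(presentation, waypoints,
                              rotation_complete_station = 3) {
  presentation <- match.arg(toupper(presentation), c("OP", "OA"))
  need <- c("station_cm", "anterior_mm", "caudal_mm",
            "internal_rotation_deg", "flexion_deg")
  if (!all(need %in% names(waypoints)))
    stop("waypoints must have columns: ", paste(need, collapse = ", "))
  wp <- as.data.frame(waypoints)[, need]
  if (nrow(wp) < 2L) stop("need at least two waypoints")
  if (any(diff(wp$station_cm) <= 0))
    stop("waypoint stations must be strictly increasing")
  if (wp$station_cm[1] > -3 || wp$station_cm[nrow(wp)] < 8)
    stop("waypoints must cover at least stations -3 to +8")
  if (presentation == "OP") {
    if (wp$internal_rotation_deg[1] != 45)
      stop("OP configurations start with 45 degrees internal rotation")
    at_done <- wp$internal_rotation_deg[wp$station_cm >= rotation_complete_station]
    if (length(at_done) == 0L || any(at_done != 0))
      stop("OP internal rotation must reach 0 at rotation_complete_station and stay 0")
  }
  structure(list(presentation = presentation, waypoints = wp,
                 rotation_complete_station = rotation_complete_station),
            class = "trajectory_config")
}

#' Built-in descent trajectory configurations
#'
#' Loads the packaged default waypoint table for a presentation. The
#' numerically anchored features are: 100.0 mm total anterior displacement
#' over the simulated descent, OP internal rotation from 45 degrees at
#' engagement to 0 degrees at station +3, and 20 degrees of flexion reached
#' at the midpelvis (station 0) waypoint, increasing after the ischial-spine
#' region is passed. Intermediate values are neutral placeholders (the
#' published curves are not tabulated) and the files document this.
#'
#' @param presentation `"OP"` or `"OA"`.
#' @return A [trajectory_config()].
#' @export
default_trajectory <- function(presentation = c("OP", "OA")) {
  presentation <- match.arg(toupper(presentation[1]), c("OP", "OA"))
  path <- system.file("extdata",
                      sprintf("trajectory_%s.json", tolower(presentation)),
                      package = "ogdenlam", mustWork = TRUE)
  read_trajectory_config(path)
}

#' Read/write a trajectory configuration (JSON or YAML)
#'
#' @param path Config file path (`.json`, `.yaml`/`.yml`).
#' @return `read_trajectory_config`: a [trajectory_config()];
#'   `write_trajectory_config`: `path` invisibly.
#' @export
read_trajectory_config <- function(path) {
  obj <- switch(tolower(tools::file_ext(path)),
                json = jsonlite::fromJSON(path),
                yaml = , yml = yaml::read_yaml(path),
                stop("config must be .json or .yaml"))
  trajectory_config(
    presentation = obj$presentation,
    waypoints = as.data.frame(obj$waypoints),
    rotation_complete_station = obj$rotation_complete_station
  )
}

#' @rdname read_trajectory_config
#' @param config A [trajectory_config()].
#' @export
write_trajectory_config <- function(config, path) {
  stopifnot(inherits(config, "trajectory_config"))
  obj <- list(presentation = config$presentation,
              rotation_complete_station = config$rotation_complete_station,
              waypoints = config$waypoints)
  switch(tolower(tools::file_ext(path)),
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                     digits = NA, dataframe = "columns"),
         yaml = , yml = yaml::write_yaml(obj, path),
         stop("config must be .json or .yaml"))
  invisible(path)
}

#' Head pose at a given station
#'
#' Component-wise linear interpolation between the bracketing waypoints;
#' exact at waypoint stations. Requests outside the configured station range
#' raise an error.
#'
#' @param config A [trajectory_config()].
#' @param station Station in cm (scalar).
#' @return Object of class `station_pose`: a one-row data frame with columns
#'   `station_cm`, `anterior_mm`, `caudal_mm`, `internal_rotation_deg`,
#'   `flexion_deg`.
#' @export
pose_at_station <- function(config, station) {
  stopifnot(inherits(config, "trajectory_config"), length(station) == 1L)
  wp <- config$waypoints
  rng <- range(wp$station_cm)
  if (!is.finite(station) || station < rng[1] || station > rng[2])
    stop(sprintf("station %g outside configured range [%g, %g]",
                 station, rng[1], rng[2]))
  pose <- data.frame(station_cm = station)
  for (col in c("anterior_mm", "caudal_mm", "internal_rotation_deg", "flexion_deg"))
    pose[[col]] <- stats::approx(wp$station_cm, wp[[col]], xout = station,
                                 method = "linear", ties = "ordered")$y
  class(pose) <- c("station_pose", "data.frame")
  pose
}

#' Tabulate a trajectory on a regular station grid
#'
#' Poses from the first to the last configured station at the given step,
#' with the final station always included.
#'
#' @param config A [trajectory_config()].
#' @param step Station increment in cm (> 0).
#' @return Data frame of poses, one row per station.
#' @export
trajectory_table <- function(config, step) {
  stopifnot(inherits(config, "trajectory_config"))
  if (!is.finite(step) || step <= 0) stop("'step' must be positive")
  rng <- range(config$waypoints$station_cm)
  stations <- seq(rng[1], rng[2], by = step)
  if (stations[length(stations)] < rng[2]) stations <- c(stations, rng[2])
  out <- do.call(rbind, lapply(stations, function(s) pose_at_station(config, s)))
  rownames(out) <- NULL
  out
}

#' Write a trajectory table as CSV
#'
#' @param config A [trajectory_config()].
#' @param path Output CSV path.
#' @param step Station increment in cm.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(config, path, step = 0.5) {
  tab <- trajectory_table(config, step)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# presentation=%s", config$presentation),
    "# units: station cm (ischial-spine plane = 0), displacements mm, rotations deg",
    "# convention: anterior = +x, caudal = +z"), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
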