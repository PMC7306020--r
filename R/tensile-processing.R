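#' Specimen geometry for a cuboid tensile sample
#'
#' @param width_mm,thickness_mm Cross-section dimensions (mm), measured on the
#'   unloaded sample; the initial cross-sectional area is their product.
#' @param gauge_length_mm Initial free length between the grips (mm);
#'   typically 5 or 10 mm for levator ani samples, any positive value accepted.
#' @return Object of class `specimen_geometry`.
#' @export
specimen_geometry <- function(width_mm, thickness_mm, gauge_length_mm) {
  v <- c(width_mm, thickness_mm, gauge_length_mm)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("specimen dimensions must be finite and strictly positive")
  structure(list(width_mm = width_mm, thickness_mm = thickness_mm,
                 gauge_length_mm = gauge_length_mm),
            class = "specimen_geometry")
}

#' Initial cross-sectional area of a cuboid specimen
#'
#' @param geometry A [specimen_geometry()].
#' @return Area in mm^2 (width x thickness; rectangular cross-section).
#' @export
cross_section_area <- function(geometry) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  geometry$width_mm * geometry$thickness_mm
}

#' Raw uniaxial tensile-test record
#'
#' Holds the machine output of one test: time, grip elongation and tensile
#' force series, together with the specimen geometry needed to reduce them.
#'
#' @param specimen_id Character id.
#' @param geometry A [specimen_geometry()].
#' @param time_s,elongation_mm,force_n Equal-length numeric series
#'   (length >= 2); time strictly increasing, elongation non-negative at the
#'   first sample.
#' @return Object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, geometry, time_s, elongation_mm, force_n) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  n <- length(time_s)
  if (n < 2L || length(elongation_mm) != n || length(force_n) != n)
    stop("time, elongation and force series must have equal length >= 2")
  if (any(diff(time_s) <= 0)) stop("'time_s' must be strictly increasing")
  if (elongation_mm[1] < 0) stop("elongation must be non-negative at the start")
  structure(list(specimen_id = as.character(specimen_id), geometry = geometry,
                 time_s = as.numeric(time_s),
                 elongation_mm = as.numeric(elongation_mm),
                 force_n = as.numeric(force_n)),
            class = "specimen_record")
}

#' Nominal stress-stretch curve of one specimen
#'
#' @param specimen_id Character id.
#' @param stretch Stretch series \eqn{\lambda = 1 + \epsilon}; must start at
#'   \eqn{\lambda \ge 1}.
#' @param nominal_stress_mpa Nominal (first Piola) stress series, MPa.
#' @return Object of class `stress_strain_curve` with fields `stretch`,
#'   `strain` (\eqn{\lambda - 1}) and `nominal_stress_mpa`.
#' @export
stress_strain_curve <- function(specimen_id, stretch, nominal_stress_mpa) {
  n <- length(stretch)
  if (n < 1L || length(nominal_stress_mpa) != n)
    stop("stretch and stress series must have equal positive length")
  if (stretch[1] < 1) stop("stretch must be >= 1 at the first sample")
  structure(list(specimen_id = as.character(specimen_id),
                 stretch = as.numeric(stretch),
                 strain = as.numeric(stretch) - 1,
                 nominal_stress_mpa = as.numeric(nominal_stress_mpa)),
            class = "stress_strain_curve")
}

#' Reduce a raw tensile record to a nominal stress-stretch curve
#'
#' Nominal (engineering) conventions: stress is force over the *initial*
#' cross-section (N/mm^2 = MPa, so no unit constants appear), strain is
#' elongation over the initial gauge length, stretch is 1 + strain.
#'
#' Records that contain preconditioning cycles (cyclic loading applied before
#' the measured ramp) are handled by keeping only the final monotone loading
#' ramp, identified as the longest suffix with non-decreasing elongation; for
#' a plain monotone ramp this is the whole record.
#'
#' @param record A [specimen_record()].
#' @return A [stress_strain_curve()].
#' @export
to_stress_strain <- function(record) {
  stopifnot(inherits(record, "specimen_record"))
  area <- cross_section_area(record$geometry)
  el <- record$elongation_mm
  # longest suffix with non-decreasing elongation = final loading ramp
  start <- length(el)
  while (start > 1L && el[start - 1L] <= el[start]) start <- start - 1L
  idx <- start:length(el)
  stress_strain_curve(
    specimen_id = record$specimen_id,
    stretch = 1 + el[idx] / record$geometry$gauge_length_mm,
    nominal_stress_mpa = record$force_n[idx] / area
  )
}

#' Truncate a stress-stretch curve at rupture
#'
#' Uniaxial extension is run until the tissue ruptures, which shows up as a
#' sharp stress drop. The rupture point is detected as the first sample whose
#' stress falls below `(1 - drop_fraction)` times the running maximum; the
#' curve is cut just before it (the last pre-drop sample is kept). Curves
#' without such a drop are returned unchanged, so the operation is idempotent.
#'
#' To keep the relative rule meaningful on noisy records, detection is armed
#' only once the running maximum exceeds `min_peak_fraction` of the curve's
#' overall peak: rupture is by definition a drop from the curve's peak
#' region, while in the low-stress toe region measurement noise would
#' otherwise trigger spurious "drops" of the tiny running maximum.
#'
#' @param curve A [stress_strain_curve()].
#' @param drop_fraction Relative drop from the running maximum that counts as
#'   rupture; must lie in (0, 1). Default 0.2.
#' @param min_peak_fraction Fraction of the overall stress maximum that the
#'   running maximum must reach before drop detection is active (default
#'   0.5; 0 disables the guard).
#' @return A [stress_strain_curve()], a prefix of the input.
#' @export
truncate_at_rupture <- function(curve, drop_fraction = 0.2,
                                min_peak_fraction = 0.5) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (!is.finite(drop_fraction) || drop_fraction <= 0 || drop_fraction >= 1)
    stop("'drop_fraction' must lie in (0, 1)")
  s <- curve$nominal_stress_mpa
  runmax <- cummax(s)
  armed <- runmax > min_peak_fraction * max(s)
  bad <- which(s < (1 - drop_fraction) * runmax & armed)
  if (length(bad) == 0L) return(curve)
  keep <- seq_len(bad[1] - 1L)
  stress_strain_curve(curve$specimen_id, curve$stretch[keep], s[keep])
}

#' Read and write specimen records and curves as CSV
#'
#' A specimen record CSV carries the geometry in comment header lines
#' (`# specimen_id=..`, `# width_mm=..`, `# thickness_mm=..`,
#' `# gauge_length_mm=..`) followed by the columns
#' `time_s,elongation_mm,force_n`. A curve CSV has columns
#' `stretch,strain,nominal_stress_mpa`. One file per specimen; a cohort is a
#' directory of such files.
#'
#' @param record A [specimen_record()].
#' @param path File path.
#' @return `read_specimen_csv` returns a [specimen_record()];
#'   `read_curve_csv` a [stress_strain_curve()]; the writers return `path`
#'   invisibly.
#' @export
write_specimen_csv <- function(record, path) {
  stopifnot(inherits(record, "specimen_record"))
  g <- record$geometry
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# specimen_id=%s", record$specimen_id),
    sprintf("# width_mm=%.17g", g$width_mm),
    sprintf("# thickness_mm=%.17g", g$thickness_mm),
    sprintf("# gauge_length_mm=%.17g", g$gauge_length_mm)
  ), con)
  write_csv_full_precision(
    data.frame(time_s = record$time_s, elongation_mm = record$elongation_mm,
               force_n = record$force_n),
    con)
  invisible(path)
}

# write.csv at 17 significant digits so numeric round trips are lossless
write_csv_full_precision <- function(df, con) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col))
  names(out) <- names(df)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
}

#' @rdname write_specimen_csv
#' @export
read_specimen_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("missing '# %s=' header in %s", key, path))
    sub(sprintf("^# %s=", key), "", m)
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  specimen_record(
    specimen_id = meta("specimen_id"),
    geometry = specimen_geometry(as.numeric(meta("width_mm")),
                                 as.numeric(meta("thickness_mm")),
                                 as.numeric(meta("gauge_length_mm"))),
    time_s = df$time_s, elongation_mm = df$elongation_mm, force_n = df$force_n
  )
}

#' @rdname write_specimen_csv
#' @param curve A [stress_strain_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# specimen_id=%s", curve$specimen_id), con)
  writeLines("# units: stress MPa, stretch/strain dimensionless", con)
  write_csv_full_precision(
    data.frame(stretch = curve$stretch, strain = curve$strain,
               nominal_stress_mpa = curve$nominal_stress_mpa),
    con)
  invisible(path)
}

#' @rdname write_specimen_csv
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  id_line <- grep("^# specimen_id=", lines, value = TRUE)
  id <- if (length(id_line) >= 1L) sub("^# specimen_id=", "", id_line[1]) else
    tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  stress_strain_curve(id, df$stretch, df$nominal_stress_mpa)
}
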