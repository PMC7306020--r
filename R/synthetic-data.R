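#' Specification of a synthetic tensile-test cohort
#'
#' Describes a cohort of simulated uniaxial tensile tests with the structure
#' of a porcine levator ani experiment: cuboid specimens of roughly
#' 6 x 4 mm cross-section and 5 or 10 mm gauge length, loaded at 6 mm/min
#' until rupture, with nominal-stress behavior governed by a two-term Ogden
#' law. Defaults reproduce the study conditions; the packaged 20-row porcine
#' constants table is the default ground truth.
#'
#' @param n_specimens Number of specimens (default 20: ten animals, left and
#'   right side).
#' @param geometry_mean A [specimen_geometry()] giving mean width, thickness
#'   and gauge length (defaults 6, 4, 10 mm).
#' @param geometry_sd Relative SD of sampled width/thickness (default 0.05,
#'   caliper-scale variability); gauge length is kept fixed at its mean.
#' @param truth_mode `"fixed-table"` (specimen i uses row i of
#'   `truth_table`) or `"sampled"` (rows resampled with replacement, which
#'   preserves the between-parameter correlations of the table).
#' @param truth_table List of [ogden_params()]; defaults to
#'   [porcine_lam_ogden_list()].
#' @param loading_velocity_mm_per_min Crosshead speed (default 6 mm/min).
#' @param sample_rate_hz Sampling rate of the simulated machine (default
#'   10 Hz; real traction-machine rates vary and are rarely reported).
#' @param rupture_stretch_range Range (lo, hi) of the uniformly sampled
#'   rupture stretch, within (1, 4); default c(1.4, 2.0).
#' @param force_noise_rel Gaussian force noise SD as a fraction of each
#'   record's peak force (default 0.005).
#' @param precondition If `TRUE`, emit 20 triangular preconditioning cycles
#'   to 15\% strain ahead of the final ramp (default `FALSE`).
#' @param rng_seed Integer master seed; per-specimen seeds are derived from
#'   it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 20L,
                        geometry_mean = specimen_geometry(6, 4, 10),
                        geometry_sd = 0.05,
                        truth_mode = c("fixed-table", "sampled"),
                        truth_table = porcine_lam_ogden_list(),
                        loading_velocity_mm_per_min = 6,
                        sample_rate_hz = 10,
                        rupture_stretch_range = c(1.4, 2.0),
                        force_noise_rel = 0.005,
                        precondition = FALSE,
                        rng_seed = 1L) {
  truth_mode <- match.arg(truth_mode)
  n_specimens <- as.integer(n_specimens)
  if (n_specimens < 1L) stop("'n_specimens' must be >= 1")
  if (force_noise_rel < 0) stop("'force_noise_rel' must be >= 0")
  r <- rupture_stretch_range
  if (length(r) != 2L || r[1] <= 1 || r[2] >= 4 || r[1] > r[2])
    stop("'rupture_stretch_range' must lie within (1, 4)")
  stopifnot(inherits(geometry_mean, "specimen_geometry"))
  if (truth_mode == "fixed-table" && length(truth_table) < n_specimens)
    stop(sprintf("fixed-table truth needs >= %d parameter sets, got %d",
                 n_specimens, length(truth_table)))
  structure(list(n_specimens = n_specimens, geometry_mean = geometry_mean,
                 geometry_sd = geometry_sd, truth_mode = truth_mode,
                 truth_table = truth_table,
                 loading_velocity_mm_per_min = loading_velocity_mm_per_min,
                 sample_rate_hz = sample_rate_hz,
                 rupture_stretch_range = r,
                 force_noise_rel = force_noise_rel,
                 precondition = precondition,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% 2147483647L)
  force(expr)
}

#' Simulate one uniaxial tensile test
#'
#' Forward model of the testing protocol: the crosshead moves at constant
#' velocity, so elongation is exactly velocity x time; the axial stretch is
#' `1 + elongation / gauge_length` and the clean force is
#' `uniaxial_nominal_stress(truth, stretch) * initial_area`. Gaussian noise
#' with SD `force_noise_rel x peak clean force` is added to the force
#' channel. After the rupture stretch (sampled uniformly from the spec's
#' range) the record terminates with three post-rupture samples whose force
#' collapses to 30\%, 10\% and 2\% of the peak, so downstream rupture
#' truncation has a drop to detect. With `precondition = TRUE`, 20
#' triangular cycles to 15\% strain precede the ramp.
#'
#' @param truth Ground-truth [ogden_params()].
#' @param geometry A [specimen_geometry()].
#' @param spec A [cohort_spec()] (protocol parameters).
#' @param seed Integer seed; the same seed reproduces the record bit for
#'   bit.
#' @param specimen_id Identifier for the record.
#' @return A [specimen_record()].
#' @export
generate_specimen <- function(truth, geometry, spec = cohort_spec(),
                              seed = spec$rng_seed, specimen_id = "synthetic") {
  stopifnot(inherits(truth, "ogden_params"),
            inherits(geometry, "specimen_geometry"),
            inherits(spec, "cohort_spec"))
  with_seed(seed, {
    v <- spec$loading_velocity_mm_per_min / 60       # mm/s
    L0 <- geometry$gauge_length_mm
    A0 <- cross_section_area(geometry)
    dt <- 1 / spec$sample_rate_hz
    lam_rupture <- stats::runif(1, spec$rupture_stretch_range[1],
                                spec$rupture_stretch_range[2])
    t_rupture <- (lam_rupture - 1) * L0 / v
    ramp_t <- seq(0, floor(t_rupture / dt) * dt, by = dt)

    time_s <- ramp_t
    elong <- v * ramp_t
    if (spec$precondition) {
      # 20 triangular cycles to 15% strain, then the measured ramp
      e_max <- 0.15 * L0
      half <- seq(dt, ceiling(e_max / v / dt) * dt, by = dt)
      up <- v * half
      cyc_e <- c(up, rev(up[-length(up)]), 0)
      cycles_e <- rep(cyc_e, times = 20)
      cycles_t <- seq_along(cycles_e) * dt
      time_s <- c(cycles_t, cycles_t[length(cycles_t)] + dt + ramp_t)
      elong <- c(cycles_e, elong)
    }
    stretch <- 1 + elong / L0
    force <- uniaxial_nominal_stress(truth, stretch) * A0
    peak <- max(force)
    if (spec$force_noise_rel > 0)
      force <- force + stats::rnorm(length(force), 0, spec$force_noise_rel * peak)

    # post-rupture collapse: elongation keeps advancing, force drops
    n_post <- 3L
    post_t <- time_s[length(time_s)] + dt * seq_len(n_post)
    post_e <- elong[length(elong)] + v * dt * seq_len(n_post)
    post_f <- peak * c(0.30, 0.10, 0.02)
    specimen_record(specimen_id, geometry,
                    time_s = c(time_s, post_t),
                    elongation_mm = c(elong, post_e),
                    force_n = c(force, post_f))
  })
}

#' Simulate a cohort of tensile tests
#'
#' Generates `spec$n_specimens` records with per-specimen seeds derived from
#' the master seed, together with a manifest mapping specimen ids to their
#' ground-truth parameters (for recovery testing).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `records` (list of [specimen_record()]) and
#'   `manifest` (named list of [ogden_params()], keyed by specimen id).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- (spec$rng_seed %% 1000000L) * 1024L
  truths <- if (spec$truth_mode == "fixed-table") {
    spec$truth_table[seq_len(spec$n_specimens)]
  } else {
    with_seed(base + 999L,
      spec$truth_table[sample.int(length(spec$truth_table),
                                  spec$n_specimens, replace = TRUE)])
  }
  records <- vector("list", spec$n_specimens)
  manifest <- vector("list", spec$n_specimens)
  for (i in seq_len(spec$n_specimens)) {
    id <- sprintf("specimen_%02d", i)
    g <- with_seed(base + 2L * i, {
      gm <- spec$geometry_mean
      jitter <- function(m) max(0.2 * m, stats::rnorm(1, m, spec$geometry_sd * m))
      specimen_geometry(jitter(gm$width_mm), jitter(gm$thickness_mm),
                        gm$gauge_length_mm)
    })
    records[[i]] <- generate_specimen(truths[[i]], g, spec,
                                      seed = base + 2L * i + 1L,
                                      specimen_id = id)
    manifest[[i]] <- truths[[i]]
    names(manifest)[i] <- id
  }
  list(records = records, manifest = manifest)
}

#' Write a simulated cohort to a directory
#'
#' One specimen CSV per record plus a `manifest.json` holding the
#' ground-truth Ogden parameters of each specimen.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort$records)
    write_specimen_csv(rec, file.path(dir, paste0(rec$specimen_id, ".csv")))
  manifest <- lapply(cohort$manifest, function(p)
    list(terms = lapply(seq_len(p$n_terms), function(j)
      list(mu_mpa = p$mu[j], alpha = p$alpha[j])),
      bulk_k_mpa = p$bulk_k))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort manifest of ground-truth parameters
#'
#' @param path Path to a `manifest.json` written by [write_cohort_dir()].
#' @return Named list of [ogden_params()].
#' @export
read_cohort_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(p)
    ogden_params(mu = vapply(p$terms, function(t) as.numeric(t$mu_mpa), numeric(1)),
                 alpha = vapply(p$terms, function(t) as.numeric(t$alpha), numeric(1)),
                 bulk_k = if (is.null(p$bulk_k_mpa)) 0 else as.numeric(p$bulk_k_mpa)))
}
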