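#' Configuration for a simulated hyperspectral cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' reproduce the geometry of a confocal Raman mapping study of biofluid
#' drops: 18 case and 20 control patients, one 23 x 15 pixel map per
#' patient (345 spectra), wavenumber axis 725..1813 cm^-1 at 1 cm^-1
#' steps (1089 points).
#'
#' Each simulated spectrum is
#' `gain * signal * (1 + patient_effect) + baseline + noise + spikes`
#' where `signal` is the class-attenuated band sum, `gain ~ N(1, gain_sd)`
#' per spectrum, `patient_effect ~ N(0, patient_sd)` shared by all spectra
#' of a patient, the baseline is a random cubic plus a broad exponential
#' fluorescence term, noise is white Gaussian, and cosmic-ray spikes are
#' Poisson-placed single-point positive excursions.
#'
#' @param n_case,n_control Number of case / control patients.
#' @param grid_rows,grid_cols Map dimensions in pixels.
#' @param axis_start,axis_end,axis_step Wavenumber axis (cm^-1).
#' @param bands Band library data frame (see [default_band_library()]).
#' @param baseline_order Polynomial degree of the random baseline.
#' @param baseline_scale Intensity scale of the polynomial baseline.
#' @param fluor_scale Intensity scale of the broad exponential
#'   fluorescence term (0 disables it).
#' @param gain_sd SD of the per-spectrum multiplicative gain (mean 1).
#' @param patient_sd SD of the per-patient amplitude random effect.
#' @param noise_sd SD of additive white noise.
#' @param spike_rate Expected cosmic-ray spikes per spectrum.
#' @param spike_amplitude Base intensity of a spike.
#' @param seed RNG seed used by [simulate_cohort()].
#' @return A list with class `cohort_config`.
#' @export
cohort_config <- function(n_case = 18, n_control = 20,
                          grid_rows = 23, grid_cols = 15,
                          axis_start = 725, axis_end = 1813, axis_step = 1,
                          bands = default_band_library(),
                          baseline_order = 3, baseline_scale = 0.5,
                          fluor_scale = 0.3,
                          gain_sd = 0.10, patient_sd = 0.10, noise_sd = 0.08,
                          spike_rate = 0.02, spike_amplitude = 5,
                          seed = 1L) {
  stopifnot(n_case > 0, n_control > 0, grid_rows > 0, grid_cols > 0,
            axis_step > 0, axis_end > axis_start,
            baseline_order >= 0, baseline_scale >= 0, fluor_scale >= 0,
            gain_sd >= 0, patient_sd >= 0, noise_sd >= 0,
            spike_rate >= 0, spike_amplitude >= 0)
  axis <- seq(axis_start, axis_end, by = axis_step)
  if (nrow(bands) > 0) {
    stopifnot(all(bands$center >= axis_start & bands$center <= axis_end),
              all(bands$width > 0), all(bands$amplitude >= 0),
              all(bands$case_attenuation >= 0 & bands$case_attenuation <= 1))
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    axis = axis, bands = bands,
    baseline_order = as.integer(baseline_order),
    baseline_scale = baseline_scale, fluor_scale = fluor_scale,
    gain_sd = gain_sd, patient_sd = patient_sd, noise_sd = noise_sd,
    spike_rate = spike_rate, spike_amplitude = spike_amplitude,
    seed = as.integer(seed)), class = "cohort_config")
}

# Simulate n spectra sharing one class profile and one patient effect.
# Returns list(x = n x m intensity matrix, spikes = data.frame(row, index)).
# Uses the current RNG state.
simulate_spectra_block <- function(config, n, class, patient_effect) {
  class <- match.arg(as.character(class), c("control", "case"))
  axis <- config$axis
  m <- length(axis)
  profile <- band_profile(config$bands, axis, class) * (1 + patient_effect)
  gain <- 1 + stats::rnorm(n, 0, config$gain_sd)
  x <- tcrossprod(gain, profile)
  # per-spectrum random polynomial baseline on axis scaled to [-1, 1]
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  if (config$baseline_scale > 0) {
    deg <- config$baseline_order
    coefs <- matrix(stats::rnorm(n * (deg + 1)), n, deg + 1)
    basis <- outer(t, 0:deg, `^`)                      # m x (deg+1)
    x <- x + config$baseline_scale * tcrossprod(coefs, basis)
  }
  if (config$fluor_scale > 0) {
    fl <- exp(-(axis - min(axis)) / 400)
    x <- x + config$fluor_scale * tcrossprod(abs(stats::rnorm(n)), fl)
  }
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  spikes <- NULL
  if (config$spike_rate > 0 && config$spike_amplitude > 0) {
    counts <- stats::rpois(n, config$spike_rate)
    tot <- sum(counts)
    if (tot > 0) {
      rows <- rep(seq_len(n), counts)
      idx <- sample.int(m, tot, replace = TRUE)
      amp <- config$spike_amplitude * (1 + abs(stats::rnorm(tot)))
      x[cbind(rows, idx)] <- x[cbind(rows, idx)] + amp
      spikes <- data.frame(row = rows, index = idx, wavenumber = axis[idx],
                           amplitude = amp)
    }
  }
  stopifnot(all(is.finite(x)))
  list(x = x, spikes = spikes)
}

#' Simulate a single Raman spectrum
#'
#' Draws one spectrum from the generative model of [cohort_config()],
#' using the current RNG state (call `set.seed()` for reproducibility).
#'
#' @param config A [cohort_config()].
#' @param patient_effect Scalar multiplicative amplitude random effect
#'   (0 = an average patient).
#' @param class `"case"` or `"control"`.
#' @return Numeric vector of intensities on `config$axis`.
#' @export
simulate_spectrum <- function(config, patient_effect = 0, class = "control") {
  drop(simulate_spectra_block(config, 1L, class, patient_effect)$x)
}

#' Simulate a full hyperspectral cohort
#'
#' Generates one spectral map per patient plus a sample metadata table
#' and the ground truth (labels, planted band effects, spike positions)
#' needed for recovery tests. Fixing `config$seed` makes the cohort
#' bit-identical across runs.
#'
#' @param config A [cohort_config()].
#' @return A list with class `raman_cohort`: `maps` (list of
#'   [spectral_map()]), `metadata` (data frame: sample_id, patient_id,
#'   class, fluid), and `truth` (labels, planted effects, spikes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_pat <- config$n_case + config$n_control
  classes <- rep(c("case", "control"), c(config$n_case, config$n_control))
  patient_ids <- sprintf("P%02d", seq_len(n_pat))
  sample_ids <- sprintf("S%02d", seq_len(n_pat))
  effects <- stats::rnorm(n_pat, 0, config$patient_sd)
  npx <- config$grid_rows * config$grid_cols
  maps <- vector("list", n_pat)
  spikes <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    blk <- simulate_spectra_block(config, npx, classes[i], effects[i])
    maps[[i]] <- spectral_map(sample_ids[i], config$axis, blk$x,
                              config$grid_rows, config$grid_cols)
    if (!is.null(blk$spikes)) {
      blk$spikes$sample_id <- sample_ids[i]
      spikes[[i]] <- blk$spikes
    }
  }
  names(maps) <- sample_ids
  metadata <- data.frame(sample_id = sample_ids, patient_id = patient_ids,
                         class = classes, fluid = "synthetic",
                         stringsAsFactors = FALSE)
  planted <- config$bands[config$bands$case_attenuation < 1, , drop = FALSE]
  truth <- list(labels = stats::setNames(classes, patient_ids),
                planted_bands = planted,
                spikes = do.call(rbind, spikes[!vapply(spikes, is.null, TRUE)]))
  structure(list(maps = maps, metadata = metadata, truth = truth,
                 config = config), class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat("Simulated Raman cohort:", length(x$maps), "maps (",
      sum(x$metadata$class == "case"), "case /",
      sum(x$metadata$class == "control"), "control )\n")
  cat("  map geometry:", x$config$grid_rows, "x", x$config$grid_cols,
      "pixels,", length(x$config$axis), "wavenumbers\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' One wide CSV per sample (column 1 = wavenumber, remaining columns =
#' pixel spectra in row-major scan order), `metadata.csv`, and
#' `truth.json` with the planted ground truth.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raman_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (map in cohort$maps)
    write_spectra_csv(map, file.path(dir, paste0(map$sample_id, ".csv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- list(labels = as.list(cohort$truth$labels),
                planted_bands = cohort$truth$planted_bands,
                spikes = cohort$truth$spikes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
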