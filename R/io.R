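#' Spectral map container
#'
#' One sample's grid of raw spectra on a shared, strictly increasing
#' wavenumber axis. Spectra are stored as a `(grid_rows*grid_cols) x m`
#' matrix in row-major scan order (pixel row 1 left-to-right, then row 2,
#' ...), i.e. acquisition order of a raster scan.
#'
#' @param sample_id Sample identifier.
#' @param axis Strictly increasing numeric wavenumber axis (length >= 2).
#' @param intensities Matrix of intensities, `grid_rows*grid_cols` rows.
#' @param grid_rows,grid_cols Grid dimensions.
#' @return An object of class `spectral_map`.
#' @export
spectral_map <- function(sample_id, axis, intensities, grid_rows, grid_cols) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  validate_axis(axis)
  stopifnot(nrow(intensities) == grid_rows * grid_cols,
            ncol(intensities) == length(axis),
            all(is.finite(intensities)))
  structure(list(sample_id = as.character(sample_id), axis = axis,
                 intensities = intensities,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "spectral_map")
}

validate_axis <- function(axis, context = "axis") {
  if (length(axis) < 2)
    stop(context, ": need at least 2 wavenumbers", call. = FALSE)
  if (any(!is.finite(axis)) || any(diff(axis) <= 0))
    stop(context, ": wavenumber axis must be strictly increasing",
         call. = FALSE)
  invisible(axis)
}

#' Labelled spectrum matrix
#'
#' The unfolded analysis container: `n` spectra by `m` wavenumbers, with
#' one metadata row (sample_id, patient_id, class) per spectrum. Class
#' labels must be `"case"` or `"control"`.
#'
#' @param axis Strictly increasing wavenumber axis.
#' @param x Numeric matrix, `n x length(axis)`.
#' @param meta Data frame with columns `sample_id`, `patient_id`, `class`
#'   and `n` rows.
#' @return An object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(axis, x, meta) {
  axis <- as.numeric(axis)
  x <- as.matrix(x)
  validate_axis(axis)
  stopifnot(ncol(x) == length(axis), nrow(meta) == nrow(x),
            all(c("sample_id", "patient_id", "class") %in% names(meta)))
  if (any(!is.finite(x))) stop("spectrum_matrix: non-finite intensities")
  if (!all(meta$class %in% c("case", "control")))
    stop("spectrum_matrix: class labels must be 'case' or 'control'")
  structure(list(axis = axis, x = x,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE)),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat("spectrum_matrix:", nrow(x$x), "spectra x", ncol(x$x),
      "wavenumbers (", min(x$axis), "-", max(x$axis), "cm^-1 )\n")
  cat("  classes:", sum(x$meta$class == "case"), "case /",
      sum(x$meta$class == "control"), "control;",
      length(unique(x$meta$sample_id)), "samples\n")
  invisible(x)
}

#' @export
dim.spectrum_matrix <- function(x) dim(x$x)

# replace the intensity block, keeping axis/meta
set_x <- function(sm, x) { sm$x <- x; sm }

#' Write a spectral map as a wide CSV
#'
#' Column 1 is the wavenumber axis; remaining columns are the pixel
#' spectra in row-major scan order.
#'
#' @param map A [spectral_map()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  df <- data.frame(wavenumber = map$axis, t(map$intensities))
  names(df) <- c("wavenumber", sprintf("px%04d", seq_len(nrow(map$intensities))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# sniff "," vs tab from the first line
sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) >
      lengths(regmatches(l1, gregexpr(",", l1)))) "\t" else ","
}

#' Read a wide spectra CSV/TSV
#'
#' Reads one sample's spectra (column 1 = monotone wavenumber axis,
#' remaining columns = spectra), validating the axis. With grid
#' dimensions a [spectral_map()] is returned; otherwise the raw pieces.
#'
#' @param path Wide CSV/TSV file with a header row.
#' @param sample_id Sample identifier (default: file name sans extension).
#' @param grid_rows,grid_cols Optional map dimensions; their product must
#'   equal the number of spectrum columns.
#' @return A [spectral_map()] if grid dimensions are given, else a list
#'   with `axis` and `intensities` (spectra in rows).
#' @export
read_spectra_csv <- function(path, sample_id = NULL,
                             grid_rows = NULL, grid_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE)
  if (ncol(df) < 2) stop(path, ": need a wavenumber column plus spectra",
                         call. = FALSE)
  axis <- as.numeric(df[[1]])
  if (any(!is.finite(axis)) || any(diff(axis) <= 0))
    stop(path, ": column 1 must be a strictly increasing wavenumber axis",
         call. = FALSE)
  x <- t(as.matrix(df[, -1, drop = FALSE]))
  if (any(!is.finite(x))) stop(path, ": non-finite intensity values",
                               call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (!is.null(grid_rows) && !is.null(grid_cols))
    return(spectral_map(sample_id, axis, x, grid_rows, grid_cols))
  list(sample_id = sample_id, axis = axis, intensities = x)
}

#' Read a whole cohort directory
#'
#' Expects `metadata.csv` (columns sample_id, patient_id, class, ...) and
#' one wide CSV per sample named `<sample_id>.csv`. All samples must
#' share the wavenumber axis; every sample must be labelled.
#'
#' @param dir Directory written by [write_cohort()] or of the same shape.
#' @param grid_rows,grid_cols Optional map dimensions applied to every
#'   sample.
#' @return A list of [spectral_map()] (or raw spectra lists) plus the
#'   metadata data frame, as `list(maps, metadata)`.
#' @export
read_cohort <- function(dir, grid_rows = NULL, grid_cols = NULL) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir, call. = FALSE)
  metadata <- utils::read.table(meta_path, header = TRUE,
                                sep = sniff_sep(meta_path),
                                stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "class")
  if (!all(need %in% names(metadata)))
    stop("metadata.csv must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(metadata$class %in% c("case", "control")))
    stop("metadata.csv: class must be 'case' or 'control'", call. = FALSE)
  maps <- vector("list", nrow(metadata))
  axis0 <- NULL
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    f <- file.path(dir, paste0(sid, ".csv"))
    if (!file.exists(f)) stop("sample ", sid, " listed in metadata but ",
                              f, " is missing", call. = FALSE)
    maps[[i]] <- read_spectra_csv(f, sid, grid_rows, grid_cols)
    ax <- maps[[i]]$axis
    if (is.null(axis0)) axis0 <- ax
    else if (length(ax) != length(axis0) || any(abs(ax - axis0) > 1e-9))
      stop(f, ": wavenumber axis differs from other samples", call. = FALSE)
  }
  names(maps) <- metadata$sample_id
  list(maps = maps, metadata = metadata)
}

#' Unfold a spectral map into a labelled matrix
#'
#' Flattens the pixel grid into rows in row-major scan order (the order
#' in which spectra were stored), attaching sample metadata to every row.
#'
#' @param map A [spectral_map()].
#' @param patient_id,class Metadata for the rows (class defaults to
#'   `"control"` when unknown).
#' @return A [spectrum_matrix()] with `grid_rows*grid_cols` rows.
#' @export
unfold_map <- function(map, patient_id = map$sample_id, class = "control") {
  stopifnot(inherits(map, "spectral_map"))
  n <- nrow(map$intensities)
  spectrum_matrix(map$axis, map$intensities,
                  data.frame(sample_id = rep(map$sample_id, n),
                             patient_id = rep(patient_id, n),
                             class = rep(class, n),
                             stringsAsFactors = FALSE))
}

#' Fold an unfolded matrix back into a map
#'
#' Inverse of [unfold_map()] for rows belonging to one sample.
#'
#' @param sm A [spectrum_matrix()] holding exactly one sample's spectra
#'   in row-major order.
#' @param grid_rows,grid_cols Grid dimensions; product must equal rows.
#' @return A [spectral_map()].
#' @export
fold_matrix <- function(sm, grid_rows, grid_cols) {
  stopifnot(inherits(sm, "spectrum_matrix"),
            length(unique(sm$meta$sample_id)) == 1)
  spectral_map(sm$meta$sample_id[1], sm$axis, sm$x, grid_rows, grid_cols)
}

#' Unfold and stack a whole cohort
#'
#' @param cohort A [simulate_cohort()] result or a `list(maps, metadata)`
#'   as returned by [read_cohort()].
#' @return A single [spectrum_matrix()] with all samples stacked.
#' @export
unfold_cohort <- function(cohort) {
  maps <- cohort$maps
  md <- cohort$metadata
  xs <- vector("list", length(maps))
  metas <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    map <- maps[[i]]
    inten <- map$intensities
    n <- nrow(inten)
    xs[[i]] <- inten
    metas[[i]] <- data.frame(sample_id = rep(md$sample_id[i], n),
                             patient_id = rep(md$patient_id[i], n),
                             class = rep(md$class[i], n),
                             stringsAsFactors = FALSE)
  }
  spectrum_matrix(maps[[1]]$axis, do.call(rbind, xs), do.call(rbind, metas))
}

#' Block-average spectra within samples
#'
#' Within each sample (never across sample boundaries), consecutive
#' blocks of `block` rows are replaced by their mean; a trailing partial
#' block is averaged as-is. A 345-spectrum map with `block = 10` becomes
#' 35 averaged spectra (34 full blocks plus one block of 5).
#'
#' @param sm A [spectrum_matrix()].
#' @param block Block size (default 10); `block = 1` is the identity.
#' @return A [spectrum_matrix()] of block means.
#' @export
block_average <- function(sm, block = 10) {
  stopifnot(inherits(sm, "spectrum_matrix"), block >= 1)
  block <- as.integer(block)
  sids <- unique(sm$meta$sample_id)
  grp <- integer(nrow(sm$x))
  off <- 0L
  for (sid in sids) {
    rows <- which(sm$meta$sample_id == sid)
    if (length(rows) == 0) stop("empty sample: ", sid)
    grp[rows] <- off + (seq_along(rows) - 1L) %/% block
    off <- max(grp[rows]) + 1L
  }
  sums <- rowsum(sm$x, grp, reorder = TRUE)
  dimnames(sums) <- NULL
  counts <- as.vector(table(grp))
  first <- match(sort(unique(grp)), grp)
  spectrum_matrix(sm$axis, sums / counts, sm$meta[first, , drop = FALSE])
}

#' Remove cosmic-ray spikes
#'
#' Per-spectrum running-median detector: points whose residual from a
#' running median (window `window`) exceeds `z_thresh` times a robust
#' noise scale are replaced by the local median; all other points are
#' untouched. The scale is the MAD of the spectrum's successive
#' differences divided by sqrt(2) — the usual robust noise estimator.
#' (The MAD of the residuals themselves is biased low: the
#' self-inclusive running median reproduces a sizeable fraction of
#' points exactly, putting an atom at zero.) The number of corrected
#' points is attached as attribute `"spikes_corrected"` and recorded
#' per spectrum in `"spikes_by_row"`.
#'
#' @param sm A [spectrum_matrix()] or a numeric matrix (spectra in rows).
#' @param z_thresh Detection threshold in robust SD units (default 8).
#' @param window Odd running-median window (default 5).
#' @return Object of the same type with spikes replaced.
#' @export
remove_spikes <- function(sm, z_thresh = 8, window = 5) {
  stopifnot(window %% 2 == 1, z_thresh > 0)
  x <- if (inherits(sm, "spectrum_matrix")) sm$x else as.matrix(sm)
  n_corrected <- 0L
  by_row <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    med <- stats::runmed(y, window, endrule = "median")
    resid <- y - med
    scale <- stats::mad(diff(y)) / sqrt(2)
    bad <- if (scale > 0) abs(resid) > z_thresh * scale else resid != 0
    if (any(bad)) {
      x[i, bad] <- med[bad]
      by_row[i] <- sum(bad)
      n_corrected <- n_corrected + sum(bad)
    }
  }
  out <- if (inherits(sm, "spectrum_matrix")) set_x(sm, x) else x
  attr(out, "spikes_corrected") <- n_corrected
  attr(out, "spikes_by_row") <- by_row
  out
}
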