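# Preprocessing chains for Raman spectra.
#
# Three standard combinations are supported, in the stage order in which
# chemometric software applies them:
#   baseline_norm    : SG smoothing -> AWLS baseline -> vector normalisation
#   emsc_baseline    : SG smoothing -> EMSC -> AWLS baseline
#   first_derivative : SG smoothing -> SG 1st derivative

as_x <- function(sm) if (inherits(sm, "spectrum_matrix")) sm$x else as.matrix(sm)
rewrap <- function(sm, x) if (inherits(sm, "spectrum_matrix")) set_x(sm, x) else x

#' Savitzky-Golay smoothing
#'
#' Per-spectrum local least-squares polynomial smoothing. Interior points
#' of a degree-1 fit on a symmetric window equal the centred moving
#' average; edges are handled by fitting the polynomial on the boundary
#' window and evaluating it at the edge points.
#'
#' @param sm [spectrum_matrix()] or numeric matrix (spectra in rows).
#' @param window Odd window length (default 7), greater than `polyorder`
#'   and at most the axis length.
#' @param polyorder Polynomial degree (default 1).
#' @return Smoothed object of the same type.
#' @export
savgol_smooth <- function(sm, window = 7, polyorder = 1) {
  x <- as_x(sm)
  if (window %% 2 != 1) stop("window must be odd")
  stopifnot(window > polyorder, window <= ncol(x))
  out <- t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window))
  rewrap(sm, out)
}

#' Savitzky-Golay derivative
#'
#' First (or higher) derivative with respect to wavenumber, estimated by
#' local polynomial fitting; units are intensity per cm^-1 when the axis
#' step is supplied.
#'
#' @inheritParams savgol_smooth
#' @param polyorder Polynomial degree (default 2; must be >= `deriv`).
#' @param deriv Derivative order (default 1).
#' @param step Axis step in cm^-1; taken from the object's axis when
#'   available, else 1.
#' @return Differentiated object of the same type.
#' @export
savgol_derivative <- function(sm, window = 7, polyorder = 2, deriv = 1,
                              step = NULL) {
  x <- as_x(sm)
  if (window %% 2 != 1) stop("window must be odd")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  if (is.null(step))
    step <- if (inherits(sm, "spectrum_matrix")) diff(sm$axis[1:2]) else 1
  out <- t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv, ts = step))
  rewrap(sm, out)
}

#' Automatic weighted least squares (AWLS) baseline correction
#'
#' Iteratively reweighted polynomial fit that hugs the lower envelope of
#' a spectrum: a degree-`order` polynomial (on the axis rescaled to
#' \[-1, 1\] for conditioning) is fitted by weighted least squares;
#' points above the fit have their weight halved (floored at `w_floor`)
#' while points at or below keep weight 1, and the fit is repeated until
#' the baseline moves less than `tol` (relative to the spectrum range)
#' or `max_iter` is reached.
#'
#' @param y Numeric spectrum.
#' @param axis Wavenumber axis (defaults to index positions).
#' @param order Polynomial degree (default 3).
#' @param max_iter,tol Iteration controls.
#' @param w_floor Smallest allowed weight.
#' @return List with `corrected`, `baseline` and logical `converged`.
#' @export
awls_baseline <- function(y, axis = seq_along(y), order = 3,
                          max_iter = 50, tol = 1e-6, w_floor = 1e-4) {
  stopifnot(length(y) > order + 1, length(axis) == length(y))
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  basis <- outer(t, 0:order, `^`)
  scale <- diff(range(y))
  if (scale == 0) {
    # flat spectrum: baseline is the constant itself
    return(list(corrected = y * 0, baseline = y, converged = TRUE))
  }
  w <- rep(1, length(y))
  b_prev <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    coef <- solve(crossprod(basis * sqrt(w)), crossprod(basis, w * y))
    b <- drop(basis %*% coef)
    if (!is.null(b_prev) && max(abs(b - b_prev)) < tol * scale) {
      converged <- TRUE
      break
    }
    b_prev <- b
    above <- y > b
    w <- ifelse(above, pmax(w / 2, w_floor), 1)
  }
  if (!converged) warning("AWLS baseline did not converge; returning last iterate")
  list(corrected = y - b, baseline = b, converged = converged)
}

# matrix wrapper: AWLS every row. Same iteration as awls_baseline but
# batched across spectra (per-iteration normal equations for all rows
# via two matrix products; 4x4 solves per still-active row).
awls_correct <- function(sm, order = 3, max_iter = 50, tol = 1e-6,
                         w_floor = 1e-4) {
  x <- as_x(sm)
  axis <- if (inherits(sm, "spectrum_matrix")) sm$axis else seq_len(ncol(x))
  n <- nrow(x); m <- ncol(x); p <- order + 1
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  basis <- outer(t, 0:order, `^`)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  PB <- basis[, pairs[, 1], drop = FALSE] * basis[, pairs[, 2], drop = FALSE]
  yscale <- apply(x, 1, function(r) diff(range(r)))
  active <- yscale > 0                      # flat rows: baseline = row itself
  W <- matrix(1, n, m)
  B <- x                                    # flat rows keep baseline = y
  B_prev <- NULL
  iter_done <- FALSE
  for (it in seq_len(max_iter)) {
    if (!any(active)) { iter_done <- TRUE; break }
    ai <- which(active)
    XtWX <- W[ai, , drop = FALSE] %*% PB                 # rows x p(p+1)/2
    XtWy <- (W[ai, , drop = FALSE] * x[ai, , drop = FALSE]) %*% basis
    coef <- matrix(0, length(ai), p)
    A <- matrix(0, p, p)
    for (j in seq_along(ai)) {
      A[cbind(pairs[, 1], pairs[, 2])] <- XtWX[j, ]
      A[cbind(pairs[, 2], pairs[, 1])] <- XtWX[j, ]
      coef[j, ] <- solve(A, XtWy[j, ])
    }
    Bnew <- tcrossprod(coef, basis)
    if (!is.null(B_prev)) {
      dmax <- apply(abs(Bnew - B_prev[ai, , drop = FALSE]), 1, max)
      conv <- dmax < tol * yscale[ai]
      B[ai[conv], ] <- Bnew[conv, , drop = FALSE]
      active[ai[conv]] <- FALSE
    }
    keep <- active[ai]
    B[ai, ] <- Bnew
    if (is.null(B_prev)) B_prev <- B else B_prev[ai, ] <- Bnew
    # reweight still-active rows: halve above-baseline weights, reset rest
    if (any(keep)) {
      ri <- ai[keep]
      above <- x[ri, , drop = FALSE] > B[ri, , drop = FALSE]
      Wn <- matrix(1, length(ri), m)
      Wn[above] <- pmax(W[ri, , drop = FALSE][above] / 2, w_floor)
      W[ri, ] <- Wn
    }
  }
  if (!iter_done && any(active))
    warning("AWLS baseline did not converge for ", sum(active),
            " spectra; returning last iterates")
  rewrap(sm, x - B)
}

#' Extended multiplicative scatter correction (EMSC)
#'
#' Fits each spectrum as
#' `x ~ a + b * reference + sum_j d_j * t^j` (with `t` the axis rescaled
#' to \[-1, 1\]) by least squares and inverts the physical model:
#' `corrected = (x - a - sum_j d_j t^j) / b`. Removes additive offsets,
#' multiplicative gain (thickness, scattering) and smooth polynomial
#' drift.
#'
#' @param sm [spectrum_matrix()] or numeric matrix.
#' @param reference Reference spectrum; defaults to the column mean of
#'   `sm`. During cross-validation pass the training-fold mean.
#' @param poly_order Degree of the polynomial drift model (default 2).
#' @return Object of the same type; attributes `emsc_fits` (data frame
#'   of a, b and drift coefficients per spectrum) and `emsc_reference`.
#'   Spectra with `|b| < 1e-8` are rejected with their row index.
#' @export
emsc_correct <- function(sm, reference = NULL, poly_order = 2) {
  x <- as_x(sm)
  axis <- if (inherits(sm, "spectrum_matrix")) sm$axis else seq_len(ncol(x))
  if (is.null(reference)) reference <- colMeans(x)
  stopifnot(length(reference) == ncol(x))
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  D <- cbind(1, reference, outer(t, seq_len(poly_order), `^`))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("EMSC design matrix is rank deficient")
  coefs <- qr.coef(qrD, t(x))                  # (2+poly_order) x n
  b <- coefs[2, ]
  if (any(abs(b) < 1e-8))
    stop("EMSC multiplicative coefficient ~ 0 for spectra: ",
         paste(which(abs(b) < 1e-8), collapse = ", "))
  drift <- D[, -2, drop = FALSE] %*% coefs[-2, , drop = FALSE]  # m x n
  out <- t((t(x) - drift) / rep(b, each = nrow(drift)))
  fits <- as.data.frame(t(coefs))
  names(fits) <- c("a", "b", paste0("d", seq_len(poly_order)))
  res <- rewrap(sm, out)
  attr(res, "emsc_fits") <- fits
  attr(res, "emsc_reference") <- reference
  res
}

#' Vector (L2) normalisation
#'
#' Divides every spectrum by its Euclidean norm, removing concentration
#' and thickness scale differences.
#'
#' @param sm [spectrum_matrix()] or numeric matrix.
#' @return Object of the same type with unit-norm rows.
#' @export
vector_normalize <- function(sm) {
  x <- as_x(sm)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0))
    stop("zero-norm spectra at rows: ", paste(which(nrm == 0), collapse = ", "))
  rewrap(sm, x / nrm)
}

#' Mean-centre a spectrum matrix
#'
#' Subtracts column (wavenumber) means. The means are stored so held-out
#' data can be centred with the training means (cross-validation
#' hygiene) via [apply_center()].
#'
#' @param sm [spectrum_matrix()] or numeric matrix with >= 2 rows.
#' @return Centred object with attribute `"column_means"`.
#' @export
mean_center <- function(sm) {
  x <- as_x(sm)
  stopifnot(nrow(x) >= 2)
  mu <- colMeans(x)
  out <- rewrap(sm, sweep(x, 2, mu))
  attr(out, "column_means") <- mu
  out
}

#' Centre new data with stored means
#' @param sm [spectrum_matrix()] or numeric matrix.
#' @param column_means Means learned on training data.
#' @return Centred object of the same type.
#' @export
apply_center <- function(sm, column_means) {
  x <- as_x(sm)
  stopifnot(length(column_means) == ncol(x))
  rewrap(sm, sweep(x, 2, column_means))
}

#' Preprocessing pipeline descriptor
#'
#' @param name One of `"baseline_norm"`, `"emsc_baseline"`,
#'   `"first_derivative"`.
#' @param sg_window,sg_polyorder Savitzky-Golay smoothing parameters
#'   (default 7 / 1).
#' @param deriv_polyorder Polynomial degree for the derivative stage
#'   (default 2).
#' @param awls_order AWLS polynomial degree (default 3).
#' @param emsc_poly_order EMSC drift polynomial degree (default 5; high
#'   enough to separate broad fluorescence curvature from the
#'   multiplicative term, within common EMSC practice).
#' @return An object of class `preprocess_pipeline`.
#' @export
preprocess_pipeline <- function(name = c("baseline_norm", "emsc_baseline",
                                         "first_derivative"),
                                sg_window = 7, sg_polyorder = 1,
                                deriv_polyorder = 2,
                                awls_order = 3, emsc_poly_order = 5) {
  name <- match.arg(name)
  stopifnot(sg_window %% 2 == 1, sg_window > sg_polyorder, awls_order >= 0)
  structure(list(name = name, sg_window = sg_window,
                 sg_polyorder = sg_polyorder,
                 deriv_polyorder = deriv_polyorder,
                 awls_order = awls_order,
                 emsc_poly_order = emsc_poly_order),
            class = "preprocess_pipeline")
}

#' Apply a preprocessing chain
#'
#' Stage order is fixed per chain: `baseline_norm` = SG smoothing, AWLS
#' baseline correction, vector normalisation; `emsc_baseline` = SG
#' smoothing, EMSC, AWLS baseline correction; `first_derivative` = SG
#' smoothing then SG first derivative.
#'
#' @param sm [spectrum_matrix()] or numeric matrix.
#' @param pipeline A [preprocess_pipeline()] or its name.
#' @param emsc_reference EMSC reference spectrum; default is the mean of
#'   the data being processed. During cross-validation pass the
#'   training-fold mean to avoid leakage.
#' @return Preprocessed object of the same type.
#' @export
apply_pipeline <- function(sm, pipeline = "emsc_baseline",
                           emsc_reference = NULL) {
  if (is.character(pipeline)) pipeline <- preprocess_pipeline(pipeline)
  stopifnot(inherits(pipeline, "preprocess_pipeline"))
  out <- savgol_smooth(sm, pipeline$sg_window, pipeline$sg_polyorder)
  switch(pipeline$name,
    baseline_norm = {
      out <- awls_correct(out, order = pipeline$awls_order)
      vector_normalize(out)
    },
    emsc_baseline = {
      out <- emsc_correct(out, reference = emsc_reference,
                          poly_order = pipeline$emsc_poly_order)
      awls_correct(out, order = pipeline$awls_order)
    },
    first_derivative =
      savgol_derivative(out, pipeline$sg_window, pipeline$deriv_polyorder, 1)
  )
}
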