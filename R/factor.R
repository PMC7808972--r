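#' Principal component analysis by SVD
#'
#' Centres the data (recording the column means), computes the thin SVD
#' and returns orthonormal loadings, scores and explained-variance
#' fractions. Loadings follow a deterministic sign convention: the
#' largest-magnitude element of each loading is positive.
#'
#' @param x Numeric matrix (spectra in rows) or [spectrum_matrix()].
#' @param k Number of components; must satisfy
#'   `k <= min(nrow - 1, ncol)`.
#' @return An object of class `pca_model`: `loadings` (m x k), `scores`
#'   (n x k), `explained_variance_fraction`, `column_means`, `k`.
#' @export
pca_fit <- function(x, k) {
  x <- as_x(x)
  n <- nrow(x); m <- ncol(x)
  if (k > min(n - 1, m)) stop("k exceeds min(n-1, m) = ", min(n - 1, m))
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = min(n, m))
  ev <- sv$d^2 / (n - 1)
  frac <- ev / sum(ev)
  V <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest |element| of each loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(loadings = V, scores = xc %*% V,
                 explained_variance_fraction = frac[seq_len(k)],
                 eigenvalues = ev[seq_len(k)],
                 column_means = mu, k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", x$k, "components,",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_fraction)),
      "variance explained\n")
  invisible(x)
}

#' Project new spectra onto a fitted PCA basis
#'
#' @param model A [pca_fit()] result.
#' @param x New data on the same axis (matrix or [spectrum_matrix()]).
#' @return Score matrix `(x - column_means) %*% loadings`.
#' @export
pca_transform <- function(model, x) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as_x(x)
  if (ncol(x) != length(model$column_means))
    stop("dimension mismatch: model has ", length(model$column_means),
         " wavenumbers, data has ", ncol(x))
  sweep(x, 2, model$column_means) %*% model$loadings
}

#' Choose the number of components by cumulative variance
#'
#' Smallest k whose cumulative explained-variance fraction reaches
#' `threshold`, capped at `cap`. Used inside training folds only.
#'
#' @param x Data matrix.
#' @param threshold Cumulative variance target (default 0.95).
#' @param cap Maximum k (default 10).
#' @return Integer number of components.
#' @export
select_n_pc <- function(x, threshold = 0.95, cap = 10) {
  x <- as_x(x)
  kmax <- min(nrow(x) - 1, ncol(x), cap)
  pm <- pca_fit(x, kmax)
  k <- which(cumsum(pm$explained_variance_fraction) >= threshold)
  if (length(k) == 0) kmax else min(k[1], cap)
}

#' Partial least squares by NIPALS (univariate response)
#'
#' Extracts latent variables by the NIPALS algorithm with X and y
#' deflation: for each LV, the weight vector `w = X'y / |X'y|`, score
#' `t = Xw`, X-loading `p = X't/(t't)`, y-loading `q = y't/(t't)`;
#' X and y are deflated by `t p'` and `t q`. Regression coefficients
#' are recovered as `B = W (P'W)^-1 q`.
#'
#' @param x Predictor matrix (spectra in rows).
#' @param y Numeric response (class indicator 0/1 or +/-1); must not be
#'   constant.
#' @param n_lv Number of latent variables (>= 1, <= rank of `x`).
#' @return Object of class `pls_model`: `weights`, `x_loadings`,
#'   `y_loadings`, `coefficients`, `x_means`, `y_mean`, `n_lv`.
#' @export
pls_fit <- function(x, y, n_lv) {
  x <- as_x(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), n_lv >= 1)
  if (stats::var(y) == 0) stop("constant response: PLS undefined")
  x_means <- colMeans(x); y_mean <- mean(y)
  E <- sweep(x, 2, x_means); f <- y - y_mean
  m <- ncol(x)
  W <- P <- matrix(0, m, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_lv <- a - 1L; break }  # X residual exhausted
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p; q[a] <- q_a
  }
  if (n_lv < 1) stop("no usable latent variables")
  W <- W[, seq_len(n_lv), drop = FALSE]
  P <- P[, seq_len(n_lv), drop = FALSE]
  q <- q[seq_len(n_lv)]
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(weights = W, x_loadings = P, y_loadings = q,
                 coefficients = drop(B), x_means = x_means,
                 y_mean = y_mean, n_lv = n_lv),
            class = "pls_model")
}

#' Predict from a PLS model
#' @param object A [pls_fit()] result.
#' @param newdata Matrix on the same variables.
#' @param ... Unused.
#' @return Numeric predictions of the response.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1)
  newdata <- as_x(newdata)
  drop(sweep(newdata, 2, object$x_means) %*% object$coefficients) +
    object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model:", x$n_lv, "latent variable(s),",
      length(x$x_means), "predictors\n")
  invisible(x)
}
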