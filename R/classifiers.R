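# Discriminant classifiers operating on PCA scores (LDA, QDA, SVM-RBF)
# or on full preprocessed spectra (PLS-DA). Binary only: labels are
# "case" (positive) and "control" (negative); ties go to "control".

check_labels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (length(unique(labels)) < 2)
    stop("training data contain a single class")
  labels
}

# ridge-stabilise a covariance when badly conditioned; records whether
# the ridge fired
stabilize_cov <- function(S, cond_max = 1e10, eps = 1e-8) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ridged <- FALSE
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_max) {
    S <- S + diag(eps * sum(diag(S)) / ncol(S), ncol(S))
    ridged <- TRUE
  }
  list(S = S, ridged = ridged)
}

class_stats <- function(x, labels) {
  lapply(c(control = "control", case = "case"), function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    if (nrow(xi) < 2) stop("need >= 2 samples per class (", cl, ")")
    list(n = nrow(xi), mean = colMeans(xi), cov = stats::cov(xi))
  })
}

#' Linear discriminant analysis (pooled-covariance Mahalanobis rule)
#'
#' Assigns the class minimising the Mahalanobis distance to the class
#' mean under the pooled covariance, minus `2*log(prior)`. Priors are
#' the empirical class frequencies. A ridge `eps * trace/m` is added
#' when the pooled covariance is ill-conditioned (condition number
#' above 1e10) and the event is recorded. Exact ties are assigned to
#' `"control"`.
#'
#' @param x Score matrix (rows = observations).
#' @param labels `"case"`/`"control"` labels, both classes present,
#'   >= 2 observations each.
#' @return Object of class `c("pca_lda", "discriminant_model")`.
#' @export
lda_fit <- function(x, labels) {
  x <- as.matrix(x); labels <- check_labels(labels)
  st <- class_stats(x, labels)
  n <- nrow(x)
  pooled <- ((st$control$n - 1) * st$control$cov +
             (st$case$n - 1) * st$case$cov) / (n - 2)
  sc <- stabilize_cov(pooled)
  structure(list(means = list(control = st$control$mean, case = st$case$mean),
                 cov = sc$S, ridged = sc$ridged,
                 priors = c(control = st$control$n / n, case = st$case$n / n)),
            class = c("pca_lda", "discriminant_model"))
}

#' Quadratic discriminant analysis (per-class covariance)
#'
#' As [lda_fit()] but each class keeps its own covariance; the decision
#' score adds the log-determinant of the class covariance.
#'
#' @inheritParams lda_fit
#' @return Object of class `c("pca_qda", "discriminant_model")`.
#' @export
qda_fit <- function(x, labels) {
  x <- as.matrix(x); labels <- check_labels(labels)
  st <- class_stats(x, labels)
  n <- nrow(x)
  covs <- lapply(st, function(s) stabilize_cov(s$cov))
  structure(list(means = list(control = st$control$mean, case = st$case$mean),
                 covs = list(control = covs$control$S, case = covs$case$S),
                 ridged = covs$control$ridged || covs$case$ridged,
                 priors = c(control = st$control$n / n, case = st$case$n / n)),
            class = c("pca_qda", "discriminant_model"))
}

mahal_sq <- function(x, mu, S) {
  d <- sweep(x, 2, mu)
  rowSums(d * t(solve(S, t(d))))
}

# decision scores: smaller = preferred; ties -> control
decide <- function(g_control, g_case) {
  ifelse(g_case < g_control, "case", "control")
}

#' @export
predict.pca_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  g <- lapply(c("control", "case"), function(cl)
    mahal_sq(newdata, object$means[[cl]], object$cov) -
      2 * log(object$priors[[cl]]))
  factor(decide(g[[1]], g[[2]]), levels = c("control", "case"))
}

#' @export
predict.pca_qda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  g <- lapply(c("control", "case"), function(cl)
    mahal_sq(newdata, object$means[[cl]], object$covs[[cl]]) +
      determinant(object$covs[[cl]])$modulus -
      2 * log(object$priors[[cl]]))
  factor(decide(g[[1]], g[[2]]), levels = c("control", "case"))
}

#' Radial-basis-function support vector machine
#'
#' Soft-margin kernel machine on PCA scores. The kernel computation is
#' delegated to \pkg{e1071}; hyperparameters default to an inner 5-fold
#' grid search over `C` in \{0.1, 1, 10, 100\} and `gamma` in
#' \{0.1, 1, 10\}/m (m = number of score dimensions), seeded for
#' reproducibility.
#'
#' @inheritParams lda_fit
#' @param C,gamma Fixed hyperparameters; when `NULL` they are chosen by
#'   the inner grid search.
#' @param inner_folds Folds of the inner search (default 5).
#' @param seed Seed for the inner-search fold assignment.
#' @return Object of class `c("pca_svm", "discriminant_model")`.
#' @export
svm_rbf_fit <- function(x, labels, C = NULL, gamma = NULL,
                        inner_folds = 5, seed = 1L) {
  x <- as.matrix(x); labels <- check_labels(labels)
  y <- factor(labels, levels = c("control", "case"))
  m <- ncol(x)
  if (is.null(C) || is.null(gamma)) {
    grid <- expand.grid(C = c(0.1, 1, 10, 100), gamma = c(0.1, 1, 10) / m)
    folds <- kfold_split(length(y), k = min(inner_folds, length(y)), seed = seed)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      ok <- 0L
      for (f in sort(unique(folds))) {
        tr <- folds != f; te <- !tr
        if (length(unique(y[tr])) < 2) next
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                          kernel = "radial", cost = grid$C[g],
                          gamma = grid$gamma[g], scale = FALSE)
        ok <- ok + sum(predict(fit, x[te, , drop = FALSE]) == y[te])
      }
      ok / length(y)
    }, numeric(1))
    best <- which.max(acc)   # ties: first (smallest C, then gamma) wins
    C <- grid$C[best]; gamma <- grid$gamma[best]
  }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(svm = fit, C = C, gamma = gamma),
            class = c("pca_svm", "discriminant_model"))
}

#' @export
predict.pca_svm <- function(object, newdata, ...) {
  p <- predict(object$svm, as.matrix(newdata))
  factor(as.character(p), levels = c("control", "case"))
}

#' Partial least squares discriminant analysis
#'
#' Regresses the 0/1 class indicator (case = 1) on the full spectra via
#' [pls_fit()]; a spectrum is predicted `"case"` when the continuous
#' output exceeds `threshold` (default 0.5, the midpoint of the
#' indicator coding).
#'
#' @param x Preprocessed spectra (rows = spectra).
#' @param labels `"case"`/`"control"` labels.
#' @param n_lv Number of latent variables.
#' @param threshold Decision threshold on the continuous output.
#' @return Object of class `c("pls_da", "discriminant_model")`.
#' @export
plsda_fit <- function(x, labels, n_lv = 2, threshold = 0.5) {
  labels <- check_labels(labels)
  y <- as.numeric(labels == "case")
  pls <- pls_fit(x, y, n_lv)
  structure(list(pls = pls, threshold = threshold),
            class = c("pls_da", "discriminant_model"))
}

#' @export
predict.pls_da <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  yhat <- predict(object$pls, newdata)
  if (type == "response") return(yhat)
  factor(ifelse(yhat > object$threshold, "case", "control"),
         levels = c("control", "case"))
}
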