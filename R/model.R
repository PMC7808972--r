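#' Fit a Raman diagnostic classifier
#'
#' The package's central fitting function: preprocesses labelled spectra
#' with one of the three standard chains, mean-centres, reduces to PCA
#' scores (except for PLS-DA, which consumes the full spectra) and fits
#' one of the four discriminant models. The returned object predicts
#' class labels for new raw spectra through the identical chain, using
#' only state learned from the training data (EMSC reference, centring
#' means, PCA basis).
#'
#' @param x Training spectra: a [spectrum_matrix()] (labels from its
#'   metadata) or a numeric matrix plus `labels`.
#' @param labels Optional `"case"`/`"control"` labels overriding the
#'   metadata.
#' @param pipeline [preprocess_pipeline()] or its name (default
#'   `"emsc_baseline"`, the chain with the best discrimination on
#'   biofluid data).
#' @param model `"pca_lda"` (default), `"pca_qda"`, `"pca_svm"` or
#'   `"pls_da"`.
#' @param n_pc Number of PCs for score-based models (`NULL` = smallest
#'   number explaining 95% of variance, capped at 10).
#' @param n_lv Latent variables for PLS-DA.
#' @param seed Seed for the SVM hyperparameter search.
#' @return An object of class `raman_classifier` with `print`,
#'   `summary` and `predict` methods.
#' @export
raman_classifier <- function(x, labels = NULL,
                             pipeline = "emsc_baseline",
                             model = c("pca_lda", "pca_qda", "pca_svm", "pls_da"),
                             n_pc = NULL, n_lv = 2, seed = 1L) {
  model <- match.arg(model)
  if (is.character(pipeline)) pipeline <- preprocess_pipeline(pipeline)
  xm <- as_x(x)
  if (is.null(labels)) {
    stopifnot(inherits(x, "spectrum_matrix"))
    labels <- x$meta$class
  }
  labels <- check_labels(labels)
  axis <- if (inherits(x, "spectrum_matrix")) x$axis else seq_len(ncol(xm))
  ref <- NULL
  if (pipeline$name == "emsc_baseline")
    ref <- colMeans(as_x(savgol_smooth(xm, pipeline$sg_window,
                                       pipeline$sg_polyorder)))
  xp <- as_x(apply_pipeline(xm, pipeline, emsc_reference = ref))
  mu <- colMeans(xp)
  xc <- sweep(xp, 2, mu)
  pca <- NULL
  fit <- if (model == "pls_da") {
    plsda_fit(xc, labels, n_lv = n_lv)
  } else {
    k <- if (is.null(n_pc)) select_n_pc(xc) else n_pc
    pca <- pca_fit(xc, k)
    switch(model,
      pca_lda = lda_fit(pca$scores, labels),
      pca_qda = qda_fit(pca$scores, labels),
      pca_svm = svm_rbf_fit(pca$scores, labels, seed = seed))
  }
  structure(list(model = model, pipeline = pipeline, fit = fit,
                 pca = pca, center = mu, emsc_reference = ref,
                 axis = axis, labels = labels,
                 training_x = xc, seed = seed),
            class = "raman_classifier")
}

#' Predict method for raman_classifier
#'
#' Applies the training preprocessing chain (with the stored EMSC
#' reference and centring means) to new raw spectra and predicts class
#' labels.
#'
#' @param object A [raman_classifier()] fit.
#' @param newdata Raw spectra on the training axis.
#' @param ... Unused.
#' @return Factor of `"control"`/`"case"` predictions.
#' @export
predict.raman_classifier <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1)
  xm <- as_x(newdata)
  xp <- as_x(apply_pipeline(xm, object$pipeline,
                            emsc_reference = object$emsc_reference))
  xc <- sweep(xp, 2, object$center)
  if (object$model == "pls_da") return(predict(object$fit, xc))
  predict(object$fit, pca_transform(object$pca, xc))
}

#' @export
print.raman_classifier <- function(x, ...) {
  cat("Raman diagnostic classifier\n")
  cat("  model:", x$model, " preprocessing:", x$pipeline$name, "\n")
  if (!is.null(x$pca))
    cat("  PCA:", x$pca$k, "components,",
        sprintf("%.1f%%", 100 * sum(x$pca$explained_variance_fraction)),
        "variance\n")
  cat("  training:", length(x$labels), "spectra (",
      sum(x$labels == "case"), "case /", sum(x$labels == "control"),
      "control )\n")
  invisible(x)
}

#' @export
summary.raman_classifier <- function(object, ...) {
  tr_pred <- if (object$model == "pls_da") predict(object$fit, object$training_x)
             else predict(object$fit, object$pca$scores)
  rep_ <- compute_metrics(confusion_counts(object$labels, tr_pred))
  rep_$model <- object$model
  rep_$pipeline <- object$pipeline$name
  cat("Training (resubstitution) performance — optimistic; use",
      "cross_validate() for honest estimates\n")
  print(rep_)
  invisible(rep_)
}

#' Plot mean class spectra and the DBM for a fitted classifier
#'
#' @param x A [raman_classifier()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the DBM spectrum.
#' @export
plot.raman_classifier <- function(x, ...) {
  xc <- x$training_x
  mc <- colMeans(xc[x$labels == "case", , drop = FALSE])
  mn <- colMeans(xc[x$labels == "control", , drop = FALSE])
  graphics::matplot(x$axis, cbind(mc, mn, mc - mn), type = "l",
                    lty = c(1, 1, 2), col = c("firebrick", "navy", "grey30"),
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "Preprocessed intensity (centred)", ...)
  graphics::legend("topright", c("case mean", "control mean", "DBM"),
                   lty = c(1, 1, 2), col = c("firebrick", "navy", "grey30"),
                   bty = "n")
  invisible(mc - mn)
}
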