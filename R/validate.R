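#' k-fold split
#'
#' Partitions units into k folds of sizes differing by at most one.
#' With `unit = "spectrum"` rows are assigned directly; with
#' `unit = "patient"` all spectra of a patient stay in one fold
#' (requires `patient_ids`). Spectrum-level folding is the default,
#' matching classification on a spectral basis; patient-level folding
#' avoids the leakage of splitting one patient's spectra across folds.
#'
#' @param n_rows Number of rows to assign.
#' @param k Number of folds (default 10); must not exceed the number of
#'   units.
#' @param unit `"spectrum"` or `"patient"`.
#' @param patient_ids Patient id per row (required for
#'   `unit = "patient"`).
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
kfold_split <- function(n_rows, k = 10, unit = c("spectrum", "patient"),
                        patient_ids = NULL, seed = 1L) {
  unit <- match.arg(unit)
  set.seed(seed)
  if (unit == "spectrum") {
    if (k > n_rows) stop("k = ", k, " exceeds number of spectra ", n_rows)
    folds <- integer(n_rows)
    folds[sample.int(n_rows)] <- rep_len(seq_len(k), n_rows)
    return(folds)
  }
  if (is.null(patient_ids) || length(patient_ids) != n_rows)
    stop("patient-level folding needs one patient id per row")
  pats <- unique(patient_ids)
  if (k > length(pats)) stop("k = ", k, " exceeds number of patients ",
                             length(pats))
  pf <- integer(length(pats))
  pf[sample.int(length(pats))] <- rep_len(seq_len(k), length(pats))
  pf[match(patient_ids, pats)]
}

#' Confusion counts from label vectors
#'
#' @param truth,pred Factors or character vectors of `"case"`/
#'   `"control"` labels; `"case"` is the positive class.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == "case" & pred == "case"),
    TN = sum(truth == "control" & pred == "control"),
    FP = sum(truth == "control" & pred == "case"),
    FN = sum(truth == "case" & pred == "control"))
}

#' F-score from sensitivity and specificity
#'
#' The harmonic mean `2 * SENS * SPEC / (SENS + SPEC)` of sensitivity
#' and specificity in percent — the overall-performance summary used
#' for imbalanced diagnostic data (not the precision/recall F1).
#'
#' @param sens,spec Sensitivity and specificity, in percent.
#' @return F-score in percent (`NA` if both are zero).
#' @export
f_score <- function(sens, spec) {
  ifelse(sens + spec == 0, NA_real_, 2 * sens * spec / (sens + spec))
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FP+TN+FN) x 100; Sensitivity = TP/(TP+FN) x
#' 100; Specificity = TN/(TN+FP) x 100; F-score = harmonic mean of
#' sensitivity and specificity. Metrics whose denominator is zero are
#' `NA` and flagged. Values are carried at full precision with an
#' integer-rounded copy for display.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (non-negative).
#' @return Object of class `metrics_report` with elements `counts`,
#'   `metrics` (full precision), `rounded`, `undefined`.
#' @export
compute_metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative TP, TN, FP, FN")
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  acc <- if (total > 0) (tp + tn) / total * 100 else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  f <- if (!is.na(sens) && !is.na(spec)) f_score(sens, spec) else NA_real_
  metrics <- c(accuracy = acc, sensitivity = sens, specificity = spec,
               f_score = f)
  structure(list(counts = counts, metrics = metrics,
                 rounded = round(metrics),
                 undefined = names(metrics)[is.na(metrics)]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion counts: TP =", x$counts[["TP"]], " TN =", x$counts[["TN"]],
      " FP =", x$counts[["FP"]], " FN =", x$counts[["FN"]], "\n")
  m <- x$metrics
  cat(sprintf("Accuracy %.1f%%  Sensitivity %.1f%%  Specificity %.1f%%  F-score %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["f_score"]))
  if (!is.null(x$model)) cat("Model:", x$model, " pipeline:", x$pipeline,
                             " k =", x$k, " seed =", x$seed, "\n")
  invisible(x)
}

# fit + predict one discriminant model inside a fold.
# score-based models get PCA reduction; PLS-DA uses the full spectra.
fit_predict_fold <- function(model, x_tr, y_tr, x_te, n_pc, n_lv, seed) {
  if (model == "pls_da") {
    fit <- plsda_fit(x_tr, y_tr, n_lv = n_lv)
    return(predict(fit, x_te))
  }
  k <- if (is.null(n_pc)) select_n_pc(x_tr) else n_pc
  pm <- pca_fit(x_tr, k)
  s_tr <- pm$scores
  s_te <- pca_transform(pm, x_te)
  fit <- switch(model,
    pca_lda = lda_fit(s_tr, y_tr),
    pca_qda = qda_fit(s_tr, y_tr),
    pca_svm = svm_rbf_fit(s_tr, y_tr, seed = seed),
    stop("unknown model: ", model))
  predict(fit, s_te)
}

#' Cross-validated diagnostic metrics
#'
#' Runs k-fold cross-validation of one or more discriminant models on
#' raw (already reduced, spike-free) spectra. All data-dependent state —
#' EMSC reference, mean centring, PCA basis, PLS fit, SVM hyperparameter
#' search — is learned on the training rows of each fold only; test
#' predictions are pooled into a single confusion table.
#'
#' @param sm A [spectrum_matrix()] (labels taken from its metadata) or a
#'   numeric matrix plus `labels`.
#' @param labels Optional label vector overriding the metadata.
#' @param models Character vector from `"pca_lda"`, `"pca_qda"`,
#'   `"pca_svm"`, `"pls_da"`.
#' @param pipeline [preprocess_pipeline()] or name, applied inside each
#'   fold.
#' @param k Number of folds (default 10).
#' @param unit Fold unit, `"spectrum"` (default) or `"patient"`.
#' @param n_pc Number of PCs for score-based models (`NULL` = smallest
#'   number explaining 95% of training-fold variance, capped at 10).
#' @param n_lv Latent variables for PLS-DA (default 2).
#' @param seed Seed for the fold assignment and SVM inner search.
#' @return A `metrics_report` for a single model, or a named list of
#'   them for several; each carries `model`, `pipeline`, `k`, `seed`,
#'   `folds` fields.
#' @export
cross_validate <- function(sm, labels = NULL, models = "pca_lda",
                           pipeline = "emsc_baseline", k = 10,
                           unit = c("spectrum", "patient"),
                           n_pc = NULL, n_lv = 2, seed = 1L) {
  unit <- match.arg(unit)
  x <- as_x(sm)
  if (is.null(labels)) {
    stopifnot(inherits(sm, "spectrum_matrix"))
    labels <- sm$meta$class
  }
  labels <- check_labels(labels)
  pids <- if (inherits(sm, "spectrum_matrix")) sm$meta$patient_id else NULL
  if (is.character(pipeline)) pipeline <- preprocess_pipeline(pipeline)
  folds <- kfold_split(nrow(x), k = k, unit = unit, patient_ids = pids,
                       seed = seed)
  stateless <- pipeline$name != "emsc_baseline"
  if (stateless)
    x_pre_all <- as_x(apply_pipeline(
      if (inherits(sm, "spectrum_matrix")) sm else x, pipeline))
  preds <- stats::setNames(
    lapply(models, function(m) rep(NA_character_, nrow(x))), models)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[tr])) < 2 || min(table(labels[tr])) < 2)
      stop("fold ", f, ": training rows must contain both classes ",
           "(>= 2 spectra each)")
    if (stateless) {
      x_tr <- x_pre_all[tr, , drop = FALSE]
      x_te <- x_pre_all[te, , drop = FALSE]
    } else {
      # EMSC reference from the SG-smoothed training rows only
      sm_tr <- savgol_smooth(x[tr, , drop = FALSE],
                             pipeline$sg_window, pipeline$sg_polyorder)
      ref <- colMeans(sm_tr)
      x_tr <- as_x(apply_pipeline(x[tr, , drop = FALSE], pipeline,
                                  emsc_reference = ref))
      x_te <- as_x(apply_pipeline(x[te, , drop = FALSE], pipeline,
                                  emsc_reference = ref))
    }
    mu <- colMeans(x_tr)
    x_tr <- sweep(x_tr, 2, mu); x_te <- sweep(x_te, 2, mu)
    for (m in models)
      preds[[m]][te] <- as.character(
        fit_predict_fold(m, x_tr, labels[tr], x_te, n_pc, n_lv,
                         seed = seed + f))
  }
  reports <- lapply(models, function(m) {
    rep_ <- compute_metrics(confusion_counts(labels, preds[[m]]))
    rep_$model <- m; rep_$pipeline <- pipeline$name
    rep_$k <- k; rep_$seed <- seed; rep_$folds <- folds
    rep_$predictions <- preds[[m]]
    rep_
  })
  names(reports) <- models
  if (length(models) == 1) reports[[1]] else reports
}
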