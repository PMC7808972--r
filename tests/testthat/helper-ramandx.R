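# Shared fixtures, all generated in code.

# a small cohort that keeps unit tests fast
small_config <- function(seed = 1, ...) {
  cohort_config(n_case = 4, n_control = 4, grid_rows = 5, grid_cols = 4,
                seed = seed, ...)
}

# build a labelled spectrum_matrix directly from a matrix
sm_from_matrix <- function(x, axis = seq_len(ncol(x)) + 724,
                           classes = rep("control", nrow(x)),
                           sample_ids = rep("S01", nrow(x)),
                           patient_ids = sample_ids) {
  spectrum_matrix(axis, x,
                  data.frame(sample_id = sample_ids, patient_id = patient_ids,
                             class = classes, stringsAsFactors = FALSE))
}

# brute-force Savitzky-Golay oracle: local polynomial regression at
# interior point i
local_polyfit <- function(y, i, window, polyorder, deriv = 0) {
  h <- (window - 1) / 2
  idx <- (i - h):(i + h)
  t <- idx - i
  fit <- stats::lm(y[idx] ~ stats::poly(t, polyorder, raw = TRUE))
  cf <- stats::coef(fit)
  if (deriv == 0) unname(cf[1]) else unname(cf[2])  # value / slope at t = 0
}

# recovery bookkeeping for biomarker tests
planted_hits <- function(bm, bands = c(1004, 1334, 1448, 1657), tol = 5) {
  vapply(bands, function(w) {
    i <- which(abs(bm$wavenumber - w) <= tol)
    length(i) > 0 && bm$direction[i[1]] == "lower_in_case"
  }, logical(1))
}
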