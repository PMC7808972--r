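test_that("DBM spectrum is the antisymmetric case-control mean difference", {
  set.seed(50)
  x <- matrix(rnorm(200), 20, 10)
  labels <- rep(c("case", "control"), each = 10)
  d <- dbm_spectrum(x, labels)
  expect_equal(as.numeric(d),
               colMeans(x[1:10, ]) - colMeans(x[11:20, ]), tolerance = 1e-12)
  swapped <- ifelse(labels == "case", "control", "case")
  expect_equal(as.numeric(dbm_spectrum(x, swapped)), -as.numeric(d),
               tolerance = 1e-12)
  # identical class means give a zero spectrum
  x2 <- rbind(x[1:10, ], x[1:10, ])
  expect_equal(as.numeric(dbm_spectrum(x2, labels)), rep(0, 10))
  expect_error(dbm_spectrum(x, rep("case", 20)), "both classes")
})

test_that("DBM is negative at a planted case-attenuated band", {
  cfg <- small_config(seed = 51)
  co <- simulate_cohort(cfg)
  sm <- block_average(unfold_cohort(co), 10)
  p <- apply_pipeline(sm, "emsc_baseline")
  d <- dbm_spectrum(p)
  expect_lt(d[which(p$axis == 1004)], 0)
})

test_that("peak detection honours prominence and separation rules", {
  ax <- seq(725, 1024)
  g <- function(c, w, a) a * exp(-log(2) * ((ax - c) / w)^2)
  one <- g(850, 8, 1)
  pk <- detect_peaks(one, ax, min_prominence = 0.5)
  expect_length(pk, 1)
  expect_lte(abs(pk[1] - 850), 1)
  # two bumps 3 cm^-1 apart: only the larger survives a 10 cm^-1 window
  two <- g(900, 4, 1) + g(903, 4, 0.6)
  pk2 <- detect_peaks(two, ax, min_prominence = 0.1, min_separation = 10)
  expect_length(pk2, 1)
  expect_lte(abs(pk2[1] - 900), 2)
  # magnitude ordering and negative peaks via |y|
  mix <- g(800, 6, 0.5) - g(950, 6, 1.2)
  pk3 <- detect_peaks(mix, ax, min_prominence = 0.2)
  expect_equal(as.numeric(round(pk3)), c(950, 800), tolerance = 1)
  expect_equal(sign(attr(pk3, "height")), c(-1, 1))
  expect_length(detect_peaks(rep(0, 300), ax, min_prominence = 1), 0)
})

test_that("coincidence rule requires matched DBM and loading peaks", {
  ax <- seq(725, 1124)
  g <- function(c, w, a) a * exp(-log(2) * ((ax - c) / w)^2)
  set.seed(52)
  n <- 40
  labels <- rep(c("case", "control"), each = n / 2)
  # class effect at 900 only; unmatched DBM structure at 1050
  base <- g(800, 10, 1) + g(900, 8, 1) + g(1050, 9, 0.8)
  x <- t(sapply(labels, function(cl)
    base - (cl == "case") * 0.3 * g(900, 8, 1) + rnorm(length(ax), 0, 0.01)))
  loadings <- g(900, 8, 1)   # loading peak only near 900
  bm <- coincident_biomarkers(x, labels, ax, loadings = loadings,
                              dbm_prominence = 0.05,
                              loading_prominence = 0.05)
  expect_equal(nrow(bm), 1)
  expect_lte(abs(bm$wavenumber - 900), 2)
  expect_equal(bm$direction, "lower_in_case")
  expect_lt(bm$p_value, 0.001)
  # no loading peak within tolerance -> excluded
  far <- g(1050, 9, 1)
  bm2 <- coincident_biomarkers(x, labels, ax, loadings = far,
                               dbm_prominence = 0.05,
                               loading_prominence = 0.05, tolerance = 5)
  expect_false(any(abs(bm2$wavenumber - 900) <= 5))
  # zero-effect data: the planted band must not reappear
  x0 <- t(sapply(labels, function(cl) base + rnorm(length(ax), 0, 0.01)))
  bm0 <- coincident_biomarkers(x0, labels, ax, loadings = loadings,
                               dbm_prominence = 0.05,
                               loading_prominence = 0.05)
  expect_true(nrow(bm0) == 0 || all(bm0$p_value > 1e-4))
})

test_that("per-wavenumber ANOVA matches aov and is affine invariant", {
  set.seed(53)
  x <- matrix(rnorm(30 * 8), 30, 8)
  labels <- rep(c("case", "control"), times = c(14, 16))
  an <- anova_pvalues(x, labels, axis = 1:8)
  for (j in c(1, 4, 8)) {
    ref <- summary(stats::aov(x[, j] ~ factor(labels)))[[1]]
    expect_equal(an$statistic[j], ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(an$p_value[j], ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # F equals the squared pooled t statistic
  tstat <- stats::t.test(x[labels == "case", 2], x[labels == "control", 2],
                         var.equal = TRUE)$statistic
  expect_equal(an$statistic[2], unname(tstat)^2, tolerance = 1e-10)
  # affine rescaling leaves p-values untouched
  an2 <- anova_pvalues(3 * x + 7, labels, axis = 1:8)
  expect_equal(an2$p_value, an$p_value, tolerance = 1e-10)
  # degenerate column flagged
  xz <- x; xz[, 3] <- 5
  expect_true(anova_pvalues(xz, labels, axis = 1:8)$degenerate[3])
})

test_that("null ANOVA p-values are uniform across wavenumbers", {
  set.seed(54)
  x <- matrix(rnorm(60 * 400), 60, 400)
  labels <- rep(c("case", "control"), each = 30)
  p <- anova_pvalues(x, labels, axis = seq_len(400))$p_value
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("two-group MANOVA collapses to ANOVA in 1-D and matches manova in 3-D", {
  set.seed(55)
  y <- c(rnorm(20, 0), rnorm(25, 0.8))
  labels <- rep(c("control", "case"), times = c(20, 25))
  mv <- manova_scores(matrix(y, ncol = 1), labels)
  ref <- summary(stats::aov(y ~ factor(labels)))[[1]]
  expect_equal(mv$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mv$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  # 3-D against the base-R Wilks test
  s <- matrix(rnorm(60 * 3), 60, 3)
  s[1:30, 1] <- s[1:30, 1] + 1
  lab3 <- rep(c("case", "control"), each = 30)
  mv3 <- manova_scores(s, lab3)
  ref3 <- summary(stats::manova(s ~ factor(lab3)), test = "Wilks")$stats
  expect_equal(mv3$statistic, ref3[1, "Wilks"], tolerance = 1e-8)
  expect_equal(mv3$F, ref3[1, "approx F"], tolerance = 1e-8)
  expect_equal(mv3$p_value, ref3[1, "Pr(>F)"], tolerance = 1e-8)
  # extreme separation reports the representable lower bound
  s2 <- s; s2[lab3 == "case", ] <- s2[lab3 == "case", ] + 100
  expect_gt(manova_scores(s2, lab3)$p_value, 0)
  expect_lt(manova_scores(s2, lab3)$p_value, 1e-60)
  few <- c(1:4, 31:34)   # both groups present but too small for p = 3
  expect_error(manova_scores(s[few, ], lab3[few]), "members")
})

test_that("SNR scales inversely with noise and diverges without noise", {
  ax <- seq(725, 1224)
  band <- 5 * exp(-log(2) * ((ax - 900) / 10)^2)
  expect_equal(snr_estimate(band, ax, c(860, 940), c(1100, 1200)), Inf)
  set.seed(56)
  snr_at <- function(sd) {
    mean(replicate(30, {
      y <- band + rnorm(length(ax), 0, sd)
      snr_estimate(y, ax, c(860, 940), c(1100, 1200))
    }))
  }
  r1 <- snr_at(0.05); r2 <- snr_at(0.10)
  expect_gt(r1 / r2, 1.6); expect_lt(r1 / r2, 2.4)
  # pure noise: order-one ratio
  y0 <- rnorm(length(ax), 0, 0.1)
  expect_lt(snr_estimate(y0, ax, c(860, 940), c(1100, 1200)), 10)
  expect_error(snr_estimate(band, ax, c(860, 940), c(900, 1000)), "disjoint")
})
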