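test_that("degree-1 SG smoothing equals the moving average; oracle agrees", {
  set.seed(6)
  y <- sin(seq(0, 6, length.out = 200)) + rnorm(200, 0, 0.1)
  sm <- savgol_smooth(matrix(y, 1), window = 7, polyorder = 1)[1, ]
  ma <- stats::filter(y, rep(1 / 7, 7))
  interior <- 4:197
  expect_equal(sm[interior], ma[interior], tolerance = 1e-12,
               ignore_attr = TRUE)
  # brute-force local polynomial regression at random interior points
  for (polyorder in c(1, 2)) {
    sg <- savgol_smooth(matrix(y, 1), 7, polyorder)[1, ]
    for (i in sample(10:190, 20))
      expect_equal(sg[i], local_polyfit(y, i, 7, polyorder),
                   tolerance = 1e-10)
  }
  # constant spectrum unchanged
  expect_equal(savgol_smooth(matrix(3, 1, 50), 7, 1)[1, ], rep(3, 50))
  expect_error(savgol_smooth(matrix(y, 1), window = 6), "odd")
})

test_that("SG derivative is exact on polynomials and locates band centres", {
  ax <- seq(725, 924)
  const <- savgol_derivative(matrix(5, 1, 200), step = 1)[1, ]
  expect_equal(const, rep(0, 200), tolerance = 1e-12)
  lin <- savgol_derivative(matrix(2 + 0.3 * ax, 1), step = 1)[1, ]
  expect_equal(lin[4:197], rep(0.3, 194), tolerance = 1e-10)
  # derivative of a gaussian crosses zero at the centre +/- 1 step
  g <- exp(-log(2) * ((ax - 800) / 15)^2)
  dg <- savgol_derivative(matrix(g, 1), step = 1)[1, ]
  cross <- ax[which(diff(sign(dg)) != 0)]
  expect_true(any(abs(cross - 800) <= 1))
  expect_error(savgol_derivative(matrix(g, 1), polyorder = 1, deriv = 2),
               "polyorder")
})

test_that("AWLS recovers planted polynomial baselines", {
  ax <- seq(725, 1813)
  t <- 2 * (ax - 725) / (1813 - 725) - 1
  cubic <- 1 + 0.5 * t - 2 * t^2 + 1.5 * t^3
  # baseline-only input: corrected ~ 0
  r <- awls_baseline(cubic, ax, order = 3)
  expect_lt(max(abs(r$corrected)), 1e-6 * diff(range(cubic)))
  expect_true(r$converged)
  # cubic + positive narrow peaks: baseline within 1% off-peak
  peaks <- 3 / (1 + ((ax - 1000) / 6)^2) + 2 / (1 + ((ax - 1500) / 8)^2)
  r2 <- awls_baseline(cubic + peaks, ax, order = 3)
  off <- abs(ax - 1000) > 60 & abs(ax - 1500) > 60
  expect_lt(max(abs(r2$baseline - cubic)[off]), 0.01 * diff(range(cubic)))
  # all-zero spectrum
  r0 <- awls_baseline(rep(0, 100))
  expect_equal(r0$corrected, rep(0, 100))
  expect_equal(r0$baseline, rep(0, 100))
  # monotone-safe: baseline never exceeds spectrum by more than a whisker
  expect_true(all(r2$baseline <= cubic + peaks + 0.01 * diff(range(cubic))))
})

test_that("batched AWLS equals the single-spectrum reference", {
  set.seed(7)
  ax <- seq(725, 924)
  x <- t(replicate(6, {
    t <- seq(-1, 1, length.out = 200)
    rnorm(1, 2) + 2 * t^3 + 1.5 / (1 + ((ax - 800) / 5)^2) + rnorm(200, 0, 0.05)
  }))
  single <- t(sapply(seq_len(6), function(i) awls_baseline(x[i, ], ax)$corrected))
  batched <- ramandx:::awls_correct(sm_from_matrix(x, axis = ax))$x
  expect_equal(batched, single, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("EMSC inverts gain, offset and polynomial drift corruption", {
  set.seed(8)
  ax <- seq(725, 1124)
  t <- 2 * (ax - min(ax)) / diff(range(ax)) - 1
  ref <- 1 / (1 + ((ax - 900) / 20)^2) + 0.6 / (1 + ((ax - 1050) / 10)^2)
  # reference itself comes back unchanged with (a, b, d) = (0, 1, 0)
  out <- emsc_correct(rbind(ref, ref), reference = ref)
  fits <- attr(out, "emsc_fits")
  expect_equal(unname(as.matrix(out)), rbind(ref, ref), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fits$a, c(0, 0), tolerance = 1e-8)
  expect_equal(fits$b, c(1, 1), tolerance = 1e-8)
  # forced analytic inversion
  x <- 2.5 * ref + 3
  out2 <- emsc_correct(matrix(x, 1), reference = ref)
  expect_equal(out2[1, ], ref, tolerance = 1e-8, ignore_attr = TRUE)
  # random gain / offset / quadratic drift
  n <- 8
  gains <- runif(n, 0.5, 2); offs <- rnorm(n, 0, 2)
  d1 <- rnorm(n); d2 <- rnorm(n)
  corrupted <- t(sapply(seq_len(n), function(i)
    gains[i] * ref + offs[i] + d1[i] * t + d2[i] * t^2))
  out3 <- emsc_correct(corrupted, reference = ref)
  for (i in seq_len(n))
    expect_equal(out3[i, ], ref, tolerance = 1e-8, ignore_attr = TRUE)
  # near-zero multiplicative coefficient is rejected with the row index
  expect_error(emsc_correct(matrix(0 * ref + 1, 1), reference = ref), "1")
})

test_that("vector normalisation yields unit, scale-invariant rows", {
  set.seed(9)
  x <- matrix(rnorm(40), 4, 10)
  v <- vector_normalize(x)
  expect_equal(sqrt(rowSums(v^2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(vector_normalize(10 * x), v, tolerance = 1e-12)
  q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[1:3, ]  # orthogonal rows
  vq <- vector_normalize(q)
  expect_equal(tcrossprod(vq), diag(3), tolerance = 1e-10)
  x0 <- x; x0[2, ] <- 0
  expect_error(vector_normalize(x0), "2")
})

test_that("mean centring stores reusable training means", {
  set.seed(10)
  x <- matrix(rnorm(60, 5), 6, 10)
  c1 <- mean_center(x)
  expect_lt(max(abs(colMeans(c1))), 1e-12)
  expect_equal(mean_center(c1) + 0, c1 + 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  # leakage guard: training means applied to held-out rows leave a
  # nonzero residual mean
  tr <- x[1:4, ]; te <- x[5:6, ]
  cent <- apply_center(te, attr(mean_center(tr), "column_means"))
  expect_gt(max(abs(colMeans(cent))), 1e-6)
})

test_that("the three pipelines satisfy their stage contracts", {
  co <- simulate_cohort(small_config(seed = 12))
  sm <- block_average(unfold_cohort(co), 10)
  bn <- apply_pipeline(sm, "baseline_norm")
  expect_equal(sqrt(rowSums(bn$x^2)), rep(1, nrow(bn$x)), tolerance = 1e-12)

  # emsc_baseline collapses gain-corrupted copies of one spectrum
  y <- sm$x[1, ]
  copies <- outer(c(0.6, 1, 1.7, 2.4), y)
  extra <- rbind(copies, sm$x[2:5, ])   # context rows keep the fit honest
  eb <- apply_pipeline(sm_from_matrix(extra, axis = sm$axis), "emsc_baseline",
                       emsc_reference = y)
  spread <- apply(eb$x[1:4, ], 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-6 * diff(range(eb$x[1, ])))

  # first derivative kills constant offsets
  two <- rbind(y, y + 5)
  fd <- apply_pipeline(sm_from_matrix(two, axis = sm$axis), "first_derivative")
  expect_equal(fd$x[1, ], fd$x[2, ], tolerance = 1e-10)

  expect_error(apply_pipeline(sm, "rubber_band"))
})

test_that("pipelines are deterministic and row-permutation equivariant", {
  co <- simulate_cohort(small_config(seed = 13))
  sm <- block_average(unfold_cohort(co), 10)
  for (pl in c("baseline_norm", "emsc_baseline", "first_derivative")) {
    a <- apply_pipeline(sm, pl)
    b <- apply_pipeline(sm, pl)
    expect_identical(a$x, b$x)
    perm <- sample(nrow(sm$x))
    smp <- sm_from_matrix(sm$x[perm, ], axis = sm$axis,
                          classes = sm$meta$class[perm],
                          sample_ids = sm$meta$sample_id[perm])
    # fix the EMSC reference so the permuted run sees identical state
    ref <- if (pl == "emsc_baseline") colMeans(ramandx:::as_x(
      savgol_smooth(sm, 7, 1))) else NULL
    ap <- apply_pipeline(sm, pl, emsc_reference = ref)
    bp <- apply_pipeline(smp, pl, emsc_reference = ref)
    expect_equal(bp$x, ap$x[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("noiseless gain corruption is removed by the matched pipelines", {
  cfg <- small_config(seed = 14, gain_sd = 0.3, noise_sd = 0,
                      baseline_scale = 0, fluor_scale = 0, spike_rate = 0,
                      patient_sd = 0)
  co <- simulate_cohort(cfg)
  sm <- block_average(unfold_cohort(co), 10)
  bn <- apply_pipeline(sm, "baseline_norm")
  # all control rows derive from one profile: unit-norm output identical
  ctrl <- bn$x[bn$meta$class == "control", ]
  expect_lt(max(apply(ctrl, 2, function(col) diff(range(col)))), 1e-8)
})
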