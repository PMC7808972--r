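make_clusters <- function(n = 20, sep = 6, sd = 1, seed = 30) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, -sep / 2, sd), n, 2),
             matrix(rnorm(2 * n, sep / 2, sd), n, 2))
  list(x = x, labels = rep(c("control", "case"), each = n))
}

test_that("LDA separates clusters and matches the brute-force Mahalanobis rule", {
  cl <- make_clusters()
  fit <- lda_fit(cl$x, cl$labels)
  expect_equal(mean(predict(fit, cl$x) == cl$labels), 1)
  # brute force on a 10-point toy set via explicit covariance inverse
  toy <- make_clusters(n = 5, sep = 2, seed = 31)
  f2 <- lda_fit(toy$x, toy$labels)
  Sinv <- solve(f2$cov)
  g <- sapply(c("control", "case"), function(cls) {
    d <- sweep(toy$x, 2, f2$means[[cls]])
    rowSums((d %*% Sinv) * d) - 2 * log(f2$priors[[cls]])
  })
  brute <- ifelse(g[, "case"] < g[, "control"], "case", "control")
  expect_equal(as.character(predict(f2, toy$x)), brute)
  # the same decision values via solve() agree with the explicit inverse
  d <- sweep(toy$x, 2, f2$means$case)
  expect_equal(rowSums(d * t(solve(f2$cov, t(d)))),
               rowSums((d %*% Sinv) * d), tolerance = 1e-8)
  expect_error(lda_fit(cl$x[1:20, ], cl$labels[1:20]), "single class")
})

test_that("exact decision ties go to the control class", {
  x <- rbind(c(-2, 0), c(-1, 1), c(-1, -1), c(2, 0), c(1, 1), c(1, -1))
  labels <- rep(c("control", "case"), each = 3)
  fit <- lda_fit(x, labels)
  expect_equal(as.character(predict(fit, rbind(c(0, 0), c(0, 3)))),
               c("control", "control"))
})

test_that("LDA agrees with an independent reference implementation", {
  cl <- make_clusters(n = 30, sep = 3, seed = 32)
  fit <- lda_fit(cl$x, cl$labels)
  ref <- MASS::lda(cl$x, grouping = factor(cl$labels))
  test <- matrix(rnorm(60, 0, 2), 30, 2)
  expect_equal(as.character(predict(fit, test)),
               as.character(predict(ref, test)$class))
})

test_that("QDA collapses to LDA under identical class covariances", {
  set.seed(33)
  base <- matrix(rnorm(60), 30, 2)
  x <- rbind(base, sweep(base, 2, c(4, -3), `+`))  # exactly equal covariances
  labels <- rep(c("control", "case"), each = 30)
  test <- matrix(rnorm(100, 1, 3), 50, 2)
  expect_equal(as.character(predict(qda_fit(x, labels), test)),
               as.character(predict(lda_fit(x, labels), test)))
})

test_that("QDA handles variance-only separation where LDA cannot", {
  set.seed(34)
  n <- 200
  x <- rbind(matrix(rnorm(2 * n, 0, 0.3), n, 2),
             matrix(rnorm(2 * n, 0, 2.0), n, 2))
  labels <- rep(c("control", "case"), each = n)
  qf <- qda_fit(x, labels); lf <- lda_fit(x, labels)
  xt <- rbind(matrix(rnorm(400, 0, 0.3), 200, 2),
              matrix(rnorm(400, 0, 2.0), 200, 2))
  yt <- rep(c("control", "case"), each = 200)
  expect_gt(mean(predict(qf, xt) == yt), 0.65)
  expect_lt(abs(mean(predict(lf, xt) == yt) - 0.5), 0.15)
  # the quadratic boundary encircles the tight class
  grid_near <- cbind(runif(50, -0.1, 0.1), runif(50, -0.1, 0.1))
  grid_far <- 5 * cbind(cos(seq(0, 2 * pi, length.out = 50)),
                        sin(seq(0, 2 * pi, length.out = 50)))
  expect_true(all(predict(qf, grid_near) == "control"))
  expect_true(all(predict(qf, grid_far) == "case"))
})

test_that("RBF-SVM solves the XOR problem that defeats LDA", {
  set.seed(35)
  n <- 50
  centers <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
  x <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(2 * n, 0, 0.25), n, 2), 2, centers[i, ], `+`)))
  labels <- rep(c("case", "case", "control", "control"), each = n)
  folds <- kfold_split(nrow(x), k = 5, seed = 35)
  pred_svm <- pred_lda <- character(nrow(x))
  for (f in 1:5) {
    tr <- folds != f
    fs <- svm_rbf_fit(x[tr, ], labels[tr], seed = 35)
    pred_svm[!tr] <- as.character(predict(fs, x[!tr, ]))
    fl <- lda_fit(x[tr, ], labels[tr])
    pred_lda[!tr] <- as.character(predict(fl, x[!tr, ]))
  }
  expect_gt(mean(pred_svm == labels), 0.9)
  expect_lt(abs(mean(pred_lda == labels) - 0.5), 0.15)
  # linearly separable data with a large gamma: perfect training fit
  cl <- make_clusters(seed = 36)
  fit <- svm_rbf_fit(cl$x, cl$labels, C = 10, gamma = 5)
  expect_equal(mean(predict(fit, cl$x) == cl$labels), 1)
  # refitting on identical data gives an identical decision function
  fit2 <- svm_rbf_fit(cl$x, cl$labels, C = 10, gamma = 5)
  probe <- matrix(rnorm(40, 0, 3), 20, 2)
  expect_identical(predict(fit, probe), predict(fit2, probe))
})

test_that("PLS-DA thresholds the shared PLS regression core", {
  set.seed(37)
  x <- cbind(c(rnorm(20, -2, 0.3), rnorm(20, 2, 0.3)), matrix(rnorm(160), 40, 4))
  labels <- rep(c("control", "case"), each = 20)
  fit <- plsda_fit(x, labels, n_lv = 1)
  expect_equal(mean(predict(fit, x) == labels), 1)
  # continuous outputs equal the PLS regression oracle
  oracle <- pls_fit(x, as.numeric(labels == "case"), 1)
  expect_equal(predict(fit, x, type = "response"), predict(oracle, x),
               tolerance = 1e-8)
})

test_that("all four classifiers ignore training row order", {
  cl <- make_clusters(n = 15, sep = 3, seed = 38)
  test <- matrix(rnorm(40, 0, 2), 20, 2)
  perm <- sample(nrow(cl$x))
  fits <- list(
    list(lda_fit(cl$x, cl$labels), lda_fit(cl$x[perm, ], cl$labels[perm])),
    list(qda_fit(cl$x, cl$labels), qda_fit(cl$x[perm, ], cl$labels[perm])),
    list(svm_rbf_fit(cl$x, cl$labels, C = 1, gamma = 0.5),
         svm_rbf_fit(cl$x[perm, ], cl$labels[perm], C = 1, gamma = 0.5)),
    list(plsda_fit(cl$x, cl$labels, 1),
         plsda_fit(cl$x[perm, ], cl$labels[perm], 1)))
  for (pair in fits)
    expect_equal(as.character(predict(pair[[1]], test)),
                 as.character(predict(pair[[2]], test)))
})

test_that("label-shuffled PLS-DA cross-validates at chance", {
  set.seed(39)
  x <- matrix(rnorm(600 * 5), 600, 5)
  labels <- sample(rep(c("case", "control"), each = 300))
  folds <- kfold_split(600, k = 10, seed = 39)
  pred <- character(600)
  for (f in 1:10) {
    tr <- folds != f
    fit <- plsda_fit(x[tr, ], labels[tr], n_lv = 2)
    pred[!tr] <- as.character(predict(fit, x[!tr, ]))
  }
  acc <- mean(pred == labels)
  expect_gt(acc, 0.4); expect_lt(acc, 0.6)
})
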