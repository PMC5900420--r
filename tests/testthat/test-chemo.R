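test_that("full-rank PLSR reproduces the least-squares solution", {
  errs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(100), 20, 5)
      y <- rnorm(20)
    })
    b_ols <- qr.solve(cbind(1, X), y)
    m <- fit_plsr(X, y, 5)
    max(abs(c(m$intercept, unname(m$coefficients)) - b_ols))
  }, numeric(1))
  expect_lt(max(errs), 1e-8)
})

test_that("single-predictor PLSR equals the univariate slope", {
  withr::with_seed(3, {
    x <- rnorm(30)
    y <- 2 * x + rnorm(30, 0, 0.1)
  })
  m <- fit_plsr(matrix(x, dimnames = list(NULL, "x")), y, 1)
  expect_equal(unname(m$coefficients), cov(x, y) / var(x),
               tolerance = 1e-12)
})

test_that("constant response yields zero coefficients and mean intercept", {
  withr::with_seed(4, X <- matrix(rnorm(40), 10, 4))
  m <- suppressWarnings(fit_plsr(X, rep(7, 10), 2))
  expect_equal(unname(m$coefficients), rep(0, 4))
  expect_equal(m$intercept, 7)
})

test_that("prediction via coefficients equals the score recursion", {
  for (s in 1:5) {
    withr::with_seed(s, {
      X <- matrix(rnorm(30 * 8), 30, 8)
      y <- X[, 1] - 2 * X[, 3] + rnorm(30, 0, 0.3)
      Xnew <- matrix(rnorm(10 * 8), 10, 8)
    })
    m <- fit_plsr(X, y, 4, scale = s %% 2 == 0)
    expect_equal(predict(m, Xnew), predict_by_recursion(m, Xnew),
                 tolerance = 1e-10)
  }
})

test_that("predicting the calibration mean returns the response mean", {
  withr::with_seed(6, {
    X <- matrix(rnorm(60), 15, 4)
    y <- rnorm(15)
  })
  m <- fit_plsr(X, y, 2)
  expect_equal(predict(m, colMeans(X)), mean(y), tolerance = 1e-12)
})

test_that("prediction matches features by name and reports missing ones", {
  withr::with_seed(7, {
    X <- matrix(rnorm(60), 15, 4,
                dimnames = list(NULL, c("w1", "w2", "w3", "w4")))
    y <- rnorm(15)
  })
  m <- fit_plsr(X, y, 2)
  shuffled <- X[, c(3, 1, 4, 2)]
  expect_equal(predict(m, shuffled), predict(m, X), tolerance = 1e-12)
  expect_error(predict(m, X[, 1:3]), "w4")
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(11, {
    X <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- X[, 2] - X[, 5] + rnorm(40, 0.5)
  })
  m <- fit_plsr(X, y, 3, scale = TRUE)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  pred_ref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(predict(m, X)), unname(pred_ref), tolerance = 1e-6)
})

test_that("LOO cross-validation finds the true latent dimension", {
  withr::with_seed(9, {
    T2 <- matrix(rnorm(80), 40, 2)
    X <- T2 %*% matrix(rnorm(12), 2, 6)
    y <- as.numeric(T2 %*% c(1, -2))
  })
  expect_equal(select_lv_loocv(X, y, 5)$n_lv, 2)
  # trivial case: three samples allow a single component
  withr::with_seed(10, {
    X3 <- matrix(rnorm(9), 3, 3)
    y3 <- rnorm(3)
  })
  expect_equal(select_lv_loocv(X3, y3, 1)$n_lv, 1)
})

test_that("LOO cross-validation stays parsimonious on pure noise", {
  small <- vapply(1:20, function(s) {
    withr::with_seed(300 + s, {
      X <- matrix(rnorm(30 * 10), 30, 10)
      y <- rnorm(30)
    })
    select_lv_loocv(X, y, 8)$n_lv <= 3
  }, logical(1))
  expect_gte(mean(small), 0.9)
})

test_that("outlier screening flags an injected shift and only that", {
  d <- simulate_sparse_bands(n = 40, seed = 12)
  y2 <- d$y
  y2[23] <- y2[23] + 10 * sd(y2)
  flagged <- detect_outliers(d$X, y2, n_lv = 5)
  expect_true(23 %in% flagged)
  expect_identical(detect_outliers(d$X, d$y, n_lv = 5, k_sd = Inf),
                   integer(0))
  clean_runs <- vapply(1:20, function(s) {
    dd <- simulate_sparse_bands(n = 20, seed = 400 + s)
    length(detect_outliers(dd$X, dd$y, n_lv = 5)) == 0
  }, logical(1))
  expect_gte(mean(clean_runs), 0.85)
})

test_that("SPXY returns the reported split sizes", {
  withr::with_seed(13, {
    X <- matrix(rnorm(216 * 5), 216, 5)
    y <- rnorm(216)
  })
  s <- spxy_split(X, y, 2 / 3)
  expect_length(s$calibration_indices, 144)
  expect_length(s$prediction_indices, 72)
  expect_length(intersect(s$calibration_indices, s$prediction_indices), 0)
  expect_setequal(c(s$calibration_indices, s$prediction_indices), 1:216)
})

test_that("SPXY picks the extremes of collinear points (brute-force case)", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  s <- spxy_split(X, c(0, 1, 2), 2 / 3)
  expect_identical(s$calibration_indices, c(1L, 3L))
  expect_identical(s$prediction_indices, 2L)
  # near-unity fraction leaves a single prediction sample
  withr::with_seed(14, Xr <- matrix(rnorm(20), 10, 2))
  s2 <- spxy_split(Xr, rnorm(10), 0.95)
  expect_length(s2$prediction_indices, 1)
})

test_that("SPXY is deterministic and permutation-equivariant", {
  withr::with_seed(15, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- rnorm(40)
    perm <- sample(40)
  })
  s1 <- spxy_split(X, y, 0.6)
  expect_identical(s1, spxy_split(X, y, 0.6))
  s2 <- spxy_split(X[perm, ], y[perm], 0.6)
  expect_setequal(perm[s2$calibration_indices], s1$calibration_indices)
})

test_that("PLS-DA separates well-separated clusters perfectly", {
  d <- make_two_clusters(n_per = 30, delta = 6)
  m <- fit_plsda(d$X, d$labels, 2)
  expect_identical(m$mode, "discriminant")
  cls <- classify_plsda(m, d$X)$class
  expect_equal(classification_accuracy(d$labels, cls), 1)
  # duplicated training row predicts identically
  expect_equal(predict(m, d$X[c(1, 1), ])[1], predict(m, d$X[c(1, 1), ])[2])
  expect_error(fit_plsda(d$X, rep(1L, 60), 2), "both classes")
  expect_error(fit_plsda(d$X, rep(c(0L, 3L), 30), 2), "coded 1 or 2")
})

test_that("permuted labels give chance-level prediction accuracy", {
  acc <- vapply(1:20, function(s) {
    d <- make_two_clusters(n_per = 30, delta = 6, seed = 500 + s)
    perm_labels <- withr::with_seed(s, sample(d$labels))
    tr <- seq_len(40); te <- 41:60
    m <- fit_plsda(d$X[tr, ], perm_labels[tr], 2)
    classification_accuracy(perm_labels[te],
                            classify_plsda(m, d$X[te, ])$class)
  }, numeric(1))
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.65)
})

test_that("the PLS-DA decision rule honours its interval boundaries", {
  m <- make_identity_plsda()
  res <- classify_plsda(m, matrix(c(1.4, 2.6, 1.5, 2.5, 0.5, 0.9),
                                  dimnames = list(NULL, "f1")))
  expect_identical(res$class, c(1L, NA, 1L, 2L, NA, 1L))
  expect_identical(res$valid, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # unclassified counts as incorrect
  expect_equal(classification_accuracy(c(1, 2, 1, 2, 1, 1), res$class),
               4 / 6)
})

test_that("regression metrics match definitions and hand arithmetic", {
  y <- c(1, 2, 3, 4); yh <- c(1.1, 1.9, 3.2, 3.8)
  m <- regression_metrics(y, yh)
  expect_equal(m$rmse, sqrt(sum(c(.1, .1, .2, .2)^2) / 4), tolerance = 1e-12)
  expect_equal(m$r2, 1 - 0.1 / 5, tolerance = 1e-12)
  perf <- regression_metrics(y, y)
  expect_equal(perf$r2, 1); expect_equal(perf$rmse, 0)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)
})

test_that("model JSON round-trips through write/read", {
  withr::with_seed(16, {
    X <- matrix(rnorm(60), 15, 4,
                dimnames = list(NULL, c("505", "534", "673", "704")))
    y <- rnorm(15)
  })
  m <- fit_plsr(X, y, 2)
  path <- file.path(withr::local_tempdir(), "m.json")
  write_pls_model(m, path, metadata = list(note = "round-trip"))
  back <- read_pls_model(path)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
  expect_identical(back$feature_names, m$feature_names)
})
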