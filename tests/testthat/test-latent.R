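test_that("PCA handles degenerate rank, duplicates and reconstruction", {
  # rank-1 data: one latent direction, zero noise
  set.seed(1)
  u <- rnorm(10); v <- rnorm(6)
  X <- outer(u, v) + 5
  dimnames(X) <- list(sprintf("s%02d", 1:10), sprintf("m%02d", 1:6))
  m <- fit_pca(X, scaling = "center_only")
  expect_equal(m$explained_variance_fraction[1], 1)
  # duplicated sample rows give identical score rows
  X2 <- rbind(X, X[1, , drop = FALSE])
  rownames(X2)[11] <- "dup"
  m2 <- fit_pca(X2, scaling = "center_only")
  expect_equal(unname(m2$scores["dup", ]), unname(m2$scores["s01", ]))
  # full-rank reconstruction of the centered/scaled matrix
  set.seed(2)
  Y <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(sprintf("s%d", 1:8), sprintf("m%d", 1:5)))
  mf <- fit_pca(Y, n_components = 5)
  recon <- mf$scores %*% t(mf$loadings)
  scaled <- scale(Y)
  expect_lt(max(abs(recon - scaled)), 1e-8)
  expect_equal(sum(mf$explained_variance_fraction), 1, tolerance = 1e-12)
  # explained fractions are non-increasing; loadings orthonormal
  expect_true(all(diff(mf$explained_variance_fraction) <= 1e-12))
  expect_lt(max(abs(crossprod(mf$loadings) - diag(5))), 1e-8)
  # constant metabolite cannot be autoscaled
  Y[, 2] <- 3
  expect_error(fit_pca(Y), "m2")
})

test_that("OPLS-DA with zero orthogonal components is one-component PLS1", {
  set.seed(42)
  for (i in 1:100) {
    inst <- random_two_class(n_per = sample(4:8, 1), p = sample(5:25, 1),
                             shift = runif(1, 0, 2), seed = 1000 + i)
    fit <- fit_oplsda(inst$X, inst$labels, n_orthogonal = 0)
    got <- predict(fit, inst$X)$y_score
    ref <- pls1_train_predictions(inst$X, as.numeric(inst$labels == "b"))
    expect_lt(max(abs(got - ref)), 1e-8)
  }
})

test_that("orthogonal scores carry no covariance with the class vector", {
  set.seed(3)
  for (i in 1:20) {
    inst <- random_two_class(n_per = 8, p = 15, shift = 1.5, seed = 200 + i)
    k <- sample(1:3, 1)
    fit <- fit_oplsda(inst$X, inst$labels, n_orthogonal = k)
    y <- as.numeric(inst$labels == "b")
    yc <- y - mean(y)
    covs <- abs(crossprod(fit$t_ortho, yc)) / (length(y) - 1)
    expect_lt(max(covs), 1e-8)
    # filtering y-orthogonal variation never hurts training fit
    fit0 <- fit_oplsda(inst$X, inst$labels, n_orthogonal = 0)
    expect_gte(fit$r2y, fit0$r2y - 1e-10)
  }
})

test_that("a separable direction dominates weights and fit quality", {
  set.seed(9)
  n <- 10; p <- 20
  X <- matrix(rnorm(2 * n * p, sd = 0.3), 2 * n, p,
              dimnames = list(sprintf("s%02d", 1:(2 * n)),
                              sprintf("m%02d", 1:p)))
  X[(n + 1):(2 * n), 7] <- X[(n + 1):(2 * n), 7] + 4
  lab <- rep(c("a", "b"), each = n)
  fit <- fit_oplsda(X, lab, 0, scaling = "center_only")
  expect_equal(unname(which.max(abs(fit$w))), 7L)
  expect_gt(fit$r2y, 0.9)
  expect_equal(names(which.max(fit$vip)), "m07")
  expect_error(fit_oplsda(X[lab == "a", ], lab[lab == "a"], 0), "two classes")
})

test_that("VIP normalization and closed forms", {
  set.seed(4)
  for (i in 1:20) {
    inst <- random_two_class(n_per = 6, p = sample(4:30, 1),
                             shift = runif(1, 0, 2), seed = 300 + i)
    fit <- fit_oplsda(inst$X, inst$labels, sample(0:1, 1))
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)
    # ranking invariant to column order
    perm <- sample(ncol(inst$X))
    fit_p <- fit_oplsda(inst$X[, perm], inst$labels, 0)
    fit_0 <- fit_oplsda(inst$X, inst$labels, 0)
    expect_equal(fit_p$vip[colnames(inst$X)], fit_0$vip[colnames(inst$X)],
                 tolerance = 1e-10)
  }
  # closed forms through a hand-built model object
  m <- structure(list(w = c(1, -1, 1, -1) / 2,
                      metabolite_ids = letters[1:4]), class = "oplsda_model")
  expect_equal(unname(vip_scores(m)), rep(1, 4))
  m$w <- c(0, 0, 1, 0)
  expect_equal(unname(vip_scores(m)), c(0, 0, 2, 0))
})

test_that("cross-validation fold rule and q2 behave as documented", {
  set.seed(6)
  # separable classes, low noise
  inst <- random_two_class(n_per = 12, p = 15, shift = 3, seed = 61)
  cv <- cross_validate(inst$X, inst$labels, 0, seed = 1)
  expect_equal(cv$n_folds, 10)
  expect_gt(cv$q2, 0.5)
  # smaller class below 10 -> 5-fold; below 5 -> leave-one-out
  inst5 <- random_two_class(n_per = 7, p = 10, shift = 2, seed = 62)
  expect_equal(cross_validate(inst5$X, inst5$labels, 0, seed = 1)$n_folds, 5)
  inst3 <- random_two_class(n_per = 4, p = 10, shift = 2, seed = 63)
  expect_equal(cross_validate(inst3$X, inst3$labels, 0, seed = 1)$n_folds, 8)
  # null labels: q2 centered at or below zero
  set.seed(64)
  null_q2 <- replicate(30, {
    inst0 <- random_two_class(n_per = 8, p = 12, shift = 0,
                              seed = sample.int(1e6, 1))
    cross_validate(inst0$X, inst0$labels, 0, seed = 1)$q2
  })
  expect_lt(median(null_q2), 0.05)
  # invariance to sample order under the id-keyed fold mapping
  inst <- random_two_class(n_per = 11, p = 10, shift = 1, seed = 65)
  perm <- sample(nrow(inst$X))
  cv1 <- cross_validate(inst$X, inst$labels, 0, seed = 4)
  cv2 <- cross_validate(inst$X[perm, ], inst$labels[perm], 0, seed = 4)
  expect_equal(cv1$q2, cv2$q2, tolerance = 1e-12)
})

test_that("orthogonal component selection reacts to confounder structure", {
  # y-correlated signal with near-noiseless residuals: nothing orthogonal
  # to remove, so no component is added
  set.seed(71)
  n <- 10; p <- 12
  X <- matrix(rnorm(2 * n * p, sd = 0.05), 2 * n, p,
              dimnames = list(sprintf("s%02d", 1:(2 * n)),
                              sprintf("m%02d", 1:p)))
  lab <- rep(c("a", "b"), each = n)
  X[, 1:6] <- X[, 1:6] + 2 * (lab == "b")
  expect_equal(choose_n_orthogonal(X, lab, seed = 2), 0L)
  expect_equal(choose_n_orthogonal(X, lab, k_max = 0), 0L)
  # a strong y-orthogonal confounder direction drowning the class signal:
  # filtering it is essential and at least one component is chosen
  set.seed(73)
  X2 <- matrix(rnorm(2 * n * 20, sd = 0.5), 2 * n, 20,
               dimnames = list(sprintf("s%02d", 1:(2 * n)),
                               sprintf("m%02d", 1:20)))
  X2[, 1:10] <- X2[, 1:10] + 0.8 * (lab == "b")
  conf <- rnorm(2 * n, sd = 4)
  conf <- conf - mean(conf)
  yc <- (lab == "b") - mean(lab == "b")
  conf <- conf - sum(conf * yc) / sum(yc^2) * yc        # exactly y-orthogonal
  X2 <- X2 + outer(conf, runif(20, 0.5, 1.5))
  k <- choose_n_orthogonal(X2, lab, seed = 2)
  expect_gte(k, 1L)
  # and the filtered model predicts much better than the unfiltered one
  q0 <- cross_validate(X2, lab, 0, seed = 2)$q2
  qk <- cross_validate(X2, lab, k, seed = 2)$q2
  expect_gt(qk, q0 + 0.2)
})

test_that("CV-ANOVA conventions: no improvement, strong model, calibration", {
  set.seed(81)
  # strongly predictive model
  inst <- random_two_class(n_per = 10, p = 12, shift = 3, seed = 82)
  cv <- cross_validate(inst$X, inst$labels, 0, seed = 1)
  expect_lt(cv_anova(cv, inst$labels, 0)$p_value, 0.01)
  # predictions no better than the intercept -> F floored, p = 1
  fake <- list(predictions = rep(0.5, 20), press = cv$tss, tss = cv$tss)
  expect_equal(cv_anova(fake, inst$labels, 0)$p_value, 1)
  expect_equal(cv_anova(fake, inst$labels, 0)$f_stat, 0)
  # perfect predictions -> degenerate flag, tiny p
  perf <- list(predictions = as.numeric(inst$labels == "b"), press = 0,
               tss = cv$tss)
  ca <- cv_anova(perf, inst$labels, 0)
  expect_true(ca$degenerate)
  expect_lt(ca$p_value, 1e-6)
  # null labels: the test must not be anticonservative
  set.seed(83)
  null_p <- replicate(120, {
    inst0 <- random_two_class(n_per = 8, p = 10, shift = 0,
                              seed = sample.int(1e6, 1))
    cv0 <- cross_validate(inst0$X, inst0$labels, 0, seed = 1)
    cv_anova(cv0, inst0$labels, 0)$p_value
  })
  expect_lte(mean(null_p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("permutation test follows the add-one rule and is reproducible", {
  set.seed(91)
  inst <- random_two_class(n_per = 10, p = 12, shift = 3, seed = 92)
  pt <- permutation_test(inst$X, inst$labels, 0, n_permutations = 100,
                         seed = 5)
  # observed separation beats every permutation
  expect_equal(pt$p_q2, 1 / 101)
  expect_equal(pt$p_r2y, 1 / 101)
  pt2 <- permutation_test(inst$X, inst$labels, 0, n_permutations = 100,
                          seed = 5)
  expect_identical(pt, pt2)
  expect_error(permutation_test(inst$X, inst$labels, 0, n_permutations = 0),
               "n_permutations")
})

test_that("validate_oplsda combines the validation evidence", {
  inst <- random_two_class(n_per = 10, p = 15, shift = 3, seed = 95)
  val <- validate_oplsda(inst$X, inst$labels, n_permutations = 50, seed = 3)
  expect_true(val$validated)
  expect_gt(val$cv$q2, 0)
  null <- random_two_class(n_per = 10, p = 15, shift = 0, seed = 96)
  val0 <- validate_oplsda(null$X, null$labels, n_permutations = 50, seed = 3)
  expect_false(val0$validated)
})
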