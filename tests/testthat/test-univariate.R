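test_that("fold change is the ratio of group means with direction", {
  expect_equal(fold_change(c(2, 2), c(2, 2))$fold_change, 1)
  fc <- fold_change(c(1, 3), c(3, 5))
  expect_equal(fc$fold_change, 2)
  expect_equal(fc$direction, "up")
  # reciprocity under group swap
  a <- rexp(5) + 0.1; b <- rexp(7) + 0.1
  expect_equal(fold_change(a, b)$fold_change * fold_change(b, a)$fold_change, 1)
  expect_error(fold_change(numeric(0), 1), "non-empty")
  expect_error(fold_change(c(0, 0), c(1, 2)), "zero mean")
})

test_that("Welch test matches the reference implementation", {
  set.seed(101)
  for (i in 1:1000) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    a <- rnorm(na, sd = runif(1, 0.2, 3))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.2, 3))
    got <- welch_test(a, b)
    ref <- stats::t.test(b, a, var.equal = FALSE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch degenerate conventions", {
  eq <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_value, 1)
  const_eq <- welch_test(c(2, 2, 2), c(2, 2))
  expect_equal(const_eq$p_value, 1)
  expect_true(const_eq$degenerate)
  const_diff <- welch_test(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(const_diff$p_value, 0)
  expect_true(const_diff$degenerate)
  # near-constant groups: tiny jitter keeps a finite but extreme test
  set.seed(2)
  p <- welch_test(rnorm(4, 0, 1e-6), rnorm(4, 1, 1e-6))$p_value
  expect_lt(p, 1e-4)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("Welch null p-values are uniform", {
  set.seed(7)
  p <- replicate(10000, welch_test(rnorm(6), rnorm(8))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("run_contrast recovers a planted effect and controls the null", {
  ids <- c(sprintf("sA%02d", 1:12), sprintf("sB%02d", 1:12))
  meta <- tiny_meta(ids, dose = 11,
                    timepoint = rep(c("TP1", "TP2"), each = 12))
  set.seed(31)
  logvals <- matrix(rnorm(24 * 200, 5, 0.2), 24, 200,
                    dimnames = list(ids, sprintf("met_%03d", 1:200)))
  logvals[13:24, 1] <- logvals[13:24, 1] + 2 * log(2)   # planted up-effect
  raw <- abundance_matrix(exp(logvals), "raw")
  pp <- preprocess(raw, meta)
  res <- run_contrast(pp$matrix, meta,
                      contrast_spec("time_within_dose", "TP1", "TP2", 11))
  top <- res[res$metabolite_id == "met_001", ]
  expect_gt(top$fold_change, 2)
  expect_lt(top$p_value, 0.05)
  expect_equal(top$direction, "up")
  # null metabolites: about 5% below 0.05 (binomial tolerance)
  null_p <- res$p_value[-1]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 199))
  # group sizes recorded
  expect_equal(attr(res, "n_a"), 12)
})

test_that("fold-change scales agree on log-symmetric data and labels swap", {
  ids <- sprintf("s%02d", 1:12)
  meta <- tiny_meta(ids, dose = 8, timepoint = rep(c("TP1", "TP2"), each = 6))
  set.seed(5)
  logvals <- matrix(rnorm(12 * 30, 3, 0.3), 12, 30,
                    dimnames = list(ids, sprintf("met_%03d", 1:30)))
  raw <- abundance_matrix(exp(logvals), "raw")
  pp <- preprocess(raw, meta)
  spec <- contrast_spec("time_within_dose", "TP1", "TP2", 8)
  nat <- run_contrast(pp$matrix, meta, spec, fc_scale = "natural")
  lg <- run_contrast(pp$matrix, meta, spec, fc_scale = "log")
  expect_equal(nat$log2_fc, lg$log2_fc, tolerance = 0.2)
  swapped <- run_contrast(pp$matrix, meta,
                          contrast_spec("time_within_dose", "TP2", "TP1", 8))
  expect_equal(swapped$fold_change, 1 / nat$fold_change, tolerance = 1e-12)
  expect_equal(swapped$p_value, nat$p_value, tolerance = 1e-12)
})

test_that("removing a metabolite leaves other p-values fixed and q-values grow", {
  set.seed(13)
  p <- runif(30)^2
  q_full <- bh_adjust(p)
  drop <- which.min(p)
  q_red <- bh_adjust(p[-drop])
  expect_true(all(q_red >= q_full[-drop] - 1e-15))
})

test_that("significance counts apply the two-sided fold-change rule", {
  res <- data.frame(metabolite_id = sprintf("m%d", 1:4),
                    fold_change = c(3, 0.4, 1.5, 2.5),
                    log2_fc = log2(c(3, 0.4, 1.5, 2.5)),
                    p_value = c(0.01, 0.01, 0.01, 0.2),
                    q_value = c(0.04, 0.2, 0.01, 0.6))
  out <- significance_counts(list(c1 = res))
  expect_equal(out$n_sig_p, 2)   # m1 up, m2 down; m3 fails fc, m4 fails p
  expect_equal(out$n_sig_q, 1)
  empty <- significance_counts(list())
  expect_equal(nrow(empty), 0)
})

test_that("contrast resolution validates groups", {
  meta <- tiny_meta(sprintf("s%d", 1:4), dose = c(0, 0, 8, 8),
                    timepoint = "TP2")
  expect_error(contrast_spec("dose_within_time", 0, 0, "TP2"), "differ")
  vals <- named_mat(rexp(4 * 3) + 1, nrow = 4)
  rownames(vals) <- meta$sample_id
  pp <- preprocess(abundance_matrix(vals), meta)
  expect_error(run_contrast(pp$matrix, meta,
                            contrast_spec("dose_within_time", 0, 8, "TP3")),
               "fewer than 2")
  # sex filter empties a group
  meta$sex <- c("F", "F", "M", "M")
  expect_error(run_contrast(pp$matrix, meta,
                            contrast_spec("dose_within_time", 0, 8, "TP2")),
               "fewer than 2")
})
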