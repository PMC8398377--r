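#' Specify a pairwise contrast
#'
#' A contrast compares two groups of samples along one design axis: either
#' two timepoint groups at a fixed radiation dose (`time_within_dose`, e.g.
#' TP1 vs TP2 at 11 Gy) or two doses at a fixed timepoint group
#' (`dose_within_time`, e.g. 0 Gy vs 12.5 Gy at TP2). Samples are restricted
#' to `sex_filter` first; the published analysis used males only.
#'
#' @param axis `"time_within_dose"` or `"dose_within_time"`.
#' @param group_a,group_b the two factor levels being compared (timepoint
#'   labels or doses, depending on `axis`); `group_a` is the reference.
#' @param fixed the level of the other axis held fixed (a dose for
#'   `time_within_dose`, a timepoint for `dose_within_time`).
#' @param sex_filter subset of `c("M", "F")` (default `"M"`).
#' @return a `contrast_spec` object.
#' @export
contrast_spec <- function(axis = c("time_within_dose", "dose_within_time"),
                          group_a, group_b, fixed, sex_filter = "M") {
  axis <- match.arg(axis)
  if (identical(group_a, group_b)) stop("group_a and group_b must differ")
  structure(list(axis = axis, group_a = group_a, group_b = group_b,
                 fixed = fixed, sex_filter = sex_filter),
            class = "contrast_spec")
}

#' @export
format.contrast_spec <- function(x, ...) {
  if (x$axis == "time_within_dose")
    sprintf("%sGy_%s_vs_%s", x$fixed, x$group_a, x$group_b)
  else
    sprintf("%s_%sGy_vs_%sGy", x$fixed, x$group_a, x$group_b)
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("contrast:", format(x), " sex:", paste(x$sex_filter, collapse = "/"), "\n")
  invisible(x)
}

# internal: resolve a contrast to the two sample-id groups
resolve_contrast <- function(meta, spec) {
  meta <- meta[meta$sex %in% spec$sex_filter, , drop = FALSE]
  if (spec$axis == "time_within_dose") {
    sub <- meta[meta$dose_gy == spec$fixed, , drop = FALSE]
    a <- sub$sample_id[sub$timepoint == spec$group_a]
    b <- sub$sample_id[sub$timepoint == spec$group_b]
  } else {
    sub <- meta[meta$timepoint == spec$fixed, , drop = FALSE]
    a <- sub$sample_id[sub$dose_gy == spec$group_a]
    b <- sub$sample_id[sub$dose_gy == spec$group_b]
  }
  if (length(a) < 2 || length(b) < 2)
    stop(sprintf("contrast %s: fewer than 2 samples in a group after sex filter (%d vs %d)",
                 format(spec), length(a), length(b)))
  list(a = a, b = b)
}

#' Fold change between two groups
#'
#' Ratio of the two group means, `mean(b) / mean(a)`, computed on positive
#' (volume-normalized, unlogged) intensities. Direction is `"up"` when the
#' ratio exceeds 1 (group b above the reference group a).
#'
#' @param values_a,values_b per-sample intensities of the two groups.
#' @return list with `fold_change` and `direction`.
#' @export
fold_change <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  ma <- mean(values_a)
  if (ma == 0) stop("zero mean in the reference group")
  fc <- mean(values_b) / ma
  list(fold_change = fc, direction = if (fc > 1) "up" else "down")
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test with Satterthwaite degrees of freedom,
#' applied to logged, imputed intensities. Degenerate inputs follow fixed
#' conventions: two constant equal groups give `t = 0, p = 1`; two constant
#' but different groups give `p = 0` flagged as degenerate (the difference
#' is exact, no sampling noise to test against).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
welch_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  out <- welch_test_matrix(matrix(values_a, nrow = 1), matrix(values_b, nrow = 1))
  list(t_stat = out$t[1], df = out$df[1], p_value = out$p[1],
       degenerate = out$degenerate[1])
}

# internal: vectorized Welch over metabolites in rows
welch_test_matrix <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  # both groups constant: equal means -> no evidence; different -> exact split
  t[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0, Inf *
                            sign(mb[degenerate] - ma[degenerate]))
  df[degenerate] <- na + nb - 2
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across metabolites within one
#' contrast.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Univariate differential abundance for one contrast
#'
#' Per retained metabolite: fold change (ratio of group means on the
#' volume-normalized, unlogged scale by default), two-sided Welch t-test on
#' the logged imputed scale, and BH adjustment across metabolites.
#'
#' @param x imputed-stage [abundance_matrix()] (logged values). The unlogged
#'   scale used for fold change is recovered by inverting the recorded log
#'   base, which is exact because imputation happens after logging.
#' @param meta sample metadata.
#' @param spec a [contrast_spec()].
#' @param fc_scale `"natural"` (ratio of arithmetic means of unlogged
#'   intensities, default) or `"log"` (ratio of geometric means).
#' @return data.frame with one row per metabolite: `metabolite_id`,
#'   `fold_change`, `log2_fc`, `t_stat`, `df`, `p_value`, `q_value`,
#'   `direction`, `degenerate`; the contrast label is attached as attribute
#'   `contrast`.
#' @export
run_contrast <- function(x, meta, spec, fc_scale = c("natural", "log")) {
  fc_scale <- match.arg(fc_scale)
  assert_stage(x, "imputed", "run_contrast")
  groups <- resolve_contrast(meta, spec)
  A <- t(unclass(x)[groups$a, , drop = FALSE])   # metabolites x samples
  B <- t(unclass(x)[groups$b, , drop = FALSE])
  w <- welch_test_matrix(A, B)
  base <- attr(x, "log_base")
  if (is.null(base)) base <- exp(1)
  if (fc_scale == "natural") {
    fc <- rowMeans(base^B) / rowMeans(base^A)
  } else {
    fc <- base^(rowMeans(B) - rowMeans(A))
  }
  out <- data.frame(metabolite_id = colnames(x),
                    fold_change = unname(fc),
                    log2_fc = unname(log2(fc)),
                    t_stat = unname(w$t),
                    df = unname(w$df),
                    p_value = unname(w$p),
                    q_value = unname(bh_adjust(w$p)),
                    direction = ifelse(fc > 1, "up", "down"),
                    degenerate = unname(w$degenerate))
  attr(out, "contrast") <- format(spec)
  attr(out, "n_a") <- length(groups$a)
  attr(out, "n_b") <- length(groups$b)
  attr(out, "fc_scale") <- fc_scale
  out
}

#' One-way ANOVA across timepoint groups at a fixed dose
#'
#' Secondary screen complementing the pairwise Welch contrasts: a classical
#' one-way ANOVA of logged abundance across all timepoint groups within one
#' dose arm, BH-adjusted over metabolites.
#'
#' @param x imputed-stage [abundance_matrix()].
#' @param meta sample metadata.
#' @param dose dose arm to test within.
#' @param sex_filter subset of `c("M", "F")` (default `"M"`).
#' @return data.frame: `metabolite_id`, `f_stat`, `p_value`, `q_value`.
#' @export
anova_timepoints <- function(x, meta, dose, sex_filter = "M") {
  assert_stage(x, "imputed", "anova_timepoints")
  sub <- meta[meta$sex %in% sex_filter & meta$dose_gy == dose, , drop = FALSE]
  tp <- factor(sub$timepoint)
  if (nlevels(tp) < 2) stop("need at least two timepoint groups")
  vals <- unclass(x)[sub$sample_id, , drop = FALSE]
  res <- apply(vals, 2, function(v) {
    fit <- stats::oneway.test(v ~ tp, var.equal = TRUE)
    c(fit$statistic, fit$p.value)
  })
  data.frame(metabolite_id = colnames(x), f_stat = res[1, ],
             p_value = res[2, ], q_value = bh_adjust(res[2, ]),
             row.names = NULL)
}

#' Build the published contrast grid
#'
#' The main comparisons: pre-exposure (TP1) versus each post-exposure group
#' (TP2, TP3, TP4) within every dose arm, and sham (0 Gy) versus each
#' irradiated dose within every timepoint group.
#'
#' @param doses dose levels present (default the study's 0/8/11/12.5/14 Gy).
#' @param timepoints timepoint labels (default TP1..TP4).
#' @param sex_filter passed to each [contrast_spec()].
#' @return named list of `contrast_spec`s.
#' @export
contrast_grid <- function(doses = c(0, 8, 11, 12.5, 14),
                          timepoints = c("TP1", "TP2", "TP3", "TP4"),
                          sex_filter = "M") {
  specs <- list()
  for (d in doses) {
    for (tp in setdiff(timepoints, timepoints[1])) {
      s <- contrast_spec("time_within_dose", timepoints[1], tp, d, sex_filter)
      specs[[format(s)]] <- s
    }
  }
  sham <- doses[1]
  for (tp in timepoints) {
    for (d in setdiff(doses, sham)) {
      s <- contrast_spec("dose_within_time", sham, d, tp, sex_filter)
      specs[[format(s)]] <- s
    }
  }
  specs
}

#' Significance counts over a contrast grid
#'
#' Tabulates, for each contrast, how many metabolites pass the fold-change
#' and significance cutoffs: once with the raw Welch p-value and once with
#' the BH-adjusted q-value. The fold-change threshold is two-sided: a
#' metabolite passes at `fc_threshold = 2` if its ratio exceeds 2 or falls
#' below 1/2.
#'
#' @param results named list of [run_contrast()] tables.
#' @param fc_threshold fold-change cutoff (default 2).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `contrast`, `n_sig_p` (fc & p), `n_sig_q` (fc & q).
#' @export
significance_counts <- function(results, fc_threshold = 2, alpha = 0.05) {
  if (!length(results))
    return(data.frame(contrast = character(), n_sig_p = integer(),
                      n_sig_q = integer()))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    pass_fc <- abs(r$log2_fc) > log2(fc_threshold)
    data.frame(contrast = nm,
               n_sig_p = sum(pass_fc & r$p_value < alpha),
               n_sig_q = sum(pass_fc & r$q_value < alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
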