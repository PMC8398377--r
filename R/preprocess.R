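#' Normalize intensities for plasma volume
#'
#' Divides each sample's intensities by that sample's plasma volume, so that
#' downstream statistics compare per-unit-volume abundance. Volume units are
#' treated as relative: only ratios between samples matter. Missing entries
#' stay missing.
#'
#' @param x raw-stage [abundance_matrix()].
#' @param volumes numeric vector of strictly positive volumes, named by
#'   sample id (or in row order if unnamed).
#' @return a normalized-stage `abundance_matrix`.
#' @export
normalize_volume <- function(x, volumes) {
  assert_stage(x, "raw", "normalize_volume")
  if (!is.null(names(volumes))) {
    v <- volumes[rownames(x)]
    bad <- rownames(x)[is.na(v)]
    if (length(bad))
      stop("no volume for sample(s): ", paste(bad, collapse = ", "))
  } else {
    if (length(volumes) != nrow(x))
      stop("unnamed volume vector must have one entry per sample")
    v <- volumes
  }
  nonpos <- rownames(x)[!is.finite(v) | v <= 0]
  if (length(nonpos))
    stop("non-positive or missing volume for sample(s): ",
         paste(nonpos, collapse = ", "))
  as_abundance(unclass(x) / v, "normalized")
}

#' Filter metabolites by missingness
#'
#' Removes metabolites whose fraction of missing (non-detected) entries is
#' strictly greater than `max_missing_fraction`; a metabolite missing in
#' exactly the threshold fraction of samples is retained. The denominator is
#' all samples in the matrix, before any arm or sex subsetting.
#'
#' @param x normalized-stage [abundance_matrix()].
#' @param max_missing_fraction maximum tolerated missing fraction
#'   (default 0.20).
#' @return list with `matrix` (filtered, still normalized stage) and
#'   `report`, a data.frame over all input metabolites with columns
#'   `metabolite_id`, `missing_fraction`, `excluded`.
#' @export
filter_missingness <- function(x, max_missing_fraction = 0.20) {
  assert_stage(x, "normalized", "filter_missingness")
  frac <- colMeans(is.na(x))
  excluded <- frac > max_missing_fraction
  report <- data.frame(metabolite_id = colnames(x),
                       missing_fraction = unname(frac),
                       excluded = unname(excluded))
  keep <- unclass(x)[, !excluded, drop = FALSE]
  list(matrix = as_abundance(keep, "normalized"), report = report)
}

#' Log-transform a normalized abundance matrix
#'
#' Applies a logarithm to every observed value; missing entries stay
#' missing. The base only shifts log-scale statistics by a constant factor
#' and changes neither p-values nor VIP; natural log is the default.
#'
#' @param x normalized-stage [abundance_matrix()].
#' @param base logarithm base (default `exp(1)`).
#' @return a logged-stage `abundance_matrix` with a `log_base` attribute.
#' @export
log_transform <- function(x, base = exp(1)) {
  assert_stage(x, "normalized", "log_transform")
  vals <- unclass(x)
  bad <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive observed value at sample '%s', metabolite '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  out <- as_abundance(log(vals, base = base), "logged")
  attr(out, "log_base") <- base
  out
}

#' Impute missing values with the per-metabolite minimum
#'
#' Replaces each missing entry with the minimum observed (logged) value of
#' that metabolite, the standard stand-in for intensities below the
#' detection limit. Observed entries are untouched, so the per-metabolite
#' minimum is unchanged by imputation.
#'
#' @param x logged-stage [abundance_matrix()].
#' @return an imputed-stage `abundance_matrix` (the `log_base` attribute is
#'   carried along).
#' @export
impute_minimum <- function(x) {
  assert_stage(x, "logged", "impute_minimum")
  vals <- unclass(x)
  all_missing <- colnames(x)[colSums(!is.na(vals)) == 0]
  if (length(all_missing))
    stop("metabolite(s) with no observed value (should have been filtered): ",
         paste(all_missing, collapse = ", "))
  for (j in which(colSums(is.na(vals)) > 0)) {
    vals[is.na(vals[, j]), j] <- min(vals[, j], na.rm = TRUE)
  }
  out <- as_abundance(vals, "imputed")
  attr(out, "log_base") <- attr(x, "log_base")
  out
}

#' Run the full preprocessing pipeline
#'
#' Volume normalization, missingness filtering, log transformation and
#' minimum-value imputation, in that fixed order.
#'
#' @param x raw-stage [abundance_matrix()].
#' @param meta sample metadata containing `sample_id` and `volume_ml`.
#' @param max_missing_fraction missingness filter threshold (default 0.20).
#' @param log_base logarithm base (default natural).
#' @return list with `matrix` (imputed stage) and `filter_report`.
#' @export
preprocess <- function(x, meta, max_missing_fraction = 0.20,
                       log_base = exp(1)) {
  vols <- stats::setNames(meta$volume_ml, meta$sample_id)
  norm <- normalize_volume(x, vols)
  filt <- filter_missingness(norm, max_missing_fraction)
  logged <- log_transform(filt$matrix, base = log_base)
  list(matrix = impute_minimum(logged), filter_report = filt$report)
}
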