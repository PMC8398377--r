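#' Run the complete biomarker-discovery pipeline
#'
#' Orchestrates every stage on either supplied data or a simulated cohort:
#' preprocessing (volume normalization, missingness filter, log transform,
#' minimum imputation), the univariate contrast grid with significance
#' counts, PCA, per-contrast OPLS-DA with validation, subpathway enrichment,
#' composite selection, the sham time-drift confounder filter for TP1-vs-TPk
#' contrasts at irradiated doses, and Venn partitions of the post-filter
#' sets. Fully deterministic under the master seed.
#'
#' Enrichment for each contrast tests the univariate significant set
#' (two-sided fold change above the threshold and Welch p below `p_max`)
#' against the background of retained metabolites. Contrasts that cannot be
#' formed (a group with fewer than 2 samples after the sex filter) are
#' recorded under `skipped`; contrasts whose groups are too small for
#' OPLS-DA (< 3 per class) keep their univariate results but cannot validate
#' a model.
#'
#' @param matrix raw-stage [abundance_matrix()], or `NULL` to simulate.
#' @param meta sample metadata (required with `matrix`).
#' @param annotation annotation data.frame (required with `matrix`).
#' @param simulate list of arguments for [simulate_cohort()] (`config`,
#'   `spec`), used when `matrix` is `NULL`.
#' @param seed master integer seed.
#' @param thresholds a [selection_thresholds()].
#' @param sex_filter subset of `c("M", "F")` (default `"M"`, the published
#'   choice: female arms were underpowered).
#' @param n_permutations OPLS-DA permutation count (default 100).
#' @param n_orthogonal `"auto"` or a fixed count for every contrast.
#' @param max_missing_fraction missingness filter threshold (default 0.20).
#' @param fc_scale fold-change scale, see [run_contrast()].
#' @param sham_filter_basis how sham-arm time-drift markers are identified
#'   for the confounder filter: `"univariate"` (default; metabolites
#'   differentially abundant in the sham arm by the fold-change and Welch-p
#'   rule, with sham-enriched subpathways) or `"composite"` (the full
#'   selection rule including VIP and model validation). The univariate
#'   basis keeps the filter active when the small sham arm cannot support a
#'   validated supervised model.
#' @param out_dir optional directory; when given, all tables, Venn
#'   partitions and a run manifest are written as TSV/JSON.
#' @return a `pipeline_result` list: `preprocessed`, `filter_report`,
#'   `univariate`, `counts`, `pca`, `oplsda`, `enrichment`, `selection`
#'   (post-confounder-filter), `selection_prefilter`, `venn`, `skipped`,
#'   `manifest`, and `truth` when simulated.
#' @export
run_full_pipeline <- function(matrix = NULL, meta = NULL, annotation = NULL,
                              simulate = list(), seed = 1L,
                              thresholds = selection_thresholds(),
                              sex_filter = "M", n_permutations = 100,
                              n_orthogonal = "auto",
                              max_missing_fraction = 0.20,
                              fc_scale = "natural",
                              sham_filter_basis = c("univariate", "composite"),
                              out_dir = NULL) {
  sham_filter_basis <- match.arg(sham_filter_basis)
  truth <- NULL
  if (is.null(matrix)) {
    sim_args <- utils::modifyList(list(seed = seed), simulate)
    cohort <- do.call(simulate_cohort, sim_args)
    matrix <- cohort$matrix
    meta <- cohort$design
    annotation <- cohort$annotation
    truth <- cohort$truth
  }
  check_metadata(meta)
  check_annotation(annotation)
  meta <- meta[meta$sex %in% sex_filter, , drop = FALSE]
  if (!nrow(meta)) stop("no samples left after sex filter")
  matrix <- as_abundance(unclass(matrix)[meta$sample_id, , drop = FALSE],
                         matrix_stage(matrix))

  prep <- preprocess(matrix, meta, max_missing_fraction)
  imputed <- prep$matrix
  background <- colnames(imputed)

  pca <- fit_pca(imputed, n_components = min(10L, nrow(imputed) - 1L,
                                             ncol(imputed)))

  doses <- sort(unique(meta$dose_gy))
  tps <- sort(unique(meta$timepoint))
  grid <- contrast_grid(doses, tps, sex_filter)

  univ <- list(); oplsda <- list(); enrich <- list()
  sel_pre <- list(); skipped <- list()
  ctr_seed <- seed + 100L
  for (nm in names(grid)) {
    spec <- grid[[nm]]
    ctr_seed <- ctr_seed + 1L
    res <- tryCatch(run_contrast(imputed, meta, spec, fc_scale = fc_scale),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[nm]] <- conditionMessage(res)
      next
    }
    univ[[nm]] <- res

    groups <- resolve_contrast(meta, spec)
    val <- NULL
    if (length(groups$a) >= 3 && length(groups$b) >= 3) {
      X <- unclass(imputed)[c(groups$a, groups$b), , drop = FALSE]
      labels <- factor(rep(c("a", "b"), c(length(groups$a), length(groups$b))),
                       levels = c("a", "b"))
      val <- tryCatch(
        validate_oplsda(X, labels, n_orthogonal = n_orthogonal,
                        n_permutations = n_permutations, seed = ctr_seed),
        error = function(e) NULL)
    }
    oplsda[[nm]] <- val

    sig <- res$metabolite_id[abs(res$log2_fc) > log2(thresholds$fc_min) &
                               res$p_value < thresholds$p_max]
    enr <- enrich_subpathways(sig, background, annotation,
                              min_size = thresholds$subpathway_min_size,
                              alpha = thresholds$subpathway_p_max)
    enrich[[nm]] <- enr

    vip <- if (!is.null(val)) val$model$vip else
      stats::setNames(rep(0, length(background)), background)
    sel_pre[[nm]] <- composite_select(res, vip,
                                      model_validated = !is.null(val) && val$validated,
                                      enrichment = enr,
                                      annotation = annotation,
                                      thresholds = thresholds)
  }

  # sham time-drift filter for TP1-vs-TPk contrasts at irradiated doses
  sel_post <- sel_pre
  sham_dose <- doses[1]
  for (nm in names(sel_pre)) {
    spec <- grid[[nm]]
    if (spec$axis != "time_within_dose" || spec$fixed == sham_dose) next
    sham_nm <- format(contrast_spec("time_within_dose", spec$group_a,
                                    spec$group_b, sham_dose, sex_filter))
    if (!sham_nm %in% names(sel_pre)) next
    sham_sel <- if (sham_filter_basis == "composite") sel_pre[[sham_nm]]
      else univariate_markers(univ[[sham_nm]], enrich[[sham_nm]], thresholds)
    sel_post[[nm]] <- confounder_filter(sel_pre[[nm]], sham_sel)
  }

  counts <- significance_counts(univ, thresholds$fc_min, thresholds$p_max)

  # Venn partitions of the post-filter selections, axes kept separate
  venn <- list()
  for (d in setdiff(doses, sham_dose)) {
    nms <- names(grid)[vapply(grid, function(s)
      s$axis == "time_within_dose" && s$fixed == d, logical(1))]
    nms <- intersect(nms, names(sel_post))
    if (length(nms) >= 2) {
      sets <- lapply(sel_post[nms], function(s) s$selected_metabolites$metabolite_id)
      names(sets) <- sub(sprintf("^%sGy_", d), "", nms)
      venn[[sprintf("time_contrasts_%sGy", d)]] <- venn_partition(sets)
    }
  }
  for (tp in setdiff(tps, tps[1])) {
    nms <- names(grid)[vapply(grid, function(s)
      s$axis == "dose_within_time" && s$fixed == tp, logical(1))]
    nms <- intersect(nms, names(sel_post))
    if (length(nms) >= 2 && length(nms) <= 4) {
      sets <- lapply(sel_post[nms], function(s) s$selected_metabolites$metabolite_id)
      names(sets) <- sub(sprintf("^%s_", tp), "", nms)
      venn[[sprintf("dose_contrasts_%s", tp)]] <- venn_partition(sets)
    }
  }

  manifest <- list(
    package = "radmetab",
    version = as.character(utils::packageVersion("radmetab")),
    seed = seed,
    sex_filter = sex_filter,
    n_samples = nrow(meta),
    n_metabolites_input = ncol(matrix),
    n_metabolites_retained = length(background),
    max_missing_fraction = max_missing_fraction,
    thresholds = unclass(thresholds),
    n_permutations = n_permutations,
    n_orthogonal = n_orthogonal,
    fc_scale = fc_scale,
    contrasts_run = names(univ),
    contrasts_skipped = skipped
  )

  result <- structure(list(preprocessed = imputed,
                           filter_report = prep$filter_report,
                           meta = meta,
                           annotation = annotation,
                           univariate = univ, counts = counts, pca = pca,
                           oplsda = oplsda, enrichment = enrich,
                           selection_prefilter = sel_pre,
                           selection = sel_post,
                           venn = venn, skipped = skipped,
                           manifest = manifest, truth = truth),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

# internal: a selection_result carrying the sham arm's differentially
# abundant metabolites (two-sided fold change + Welch p) and its enriched
# subpathways, used as the subtraction basis of the confounder filter
univariate_markers <- function(univ, enrichment, thresholds) {
  sel <- abs(univ$log2_fc) > log2(thresholds$fc_min) &
    univ$p_value < thresholds$p_max
  enr_p <- pmin(enrichment$p_over, enrichment$p_under)
  subs <- enrichment$subpathway[enrichment$K >= thresholds$subpathway_min_size &
                                  enr_p < thresholds$subpathway_p_max]
  structure(list(contrast = attr(univ, "contrast"),
                 table = univ,
                 selected_metabolites = data.frame(
                   metabolite_id = univ$metabolite_id[sel],
                   direction = univ$direction[sel]),
                 selected_subpathways = sort(subs),
                 model_validated = NA),
            class = "selection_result")
}

#' Write a pipeline result to disk
#'
#' Emits per-contrast selection TSVs, the significance count table, Venn
#' partitions and the run manifest. Output is byte-stable for a fixed
#' result object.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  wtsv(result$filter_report, file.path(dir, "filter_report.tsv"))
  wtsv(result$counts, file.path(dir, "significance_counts.tsv"))
  sel_dir <- file.path(dir, "selection")
  dir.create(sel_dir, showWarnings = FALSE)
  for (nm in names(result$selection))
    wtsv(result$selection[[nm]]$table,
         file.path(sel_dir, paste0(nm, ".tsv")))
  jsonlite::write_json(result$venn, file.path(dir, "venn.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("radmetab pipeline result\n")
  cat(sprintf("  samples: %d   metabolites retained: %d of %d\n",
              x$manifest$n_samples, x$manifest$n_metabolites_retained,
              x$manifest$n_metabolites_input))
  cat(sprintf("  contrasts run: %d   skipped: %d\n",
              length(x$univariate), length(x$skipped)))
  n_sel <- vapply(x$selection, function(s) nrow(s$selected_metabolites),
                  integer(1))
  if (length(n_sel))
    cat(sprintf("  selected metabolites (post-filter): median %d, max %d (%s)\n",
                as.integer(stats::median(n_sel)), max(n_sel),
                names(n_sel)[which.max(n_sel)]))
  invisible(x)
}
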