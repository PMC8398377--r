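#' Thresholds for composite biomarker selection
#'
#' The composite rule selects a metabolite when it passes every criterion:
#' fold change above `fc_min` (two-sided), Welch p below `p_max`, VIP above
#' `vip_min` from a validated OPLS-DA model, and membership in a subpathway
#' with at least `subpathway_min_size` tested metabolites whose
#' hypergeometric enrichment p falls below `subpathway_p_max`. Model
#' validation means permutation p < 0.05 and Q2 > 0 (configurable in
#' [validate_oplsda()]).
#'
#' @param fc_min fold-change cutoff, applied as `|log2 FC| > log2(fc_min)`.
#' @param p_max Welch p-value cutoff.
#' @param vip_min VIP cutoff.
#' @param subpathway_min_size minimum tested subpathway size.
#' @param subpathway_p_max subpathway enrichment p cutoff.
#' @param require_validated_model require the contrast's OPLS-DA model to
#'   validate before any metabolite can be selected (default `TRUE`).
#' @return a `selection_thresholds` list.
#' @export
selection_thresholds <- function(fc_min = 2, p_max = 0.05, vip_min = 1.0,
                                 subpathway_min_size = 5,
                                 subpathway_p_max = 0.05,
                                 require_validated_model = TRUE) {
  stopifnot(fc_min > 0, p_max > 0, p_max <= 1, vip_min > 0,
            subpathway_min_size > 0, subpathway_p_max > 0,
            subpathway_p_max <= 1)
  structure(list(fc_min = fc_min, p_max = p_max, vip_min = vip_min,
                 subpathway_min_size = subpathway_min_size,
                 subpathway_p_max = subpathway_p_max,
                 require_validated_model = require_validated_model),
            class = "selection_thresholds")
}

#' Composite biomarker selection for one contrast
#'
#' Intersects the univariate, multivariate and pathway evidence under a
#' [selection_thresholds()] rule and records, for every rejected metabolite,
#' which criteria removed it. Metabolites absent from the annotation can
#' never be selected (reason `"unannotated"`).
#'
#' @param univariate a [run_contrast()] result table.
#' @param vip named VIP vector covering the same metabolites.
#' @param model_validated logical: did the contrast's OPLS-DA model pass
#'   validation (ignored unless `require_validated_model`).
#' @param enrichment an [enrich_subpathways()] result for this contrast
#'   (tested subpathways only; its `small_subpathways` attribute is used for
#'   the size reason).
#' @param annotation annotation data.frame.
#' @param thresholds a [selection_thresholds()].
#' @return a `selection_result`: `contrast`, `table` (per-metabolite
#'   evidence, `selected` flag and `reasons`), `selected_metabolites`
#'   (data.frame id + direction), `selected_subpathways` (character),
#'   `model_validated`.
#' @export
composite_select <- function(univariate, vip, model_validated, enrichment,
                             annotation, thresholds = selection_thresholds()) {
  ids <- univariate$metabolite_id
  if (!all(ids %in% names(vip)))
    stop("VIP table does not cover the univariate background")
  vip <- vip[ids]
  ann_idx <- match(ids, annotation$metabolite_id)
  subp <- annotation$subpathway[ann_idx]
  superp <- annotation$superpathway[ann_idx]

  tested <- enrichment$subpathway
  enr_p <- pmin(enrichment$p_over, enrichment$p_under)
  sub_ok <- tested[enrichment$K >= thresholds$subpathway_min_size &
                     enr_p < thresholds$subpathway_p_max]

  pass_fc <- abs(univariate$log2_fc) > log2(thresholds$fc_min)
  pass_p <- univariate$p_value < thresholds$p_max
  pass_vip <- vip > thresholds$vip_min
  annotated <- !is.na(subp)
  pass_sub_size <- annotated & subp %in% tested
  pass_sub_p <- annotated & subp %in% sub_ok
  pass_model <- if (thresholds$require_validated_model)
    isTRUE(model_validated) else TRUE

  selected <- pass_fc & pass_p & pass_vip & pass_sub_size & pass_sub_p &
    pass_model
  reasons <- vapply(seq_along(ids), function(i) {
    if (selected[i]) return("")
    r <- character(0)
    if (!pass_fc[i]) r <- c(r, "fold change below threshold")
    if (!pass_p[i]) r <- c(r, "p-value above threshold")
    if (!pass_vip[i]) r <- c(r, "VIP below threshold")
    if (!annotated[i]) r <- c(r, "unannotated")
    else if (!pass_sub_size[i]) r <- c(r, "subpathway below min size")
    else if (!pass_sub_p[i]) r <- c(r, "subpathway not enriched")
    if (!pass_model) r <- c(r, "OPLS-DA model not validated")
    paste(r, collapse = "; ")
  }, character(1))

  tab <- data.frame(metabolite_id = ids, subpathway = subp,
                    superpathway = superp,
                    fold_change = univariate$fold_change,
                    log2_fc = univariate$log2_fc,
                    p_value = univariate$p_value,
                    q_value = univariate$q_value,
                    vip = unname(vip),
                    direction = univariate$direction,
                    selected = selected, reasons = reasons)
  sel_sub <- sort(intersect(sub_ok, unique(subp[selected])))
  structure(list(contrast = attr(univariate, "contrast"),
                 table = tab,
                 selected_metabolites = tab[selected,
                                            c("metabolite_id", "direction")],
                 selected_subpathways = sel_sub,
                 model_validated = isTRUE(model_validated)),
            class = "selection_result")
}

#' Remove sham time-drift markers from a candidate selection
#'
#' Time-varying-confounder filter: metabolites (and subpathways) selected in
#' the sham arm for the same timepoint contrast reflect time drift rather
#' than radiation, and are removed from the irradiated arm's selection.
#' Removals are recorded in the table with reason `"sham time drift"`. The
#' operation is idempotent.
#'
#' @param candidate `selection_result` for an irradiated arm at a TP1-vs-TPk
#'   contrast.
#' @param sham `selection_result` for the sham (0 Gy) arm at the same
#'   timepoint contrast.
#' @return the filtered `selection_result`, with a `confounders_removed`
#'   element listing what was dropped.
#' @export
confounder_filter <- function(candidate, sham) {
  stopifnot(inherits(candidate, "selection_result"),
            inherits(sham, "selection_result"))
  tp_of <- function(ctr) sub("^.*Gy_", "", ctr)
  if (!identical(tp_of(candidate$contrast), tp_of(sham$contrast)))
    stop(sprintf("contrast mismatch: '%s' vs sham '%s'",
                 candidate$contrast, sham$contrast))
  drop_met <- intersect(candidate$selected_metabolites$metabolite_id,
                        sham$selected_metabolites$metabolite_id)
  drop_sub <- intersect(candidate$selected_subpathways,
                        sham$selected_subpathways)
  out <- candidate
  hit <- out$table$metabolite_id %in% drop_met & out$table$selected
  out$table$selected[hit] <- FALSE
  out$table$reasons[hit] <- "sham time drift"
  out$selected_metabolites <-
    out$table[out$table$selected, c("metabolite_id", "direction")]
  out$selected_subpathways <- setdiff(out$selected_subpathways, drop_sub)
  out$confounders_removed <- list(metabolites = drop_met,
                                  subpathways = drop_sub)
  out
}

#' Venn partition of named sets
#'
#' Counts the elements in each exclusive intersection region of 2-4 named
#' sets; region counts sum to the size of the union.
#'
#' @param sets named list of 2-4 character vectors.
#' @return data.frame with `region` (set names joined by `&`) and `count`,
#'   one row per non-empty combination pattern (2^k - 1 rows).
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4)
    stop("venn_partition handles 2-4 sets; report larger collections as a table")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  counts <- apply(combos, 1, function(pattern) {
    if (length(u) == 0) return(0L)
    sum(apply(member, 1, function(row) all(row == pattern)))
  })
  data.frame(region = apply(combos, 1, function(pattern)
    paste(names(sets)[as.logical(pattern)], collapse = "&")),
    count = as.integer(counts), row.names = NULL)
}

#' Per-dose abundance profile at a fixed timepoint
#'
#' Group means and dispersions of logged abundance across the dose arms at
#' one timepoint group — the dose-response view used to triage candidate
#' exposure markers.
#'
#' @param x imputed-stage [abundance_matrix()].
#' @param meta sample metadata.
#' @param metabolite_ids metabolites to profile.
#' @param timepoint timepoint group label.
#' @param sex_filter subset of `c("M", "F")` (default `"M"`).
#' @return data.frame: `metabolite_id`, `dose_gy`, `n`, `mean_log`,
#'   `sd_log`.
#' @export
dose_response_profile <- function(x, meta, metabolite_ids, timepoint,
                                  sex_filter = "M") {
  assert_stage(x, "imputed", "dose_response_profile")
  unknown <- setdiff(metabolite_ids, colnames(x))
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  sub <- meta[meta$sex %in% sex_filter & meta$timepoint == timepoint, ,
              drop = FALSE]
  if (!nrow(sub)) stop("no samples at timepoint ", timepoint)
  doses <- sort(unique(sub$dose_gy))
  rows <- lapply(metabolite_ids, function(m) {
    do.call(rbind, lapply(doses, function(d) {
      v <- unclass(x)[sub$sample_id[sub$dose_gy == d], m]
      data.frame(metabolite_id = m, dose_gy = d, n = length(v),
                 mean_log = mean(v), sd_log = stats::sd(v))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
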