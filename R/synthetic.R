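#' Study design configuration for the synthetic cohort
#'
#' Encodes the sampling layout of a two-cohort nonhuman-primate abdominal
#' irradiation study: per-(dose, day, sex, cohort) sample counts, the
#' grouping of study days into timepoint groups TP1..TP4, and a seed for
#' deterministic subject/volume assignment. The default reproduces the
#' published sampling table: doses 0/8/11/12.5/14 Gy, days -5/-1 (TP1),
#' 9/10 (TP2), 28/29 (TP3), 59/60 (TP4), sexes M/F, cohorts 2016/2017,
#' 200 samples in total.
#'
#' @param counts data.frame with columns `dose_gy`, `day`, `sex`, `cohort`,
#'   `n` (non-negative integers).
#' @param timepoint_map named character vector mapping day (as character) to
#'   a timepoint-group label.
#' @param seed integer seed used for subject volumes.
#' @return a `design_config` list.
#' @export
design_config <- function(counts = default_design_counts(),
                          timepoint_map = c("-5" = "TP1", "-1" = "TP1",
                                            "9"  = "TP2", "10" = "TP2",
                                            "28" = "TP3", "29" = "TP3",
                                            "59" = "TP4", "60" = "TP4"),
                          seed = 1L) {
  stopifnot(is.data.frame(counts),
            all(c("dose_gy", "day", "sex", "cohort", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("sample counts must be non-negative")
  if (any(counts$dose_gy < 0)) stop("dose values must be non-negative")
  days <- unique(as.character(counts$day))
  unmapped <- setdiff(days, names(timepoint_map))
  if (length(unmapped))
    stop("day(s) missing from timepoint_map: ", paste(unmapped, collapse = ", "))
  structure(list(counts = counts, timepoint_map = timepoint_map,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Default per-cell sample counts
#'
#' The published sampling table: one row per (dose, day, sex, cohort) cell.
#' Days -5, 9, 29 and 59 belong to the 2016 cohort (males only); days -1,
#' 10, 28 and 60 to the 2017 cohort (males and females).
#'
#' @return data.frame with columns `dose_gy`, `day`, `sex`, `cohort`, `n`.
#' @export
default_design_counts <- function() {
  # columns of the published table, in printed order
  cell <- data.frame(
    day    = c(-5L, -1L, -1L, 9L, 10L, 10L, 28L, 28L, 29L, 59L, 60L, 60L),
    sex    = c("M", "M", "F", "M", "M", "F", "M", "F", "M", "M", "M", "F"),
    cohort = c(2016L, 2017L, 2017L, 2016L, 2017L, 2017L, 2017L, 2017L,
               2016L, 2016L, 2017L, 2017L)
  )
  n <- rbind(
    `0`    = c(4, 1, 2, 4, 2, 2, 1, 2, 4, 4, 2, 2),
    `8`    = c(0, 6, 6, 0, 5, 5, 4, 3, 0, 0, 2, 2),
    `11`   = c(12, 6, 6, 12, 6, 5, 4, 3, 11, 10, 1, 1),
    `12.5` = c(12, 0, 0, 11, 0, 0, 0, 0, 7, 6, 0, 0),
    `14`   = c(0, 6, 6, 0, 3, 4, 2, 1, 0, 0, 2, 0)
  )
  out <- do.call(rbind, lapply(rownames(n), function(d) {
    data.frame(dose_gy = as.numeric(d), cell, n = as.integer(n[d, ]))
  }))
  rownames(out) <- NULL
  out
}

#' Generate per-sample metadata from a design configuration
#'
#' Expands the per-cell counts into one metadata record per sample. Subject
#' ids are assigned deterministically within each (dose, sex, cohort) arm:
#' the k-th sample drawn on each study day belongs to subject k of that arm,
#' giving the repeated-measures structure of a longitudinal animal study.
#' Plasma volumes are drawn once per sample from a narrow log-normal around
#' 0.5 mL using the config seed.
#'
#' @param config a [design_config()].
#' @return data.frame with columns `sample_id`, `subject_id`, `sex`,
#'   `dose_gy`, `day`, `cohort`, `timepoint`, `volume_ml`.
#' @export
generate_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  counts <- config$counts[config$counts$n > 0, , drop = FALSE]
  if (nrow(counts) == 0) {
    out <- data.frame(sample_id = character(), subject_id = character(),
                      sex = character(), dose_gy = numeric(), day = integer(),
                      cohort = integer(), timepoint = character(),
                      volume_ml = numeric())
    return(out)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    data.frame(sex = r$sex, dose_gy = r$dose_gy, day = r$day,
               cohort = r$cohort, replicate = seq_len(r$n))
  }))
  rows <- rows[order(rows$dose_gy, rows$day, rows$sex, rows$cohort, rows$replicate), ]
  rows$timepoint <- unname(config$timepoint_map[as.character(rows$day)])
  rows$subject_id <- sprintf("NHP_%sGy_%s_%d_%02d",
                             rows$dose_gy, rows$sex, rows$cohort, rows$replicate)
  rows$sample_id <- sprintf("S%03d", seq_len(nrow(rows)))
  set.seed(config$seed)
  rows$volume_ml <- round(stats::rlnorm(nrow(rows), log(0.5), 0.08), 4)
  out <- rows[, c("sample_id", "subject_id", "sex", "dose_gy", "day",
                  "cohort", "timepoint", "volume_ml")]
  rownames(out) <- NULL
  out
}

#' Planted-effect specification for the synthetic abundance generator
#'
#' Describes the ground-truth structure planted into a synthetic cohort:
#' log-normal metabolite baselines, dose- and time-dependent fold-change
#' effects on an affected subset, a dose-independent sham time drift on a
#' disjoint subset, subject-level random intercepts, biological noise, and
#' detection-limit (left-censoring) missingness.
#'
#' Defaults emulate the study-scale panel: 696 named metabolites of which 50
#' carry radiation effects (|log2 fold change| drawn uniformly from
#' [1.3, 3] with random sign), 20 drift with time in every arm including
#' sham, effects peak at TP2 and partially resolve by TP4, and roughly a
#' sixth of the panel sits near the detection limit so that the 20%
#' missingness filter has work to do.
#'
#' @param n_metabolites panel size.
#' @param n_affected number of metabolites carrying dose-dependent effects
#'   (`fraction_affected` may be given instead).
#' @param fraction_affected alternative to `n_affected`, in `[0, 1]`.
#' @param effect_log2fc_range magnitude range for the planted |log2 FC|.
#' @param dose_response named vector: dose -> effect multiplier.
#' @param time_profile named vector: timepoint group -> effect multiplier
#'   (peaking at TP2, decaying at TP3/TP4).
#' @param n_sham_drift number of dose-independent time-drifting metabolites.
#' @param sham_drift_log2fc magnitude of the sham drift at its peak.
#' @param baseline_log_mean_sd length-2 vector: mean and sd of the
#'   per-metabolite baseline log-intensity.
#' @param noise_log_sd within-group biological noise on the log scale (> 0).
#' @param subject_sd sd of subject-level random intercepts on the log scale.
#' @param missing_lod_quantile detection-limit quantile for the bulk of the
#'   panel, in `[0, 1)`.
#' @param high_missing_lod_quantile detection-limit quantile for the
#'   near-detection-limit subset.
#' @param n_high_missing size of the near-detection-limit subset.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(n_metabolites = 696L,
                        n_affected = 50L,
                        fraction_affected = NULL,
                        effect_log2fc_range = c(1.3, 3),
                        dose_response = c("0" = 0, "8" = 0.5, "11" = 0.8,
                                          "12.5" = 1, "14" = 1),
                        time_profile = c(TP1 = 0, TP2 = 1, TP3 = 0.5, TP4 = 0.25),
                        n_sham_drift = 20L,
                        sham_drift_log2fc = 1.5,
                        baseline_log_mean_sd = c(10, 1),
                        noise_log_sd = 0.4,
                        subject_sd = 0.15,
                        missing_lod_quantile = 0.05,
                        high_missing_lod_quantile = 0.25,
                        n_high_missing = 118L) {
  if (!is.null(fraction_affected)) {
    if (fraction_affected < 0 || fraction_affected > 1)
      stop("fraction_affected must lie in [0, 1]")
    n_affected <- round(fraction_affected * n_metabolites)
  }
  if (noise_log_sd <= 0) stop("noise_log_sd must be positive")
  if (missing_lod_quantile < 0 || missing_lod_quantile >= 1 ||
      high_missing_lod_quantile < 0 || high_missing_lod_quantile >= 1)
    stop("detection-limit quantiles must lie in [0, 1)")
  if (n_affected + n_sham_drift > n_metabolites)
    stop("affected and sham-drift sets exceed the panel size")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_affected = as.integer(n_affected),
                 effect_log2fc_range = effect_log2fc_range,
                 dose_response = dose_response,
                 time_profile = time_profile,
                 n_sham_drift = as.integer(n_sham_drift),
                 sham_drift_log2fc = sham_drift_log2fc,
                 baseline_log_mean_sd = baseline_log_mean_sd,
                 noise_log_sd = noise_log_sd,
                 subject_sd = subject_sd,
                 missing_lod_quantile = missing_lod_quantile,
                 high_missing_lod_quantile = high_missing_lod_quantile,
                 n_high_missing = as.integer(n_high_missing)),
            class = "effect_spec")
}

#' Generate a synthetic metabolite annotation hierarchy
#'
#' Partitions a metabolite panel into subpathways nested in superpathways,
#' mimicking the two-level annotation of an untargeted plasma panel
#' (amino acid, lipid, ... superpathways; subpathway sizes mostly 3-15).
#'
#' @param metabolite_ids character vector of metabolite ids.
#' @param mean_subpathway_size expected subpathway size.
#' @param seed integer seed.
#' @return annotation data.frame (`metabolite_id`, `subpathway`,
#'   `superpathway`).
#' @export
generate_annotation <- function(metabolite_ids, mean_subpathway_size = 7,
                                seed = 1L) {
  set.seed(seed)
  m <- length(metabolite_ids)
  supers <- c("Amino Acid", "Lipid", "Carbohydrate", "Nucleotide",
              "Cofactors and Vitamins", "Xenobiotics", "Peptide", "Energy")
  sizes <- integer(0)
  while (sum(sizes) < m) {
    s <- 3L + stats::rpois(1L, mean_subpathway_size - 3)
    sizes <- c(sizes, s)
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - m)
  if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
  sub_names <- sprintf("subpathway_%03d", seq_along(sizes))
  sub_super <- sample(supers, length(sizes), replace = TRUE)
  ids <- sample(metabolite_ids)   # scatter metabolites across subpathways
  ann <- data.frame(metabolite_id = ids,
                    subpathway = rep(sub_names, sizes),
                    superpathway = rep(sub_super, sizes))
  ann <- ann[order(match(ann$metabolite_id, metabolite_ids)), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# internal: sample n metabolites subpathway-coherently from `pool`. The set
# is assembled from whole subpathways of size >= min_size plus partial
# blocks of at least min_size members, so every contributing subpathway
# overlaps the set strongly enough for enrichment to see it. A scattered
# fallback exists only for annotations that cannot host coherent blocks.
sample_coherent_set <- function(annotation, pool, n_target, min_size = 5L) {
  if (n_target == 0) return(character(0))
  sub <- split(annotation$metabolite_id, annotation$subpathway)
  sub <- sub[vapply(sub, function(mm) length(mm) >= min_size && all(mm %in% pool),
                    logical(1))]
  pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  scatter <- function(chosen, r)
    c(chosen, list(..scattered = sample(setdiff(pool, unlist(chosen)), r)))
  chosen <- list()
  r <- as.integer(n_target)
  while (r > 0L) {
    if (r < min_size) {
      # too small for a coherent block: fold the smallest chosen
      # subpathway back into the remainder and retry (retiring it so the
      # loop cannot cycle)
      if (!length(chosen)) {
        chosen <- scatter(chosen, r)
        break
      }
      sizes <- vapply(chosen, length, integer(1))
      smallest <- names(which.min(sizes))
      r <- r + sizes[[smallest]]
      sub[[smallest]] <- NULL
      chosen[[smallest]] <- NULL
      next
    }
    usable <- setdiff(names(sub), names(chosen))
    if (!length(usable)) {
      chosen <- scatter(chosen, r)
      break
    }
    usable_sz <- vapply(usable, function(s) length(sub[[s]]), integer(1))
    hosts <- usable[usable_sz >= r]
    if (length(hosts)) {
      # one subpathway absorbs the whole remainder as a partial block
      s <- pick1(hosts)
      chosen[[s]] <- sample(sub[[s]], r)
      r <- 0L
    } else if (any(r - usable_sz == 0L | r - usable_sz >= min_size)) {
      # add a whole subpathway, keeping the remainder workable
      fits <- usable[r - usable_sz == 0L | r - usable_sz >= min_size]
      s <- pick1(fits)
      chosen[[s]] <- sub[[s]]
      r <- r - length(sub[[s]])
    } else if (r - min_size >= min_size && any(usable_sz >= r - min_size)) {
      # split the remainder into two partial blocks
      s <- pick1(usable[usable_sz >= r - min_size])
      chosen[[s]] <- sample(sub[[s]], r - min_size)
      r <- min_size
    } else if (length(chosen)) {
      # stuck: no workable block at this remainder; fold and retire the
      # smallest chosen subpathway and retry with a larger remainder
      sizes <- vapply(chosen, length, integer(1))
      smallest <- names(which.min(sizes))
      r <- r + sizes[[smallest]]
      sub[[smallest]] <- NULL
      chosen[[smallest]] <- NULL
    } else {
      chosen <- scatter(chosen, r)
      break
    }
  }
  unname(unlist(chosen))
}

#' Generate synthetic abundances with known ground truth
#'
#' Simulates a raw-stage abundance matrix over a sample design: per-metabolite
#' log-normal baselines, subject random intercepts, planted dose x time
#' effects on the affected set, a dose-independent time drift on the
#' sham-drift set, and i.i.d. log-scale noise. Intensities are strictly
#' positive; censoring is applied separately by [apply_missingness()].
#'
#' @param design metadata data.frame from [generate_design()].
#' @param spec an [effect_spec()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param annotation optional annotation data.frame; when supplied, affected
#'   and sham-drift metabolites are sampled subpathway-coherently (whole
#'   subpathways of size >= 5), the structure pathway enrichment is meant to
#'   detect. When `NULL`, sets are sampled uniformly at random.
#' @return list with elements `matrix` (raw-stage [abundance_matrix()]) and
#'   `truth` (list: `affected` data.frame with per-metabolite signed log2
#'   effects, `sham_drift` ids with drift signs, `high_missing` ids,
#'   `dose_response`, `time_profile`).
#' @export
generate_abundances <- function(design, spec = effect_spec(), seed = 1L,
                                annotation = NULL) {
  if (nrow(design) == 0) stop("design is empty")
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(seed)
  m <- spec$n_metabolites
  met_ids <- sprintf("met_%04d", seq_len(m))

  # ground-truth set assignment (disjoint by construction)
  if (!is.null(annotation)) {
    stopifnot(setequal(annotation$metabolite_id, met_ids))
    affected <- sample_coherent_set(annotation, met_ids, spec$n_affected)
    drift <- sample_coherent_set(annotation, setdiff(met_ids, affected),
                                 spec$n_sham_drift)
  } else {
    affected <- sample(met_ids, spec$n_affected)
    drift <- sample(setdiff(met_ids, affected), spec$n_sham_drift)
  }
  high_missing <- sample(setdiff(met_ids, c(affected, drift)),
                         min(spec$n_high_missing, m - length(affected) - length(drift)))

  eff_sign <- sample(c(-1, 1), length(affected), replace = TRUE)
  eff_mag <- stats::runif(length(affected), spec$effect_log2fc_range[1],
                          spec$effect_log2fc_range[2])
  eff_log2 <- eff_sign * eff_mag
  drift_sign <- sample(c(-1, 1), length(drift), replace = TRUE)

  baseline <- stats::rnorm(m, spec$baseline_log_mean_sd[1],
                           spec$baseline_log_mean_sd[2])
  names(baseline) <- met_ids

  n <- nrow(design)
  dr <- spec$dose_response[as.character(design$dose_gy)]
  tp <- spec$time_profile[design$timepoint]
  if (anyNA(dr)) stop("design contains a dose absent from spec$dose_response")
  if (anyNA(tp)) stop("design contains a timepoint absent from spec$time_profile")

  # subject random intercepts, one draw per (subject, metabolite) would be
  # too strong; one scalar intercept per subject shifts all metabolites
  subjects <- unique(design$subject_id)
  subj_int <- stats::rnorm(length(subjects), 0, spec$subject_sd)
  names(subj_int) <- subjects

  logx <- matrix(rep(baseline, each = n), nrow = n,
                 dimnames = list(design$sample_id, met_ids))
  logx <- logx + subj_int[design$subject_id]

  eff_mat <- outer(dr * tp, eff_log2 * log(2))
  logx[, affected] <- logx[, affected] + eff_mat
  drift_mat <- outer(tp, drift_sign * spec$sham_drift_log2fc * log(2))
  logx[, drift] <- logx[, drift] + drift_mat

  logx <- logx + matrix(stats::rnorm(n * m, 0, spec$noise_log_sd), n, m)

  truth <- list(
    affected = data.frame(metabolite_id = affected, log2fc = eff_log2),
    sham_drift = data.frame(metabolite_id = drift, sign = drift_sign),
    high_missing = high_missing,
    dose_response = spec$dose_response,
    time_profile = spec$time_profile
  )
  list(matrix = abundance_matrix(exp(logx), stage = "raw"), truth = truth)
}

#' Apply detection-limit missingness to a raw abundance matrix
#'
#' Left-censors each metabolite at its own empirical intensity quantile:
#' entries strictly below the per-metabolite `lod_quantile` threshold become
#' missing, emulating a detection limit. A missing-completely-at-random
#' mechanism is available for sensitivity work.
#'
#' @param x raw-stage [abundance_matrix()] with strictly positive entries.
#' @param lod_quantile scalar or per-metabolite named vector in `[0, 1)`.
#' @param seed integer seed (used only by the `"mcar"` mechanism; censoring
#'   at an empirical quantile is deterministic).
#' @param mechanism `"censor"` (default, left-censoring at the quantile
#'   threshold) or `"mcar"` (each entry missing independently with
#'   probability `lod_quantile`).
#' @return a raw-stage `abundance_matrix` with `NA`s planted.
#' @export
apply_missingness <- function(x, lod_quantile, seed = 1L,
                              mechanism = c("censor", "mcar")) {
  mechanism <- match.arg(mechanism)
  assert_stage(x, "raw", "apply_missingness")
  if (any(x <= 0, na.rm = TRUE)) stop("matrix must be strictly positive")
  if (any(lod_quantile >= 1) || any(lod_quantile < 0))
    stop("lod_quantile must lie in [0, 1)")
  q <- rep_len(lod_quantile, ncol(x))
  if (!is.null(names(lod_quantile))) {
    q <- lod_quantile[colnames(x)]
    if (anyNA(q)) stop("named lod_quantile does not cover all metabolites")
  }
  vals <- unclass(x)
  if (mechanism == "censor") {
    for (j in seq_len(ncol(vals))) {
      if (q[j] <= 0) next
      thr <- stats::quantile(vals[, j], q[j], na.rm = TRUE, names = FALSE)
      vals[which(vals[, j] < thr), j] <- NA
    }
  } else {
    set.seed(seed)
    miss <- matrix(stats::runif(length(vals)) < rep(q, each = nrow(vals)),
                   nrow(vals), ncol(vals))
    vals[miss] <- NA
  }
  as_abundance(vals, "raw")
}

#' Simulate a complete synthetic cohort
#'
#' One call producing everything downstream stages need: the sample design,
#' a pathway annotation, a raw abundance matrix with planted ground truth,
#' and detection-limit missingness (the near-detection-limit subset censored
#' at the high quantile, the rest at the bulk quantile).
#'
#' @param config a [design_config()].
#' @param spec an [effect_spec()].
#' @param seed master integer seed.
#' @param males_only drop female samples before simulating abundances
#'   (default `FALSE`; downstream contrast functions have their own sex
#'   filter).
#' @return list: `design`, `annotation`, `matrix` (raw stage, with
#'   missingness), `truth`.
#' @export
simulate_cohort <- function(config = design_config(), spec = effect_spec(),
                            seed = 1L, males_only = FALSE) {
  design <- generate_design(config)
  if (males_only) design <- design[design$sex == "M", , drop = FALSE]
  met_ids <- sprintf("met_%04d", seq_len(spec$n_metabolites))
  annotation <- generate_annotation(met_ids, seed = seed + 1L)
  sim <- generate_abundances(design, spec, seed = seed + 2L,
                             annotation = annotation)
  lod <- rep(spec$missing_lod_quantile, spec$n_metabolites)
  names(lod) <- met_ids
  lod[sim$truth$high_missing] <- spec$high_missing_lod_quantile
  mat <- apply_missingness(sim$matrix, lod, seed = seed + 3L)
  list(design = design, annotation = annotation, matrix = mat,
       truth = sim$truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the CSV dialects used throughout the package plus a ground-truth
#' JSON, so a cohort can be regenerated and inspected outside R.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_csv(cohort$matrix, file.path(dir, "abundance.csv"))
  write_metadata_csv(cohort$design, file.path(dir, "metadata.csv"))
  write_annotation_csv(cohort$annotation, file.path(dir, "annotation.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(dir)
}
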