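#' Abundance matrix container
#'
#' A samples x metabolites intensity matrix carrying a processing-stage tag.
#' Stages advance strictly in the order `raw` -> `normalized` -> `logged` ->
#' `imputed`; each preprocessing step checks the stage of its input so the
#' pipeline cannot be applied out of order.
#'
#' @param values numeric matrix (samples in rows, metabolites in columns) with
#'   unique row and column names. `NA` marks a non-detected (missing) entry.
#' @param stage one of `"raw"`, `"normalized"`, `"logged"`, `"imputed"`.
#' @return an `abundance_matrix` object (a numeric matrix with a `stage`
#'   attribute).
#' @export
abundance_matrix <- function(values, stage = c("raw", "normalized", "logged", "imputed")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs sample (row) and metabolite (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in abundance matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite ids in abundance matrix")
  if (stage %in% c("raw", "normalized") && any(values < 0, na.rm = TRUE))
    stop("negative intensities are not allowed at stage '", stage, "'")
  if (stage == "imputed" && anyNA(values))
    stop("an imputed-stage matrix may not contain missing values")
  structure(values, stage = stage, class = c("abundance_matrix", "matrix", "array"))
}

#' Processing stage of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return the stage string.
#' @export
matrix_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) stop("not an abundance_matrix: no stage attribute")
  s
}

# internal: check stage and fail with a readable message
assert_stage <- function(x, expected, op) {
  s <- matrix_stage(x)
  if (!s %in% expected)
    stop(sprintf("%s expects a matrix at stage %s, got '%s' (stages advance raw -> normalized -> logged -> imputed)",
                 op, paste(sQuote(expected), collapse = " or "), s))
  invisible(x)
}

# internal: rebuild the class/attribute wrapper after matrix surgery
as_abundance <- function(values, stage) {
  structure(as.matrix(values), stage = stage,
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d metabolites, stage '%s', %d missing entries\n",
              nrow(x), ncol(x), matrix_stage(x), sum(is.na(x))))
  invisible(x)
}

#' Write / read an abundance matrix as CSV
#'
#' The on-disk dialect is a plain CSV whose first column is `sample_id` and
#' whose remaining columns are metabolite ids; an empty cell encodes a
#' missing (non-detected) value.
#'
#' @param x an `abundance_matrix`.
#' @param path file path.
#' @return `write_abundance_csv` returns `path` invisibly; `read_abundance_csv`
#'   returns an `abundance_matrix`.
#' @export
write_abundance_csv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_abundance_csv
#' @param stage stage tag to attach on read (the CSV itself is untagged).
#' @export
read_abundance_csv <- function(path, stage = "raw") {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  abundance_matrix(m, stage = stage)
}

#' Write / read the sample metadata table
#'
#' Columns: `sample_id`, `subject_id`, `sex`, `dose_gy`, `day`, `cohort`,
#' `timepoint`, `volume_ml`.
#' @param meta metadata data.frame.
#' @param path file path.
#' @export
write_metadata_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  meta <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(sample_id = "character",
                                         subject_id = "character"))
  check_metadata(meta)
  meta
}

# internal: minimal schema check for metadata
check_metadata <- function(meta) {
  need <- c("sample_id", "subject_id", "sex", "dose_gy", "day", "cohort",
            "timepoint", "volume_ml")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  invisible(meta)
}

#' Write / read the metabolite annotation table
#'
#' Columns: `metabolite_id`, `subpathway`, `superpathway`. Each metabolite
#' maps to exactly one subpathway and each subpathway to one superpathway.
#' @param annotation annotation data.frame.
#' @param path file path.
#' @export
write_annotation_csv <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  ann <- utils::read.csv(path, check.names = FALSE)
  check_annotation(ann)
  ann
}

# internal: enforce the two-level hierarchy invariants
check_annotation <- function(annotation) {
  need <- c("metabolite_id", "subpathway", "superpathway")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$metabolite_id))
    stop("a metabolite maps to more than one subpathway")
  sp <- unique(annotation[, c("subpathway", "superpathway")])
  if (anyDuplicated(sp$subpathway))
    stop("a subpathway maps to more than one superpathway")
  invisible(annotation)
}
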