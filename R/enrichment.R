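#' Hypergeometric subpathway enrichment
#'
#' Tests each annotated subpathway for over- and under-representation of a
#' significant-metabolite set within a background of tested metabolites,
#' using exact hypergeometric tail probabilities. With background size `N`,
#' subpathway size `K`, significant-set size `n` and overlap `k`, the
#' over-enrichment p-value is `P(X >= k)` and the under-enrichment p-value
#' `P(X <= k)` for `X ~ Hypergeometric(N, K, n)`; both tails include the
#' point mass at `k`. A subpathway is called significant when the smaller
#' tail falls below `alpha`; no correction across subpathways is applied by
#' default (a BH flag is available).
#'
#' Subpathways with fewer than `min_size` background members are not tested
#' and are listed in the `small_subpathways` attribute. Metabolites absent
#' from the annotation are dropped with a warning and counted in the
#' `unannotated` attribute.
#'
#' @param significant_set character vector of significant metabolite ids
#'   (must be a subset of `background_set`).
#' @param background_set character vector of all tested metabolite ids
#'   (those surviving preprocessing).
#' @param annotation annotation data.frame (`metabolite_id`, `subpathway`,
#'   `superpathway`).
#' @param min_size minimum subpathway size in the background (default 5).
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @param bh_across_sets apply BH across subpathways before flagging
#'   (default `FALSE`).
#' @return data.frame with one row per tested subpathway: `subpathway`,
#'   `superpathway`, `N`, `K`, `n`, `k`, `p_over`, `p_under`, `direction`,
#'   `significant`; attributes `small_subpathways` (data.frame) and
#'   `unannotated` (ids).
#' @export
enrich_subpathways <- function(significant_set, background_set, annotation,
                               min_size = 5, alpha = 0.05,
                               bh_across_sets = FALSE) {
  check_annotation(annotation)
  if (!all(significant_set %in% background_set))
    stop("significant_set must be a subset of background_set")
  unannotated <- setdiff(background_set, annotation$metabolite_id)
  if (length(unannotated))
    warning(length(unannotated),
            " background metabolite(s) missing from the annotation were dropped")
  bg <- intersect(background_set, annotation$metabolite_id)
  sig <- intersect(significant_set, bg)
  ann <- annotation[annotation$metabolite_id %in% bg, , drop = FALSE]
  N <- length(bg)
  n <- length(sig)
  ksub <- split(ann$metabolite_id, ann$subpathway)
  sub_super <- unique(ann[, c("subpathway", "superpathway")])
  rows <- lapply(names(ksub), function(s) {
    K <- length(ksub[[s]])
    k <- sum(sig %in% ksub[[s]])
    data.frame(subpathway = s,
               superpathway = sub_super$superpathway[sub_super$subpathway == s],
               N = N, K = K, n = n, k = k,
               p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               p_under = stats::phyper(k, K, N - K, n))
  })
  tab <- do.call(rbind, rows)
  small <- tab[tab$K < min_size, , drop = FALSE]
  tab <- tab[tab$K >= min_size, , drop = FALSE]
  tab$direction <- ifelse(tab$p_over <= tab$p_under, "over", "under")
  p_min <- pmin(tab$p_over, tab$p_under)
  if (bh_across_sets) p_min <- bh_adjust(p_min)
  tab$significant <- p_min < alpha
  tab <- tab[order(pmin(tab$p_over, tab$p_under), tab$subpathway), , drop = FALSE]
  rownames(tab) <- NULL
  rownames(small) <- NULL
  attr(tab, "small_subpathways") <- small
  attr(tab, "unannotated") <- unannotated
  tab
}

#' Exhaustive hypergeometric tail oracle
#'
#' Exact tail probabilities by explicit summation of the hypergeometric
#' point masses `C(K, i) C(N-K, n-i) / C(N, n)`. Intended as an independent
#' cross-check of [enrich_subpathways()] at small `N` in tests; summation is
#' exact for `N <= 30`.
#'
#' @param N background size (<= 30).
#' @param K subpathway size in the background.
#' @param n significant-set size.
#' @param k overlap.
#' @return list with `p_over` (`P(X >= k)`) and `p_under` (`P(X <= k)`).
#' @export
enrichment_oracle <- function(N, K, n, k) {
  if (N > 30) stop("oracle restricted to N <= 30")
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0)
    stop("inconsistent hypergeometric parameters")
  i_all <- max(0, n - (N - K)):min(K, n)
  mass <- choose(K, i_all) * choose(N - K, n - i_all) / choose(N, n)
  list(p_over = sum(mass[i_all >= k]),
       p_under = sum(mass[i_all <= k]))
}
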