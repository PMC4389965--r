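#' One-sided Fisher exact test for term over-representation
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' `k` annotated genes in a study set of size `n` drawn from a population
#' of `N` genes of which `K` are annotated. This is the per-term test of
#' term-for-term enrichment analysis. Vectorized over its arguments.
#'
#' @param k Annotated genes in the study set.
#' @param n Study-set size.
#' @param K Annotated genes in the population.
#' @param N Population size.
#' @return Exact p-value(s) in `[0, 1]`.
#' @examples
#' fisher_one_sided(5, 20, 10, 100)
#' @export
fisher_one_sided <- function(k, n, K, N) {
  if (any(n > N) || any(K > N) || any(k > pmin(n, K)) || any(k < 0)) {
    stop_bad_arg("need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `p_adj(i) = min over j >= rank(i) of (p(j) * m / j)`, capped at 1 and
#' order-preserving.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Term-for-term GO enrichment of a study gene set
#'
#' Tests each term annotated in the population with a one-sided Fisher
#' exact test ([fisher_one_sided()]) against the hypergeometric null,
#' adjusts for multiple testing by Benjamini-Hochberg, and flags terms with
#' adjusted p below `alpha` (default 0.1) as significant. Terms are tested
#' independently of the ontology graph; any annotation propagation is the
#' input table's responsibility.
#'
#' @param study Character vector of study genes (must be contained in the
#'   population).
#' @param annotations Tibble/data frame with columns `gene` and `term`.
#' @param population Character vector of background genes. Defaults to all
#'   genes appearing in `annotations`; in a time-course workflow a natural
#'   choice is the set of genes passing the intensity filter.
#' @param alpha Adjusted-p significance level (default 0.1).
#' @return A tibble sorted by raw p: `term`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_adj`, `significant`. An empty study set yields an empty table.
#' @export
enrich <- function(study, annotations, population = NULL, alpha = 0.1) {
  annotations <- dplyr::distinct(
    tibble::as_tibble(annotations), .data$gene, .data$term
  )
  population <- unique(population %||% annotations$gene)
  study <- unique(study)
  if (!all(study %in% population)) {
    stop_bad_arg("study set must be a subset of the population")
  }
  empty <- tibble::tibble(
    term = character(), k = integer(), n = integer(), K = integer(),
    N = integer(), p_raw = numeric(), p_adj = numeric(),
    significant = logical()
  )
  if (length(study) == 0L) return(empty)
  annotations <- dplyr::filter(annotations, .data$gene %in% population)
  if (nrow(annotations) == 0L) return(empty)
  annotations |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene),
      k = dplyr::n_distinct(.data$gene[.data$gene %in% study])
    ) |>
    dplyr::mutate(
      n = length(study),
      N = length(population),
      p_raw = fisher_one_sided(.data$k, .data$n, .data$K, .data$N),
      p_adj = benjamini_hochberg(.data$p_raw),
      significant = .data$p_adj < alpha
    ) |>
    dplyr::select("term", "k", "n", "K", "N", "p_raw", "p_adj", "significant") |>
    dplyr::arrange(.data$p_raw, .data$term)
}
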