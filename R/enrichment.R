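# Hypergeometric over-representation of a gene set against a gene-set
# collection, with BH correction across terms.

#' Hypergeometric gene-set over-representation
#'
#' For each term with `K` genes in the universe (size `N`) and a query of
#' size `n` with `k` genes overlapping the term, computes the upper-tail
#' hypergeometric probability `P(X >= k)` and adjusts across the
#' collection by Benjamini-Hochberg.
#'
#' @param query Character vector of gene IDs. Genes outside the universe
#'   are dropped with a warning.
#' @param collection Gene-set tibble from [read_gmt()] (`term_id`,
#'   `name`, list-column `genes`).
#' @param universe Character vector: the gene universe, typically all
#'   genes in the filtered count matrix.
#' @return Tibble sorted by `p` ascending (ties by `term_id`):
#'   `term_id`, `name`, `k`, `K`, `n`, `N`, `p`, `adj_p`.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) abort("Empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  n <- length(query)
  res <- purrr::pmap_dfr(collection, function(term_id, name, genes, ...) {
    g <- intersect(unique(genes), universe)
    K <- length(g)
    k <- length(intersect(query, g))
    # upper tail P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term_id = term_id, name = name, k = k, K = K, n = n, N = N, p = p)
  })
  res$adj_p <- if (nrow(res) > 0) bh_adjust(res$p) else double()
  dplyr::arrange(res, .data$p, .data$term_id)
}
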