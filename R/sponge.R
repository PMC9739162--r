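# miRNA selection, target integration and tripartite network assembly.

#' Select candidate sponged miRNAs from a site-count table
#'
#' Two-stage rule. Stage 1 (false-positive control): keep a miRNA only if
#' it has a nonzero site count in at least `min_circ` distinct DE
#' circRNAs — per tissue when `circ_tissue` is given (a miRNA qualifies
#' if any tissue reaches the cutoff), pooled otherwise. Stage 2: rank the
#' kept miRNAs by total site count summed over the upregulated DE
#' circRNAs (union across tissues), descending, ties broken
#' lexicographically by miRNA ID, and return the top `top_k`.
#'
#' @param sites `sponge_sites` tibble (or any tibble with `circ_id`,
#'   `mirna_id`, `n_sites`).
#' @param de_circ_up Character vector of upregulated DE circRNA IDs
#'   (union across tissues), or a named list of per-tissue ID vectors.
#' @param min_circ Stage-1 cutoff (default 10 DE circRNAs).
#' @param top_k Number of miRNAs returned (default 12). If fewer survive
#'   stage 1, all survivors are returned with a warning.
#' @param circ_tissue Optional named character vector mapping `circ_id`
#'   to tissue for per-tissue stage-1 counting.
#' @return Tibble of selected miRNAs: `mirna_id`, `rank`,
#'   `sites_in_up`, plus one `n_circ_<tissue>` qualifying-count column
#'   per tissue (or `n_circ` when pooled).
#' @export
select_mirnas <- function(sites, de_circ_up, min_circ = 10, top_k = 12,
                          circ_tissue = NULL) {
  stopifnot(nrow(sites) > 0)
  if (is.list(de_circ_up) && !is.data.frame(de_circ_up)) {
    de_circ_up <- unique(unlist(de_circ_up, use.names = FALSE))
  }
  tbl <- dplyr::filter(sites, !is.na(.data$n_sites))
  if (is.null(circ_tissue)) {
    qual <- tbl |>
      dplyr::group_by(.data$mirna_id) |>
      dplyr::summarise(n_circ = sum(.data$n_sites > 0), .groups = "drop")
    kept <- qual$mirna_id[qual$n_circ >= min_circ]
  } else {
    qual <- tbl |>
      dplyr::mutate(tissue = unname(circ_tissue[.data$circ_id])) |>
      dplyr::filter(!is.na(.data$tissue)) |>
      dplyr::group_by(.data$mirna_id, .data$tissue) |>
      dplyr::summarise(n_circ = sum(.data$n_sites > 0), .groups = "drop")
    kept <- qual |>
      dplyr::group_by(.data$mirna_id) |>
      dplyr::summarise(best = max(.data$n_circ), .groups = "drop") |>
      dplyr::filter(.data$best >= min_circ) |>
      dplyr::pull("mirna_id")
    qual <- tidyr::pivot_wider(
      qual, names_from = "tissue", values_from = "n_circ",
      names_prefix = "n_circ_", values_fill = 0L
    )
  }
  ranked <- tbl |>
    dplyr::filter(.data$mirna_id %in% kept, .data$circ_id %in% de_circ_up) |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(sites_in_up = sum(.data$n_sites), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(mirna_id = kept), by = "mirna_id") |>
    dplyr::mutate(sites_in_up = dplyr::coalesce(.data$sites_in_up, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$sites_in_up), .data$mirna_id)
  if (nrow(ranked) < top_k) {
    warn(paste0("Only ", nrow(ranked), " miRNA(s) survive the >= ", min_circ,
                " DE-circRNA cutoff; returning all of them"))
  }
  out <- utils::head(ranked, top_k)
  out$rank <- seq_len(nrow(out))
  dplyr::left_join(out, qual, by = "mirna_id")
}

.de_up_genes <- function(de_genes, alpha) {
  if (is.data.frame(de_genes)) de_genes <- list(de_genes)
  purrr::map_dfr(de_genes, function(d) {
    dplyr::filter(d, .data$adj_p < alpha, .data$log2fc > 0) |>
      dplyr::select("feature_id", "log2fc", "adj_p")
  }) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::slice_min(.data$adj_p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Intersect selected-miRNA targets with upregulated DE genes
#'
#' The affected gene set: genes that are predicted targets of at least
#' one selected miRNA and are significantly upregulated
#' (`adj_p < alpha`, `log2fc > 0`) in at least one tissue.
#'
#' @param selected Selected miRNAs ([select_mirnas()] output or a
#'   character vector of IDs).
#' @param targets Target table tibble (`mirna_id`, `gene_id`,
#'   `context_score`).
#' @param de_genes A gene-level `sponge_de` tibble, or a named list of
#'   per-tissue DE tibbles (a gene qualifies if upregulated-significant
#'   in any).
#' @param alpha Significance cutoff on `adj_p` (default 0.05).
#' @param max_context_score Optional upper bound on `context_score`
#'   (more negative = stronger); `NULL` (default) disables score
#'   filtering.
#' @return Tibble of affected genes: `gene_id`, `mirna_ids`
#'   (comma-collapsed), `n_mirnas`, `log2fc`, `adj_p` (best across
#'   tissues).
#' @export
integrate_targets <- function(selected, targets, de_genes, alpha = 0.05,
                              max_context_score = NULL) {
  ids <- if (is.data.frame(selected)) selected$mirna_id else selected
  if (nrow(targets) == 0) {
    warn("Empty target table; affected gene set is empty")
    return(tibble::tibble(gene_id = character(), mirna_ids = character(),
                          n_mirnas = integer(), log2fc = double(), adj_p = double()))
  }
  tg <- dplyr::filter(targets, .data$mirna_id %in% ids)
  if (!is.null(max_context_score)) {
    tg <- dplyr::filter(tg, .data$context_score <= max_context_score)
  }
  up <- .de_up_genes(de_genes, alpha)
  tg |>
    dplyr::inner_join(up, by = c(gene_id = "feature_id")) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mirna_ids = paste(sort(unique(.data$mirna_id)), collapse = ","),
      n_mirnas = dplyr::n_distinct(.data$mirna_id),
      log2fc = .data$log2fc[1],
      adj_p = .data$adj_p[1],
      .groups = "drop"
    )
}

#' Build the tripartite circRNA-miRNA-mRNA network
#'
#' Edges run circRNA -> miRNA (the circRNA is upregulated DE and carries
#' at least one site for a selected miRNA) and miRNA -> mRNA (the gene is
#' in the affected set and a predicted target of the miRNA). Node size is
#' the log2 of the node's interaction count.
#'
#' @param de_circ_up_by_tissue Named list: tissue -> upregulated DE
#'   circRNA IDs.
#' @param selected Selected miRNAs (tibble or ID vector).
#' @param sites Site-count tibble (`circ_id`, `mirna_id`, `n_sites`).
#' @param affected Affected gene tibble from [integrate_targets()].
#' @param targets Target table tibble.
#' @return A `sponge_network`: list with `nodes` (`id`, `class`,
#'   `tissue_of_origin`, `degree`, `log2_size`) and `edges`
#'   (`source_id`, `source_class`, `target_id`, `target_class`,
#'   `tissue_of_origin`, `mirna_color_key`). Only nodes with at least
#'   one edge are included.
#' @export
build_network <- function(de_circ_up_by_tissue, selected, sites, affected, targets) {
  mirna_ids <- if (is.data.frame(selected)) selected$mirna_id else selected
  circ_tissue <- purrr::imap_dfr(de_circ_up_by_tissue, function(ids, tis) {
    tibble::tibble(circ_id = ids, tissue = tis)
  }) |>
    dplyr::distinct(.data$circ_id, .keep_all = TRUE)
  e1 <- sites |>
    dplyr::filter(.data$mirna_id %in% mirna_ids,
                  .data$circ_id %in% circ_tissue$circ_id,
                  !is.na(.data$n_sites), .data$n_sites > 0) |>
    dplyr::left_join(circ_tissue, by = "circ_id") |>
    dplyr::transmute(
      source_id = .data$circ_id, source_class = "circRNA",
      target_id = .data$mirna_id, target_class = "miRNA",
      tissue_of_origin = .data$tissue, mirna_color_key = .data$mirna_id
    )
  e2 <- targets |>
    dplyr::filter(.data$mirna_id %in% mirna_ids,
                  .data$gene_id %in% affected$gene_id) |>
    dplyr::distinct(.data$mirna_id, .data$gene_id) |>
    dplyr::transmute(
      source_id = .data$mirna_id, source_class = "miRNA",
      target_id = .data$gene_id, target_class = "mRNA",
      tissue_of_origin = NA_character_, mirna_color_key = .data$mirna_id
    )
  edges <- dplyr::bind_rows(e1, e2)
  ends <- dplyr::bind_rows(
    dplyr::transmute(edges, id = .data$source_id, class = .data$source_class),
    dplyr::transmute(edges, id = .data$target_id, class = .data$target_class)
  )
  nodes <- ends |>
    dplyr::count(.data$id, .data$class, name = "degree") |>
    dplyr::left_join(circ_tissue, by = c(id = "circ_id")) |>
    dplyr::transmute(
      id = .data$id, class = .data$class,
      tissue_of_origin = dplyr::if_else(.data$class == "circRNA",
                                        .data$tissue, NA_character_),
      degree = as.integer(.data$degree),
      log2_size = log2(.data$degree)
    ) |>
    dplyr::arrange(factor(.data$class, levels = c("circRNA", "miRNA", "mRNA")),
                   .data$id)
  structure(list(nodes = nodes, edges = edges), class = "sponge_network")
}
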