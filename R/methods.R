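# broom-style tidiers, printers and ggplot2 autoplot methods.

#' @method tidy sponge_de
#' @export
tidy.sponge_de <- function(x, ...) {
  dplyr::arrange(tibble::as_tibble(x), .data$p)
}

#' @method glance sponge_de
#' @export
glance.sponge_de <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$adj_p < alpha),
    prior_df = attr(x, "prior_df"),
    prior_var = attr(x, "prior_var"),
    residual_df = attr(x, "residual_df")
  )
}

#' @method glance sponge_sites
#' @export
glance.sponge_sites <- function(x, ...) {
  tibble::tibble(
    n_circ = dplyr::n_distinct(x$circ_id),
    n_mirnas = dplyr::n_distinct(x$mirna_id),
    mean_sites_per_circ = attr(x, "mean_sites_per_circ")
  )
}

#' @method glance sponge_varpart
#' @export
glance.sponge_varpart <- function(x, ...) {
  terms <- c(attr(x, "covariate_terms"), "residual")
  tibble::as_tibble(lapply(
    stats::setNames(terms, paste0("median_", terms)),
    function(tm) stats::median(x[[tm]])
  ))
}

#' @method glance sponge_de_summary
#' @export
glance.sponge_de_summary <- function(x, ...) {
  tibble::tibble(
    n_nonredundant = attr(x, "n_nonredundant"),
    alpha = attr(x, "alpha")
  )
}

#' @method tidy sponge_network
#' @export
tidy.sponge_network <- function(x, ...) x$edges

#' @method glance sponge_network
#' @export
glance.sponge_network <- function(x, ...) {
  tibble::tibble(
    n_circ = sum(x$nodes$class == "circRNA"),
    n_mirna = sum(x$nodes$class == "miRNA"),
    n_mrna = sum(x$nodes$class == "mRNA"),
    n_edges = nrow(x$edges)
  )
}

#' @export
print.sponge_network <- function(x, ...) {
  g <- glance(x)
  cat("Tripartite sponge network: ", g$n_circ, " circRNAs -> ", g$n_mirna,
      " miRNAs -> ", g$n_mrna, " mRNAs (", g$n_edges, " edges)\n", sep = "")
  invisible(x)
}

#' @export
print.study_bundle <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic sponge-network study (seed ", cfg$seed, ")\n",
      "  tissues: ", paste(cfg$tissues, collapse = ", "), "\n",
      "  circRNAs per caller: ", cfg$n_circ,
      " (consensus ", length(x$truth$consensus_junctions), ")\n",
      "  genes: ", cfg$n_genes, "; miRNA panel: ", cfg$n_mirnas,
      " (", length(x$truth$sponge_mirnas), " planted sponges)\n", sep = "")
  invisible(x)
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `sponge_de` tibble.
#' @param alpha Significance cutoff for colouring (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sponge_de
#' @export
autoplot.sponge_de <- function(object, alpha = 0.05, ...) {
  d <- dplyr::mutate(
    tibble::as_tibble(object),
    status = dplyr::case_when(
      .data$adj_p < alpha & .data$log2fc > 0 ~ "up",
      .data$adj_p < alpha & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#D55E00", down = "#0072B2", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case vs control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tripartite layout plot of a sponge network
#'
#' circRNAs on the left, miRNAs in the middle, mRNAs on the right; node
#' size follows `log2_size` and edges are coloured by miRNA.
#'
#' @param object A `sponge_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sponge_network
#' @export
autoplot.sponge_network <- function(object, ...) {
  cls_x <- c(circRNA = 0, miRNA = 1, mRNA = 2)
  nodes <- object$nodes |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(y = seq(0, 1, length.out = max(dplyr::n(), 2))[seq_len(dplyr::n())]) |>
    dplyr::ungroup() |>
    dplyr::mutate(x = cls_x[.data$class])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", x0 = "x", y0 = "y"),
                     by = c(source_id = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", x1 = "x", y1 = "y"),
                     by = c(target_id = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   colour = .data$mirna_color_key),
      alpha = 0.5, linewidth = 0.3, show.legend = FALSE) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$log2_size, shape = .data$class)) +
    ggplot2::scale_x_continuous(breaks = cls_x, labels = names(cls_x),
                                limits = c(-0.2, 2.2)) +
    ggplot2::labs(x = NULL, y = NULL, size = "log2 interactions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Covariate variance-fraction plot
#'
#' @param object A `sponge_varpart` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sponge_varpart
#' @export
autoplot.sponge_varpart <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"feature_id",
    names_to = "covariate", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(.data$covariate, .data$fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "fraction of variance explained") +
    ggplot2::theme_minimal()
}

#' Bar plot of enrichment results
#'
#' @param enrichment Result tibble from [hypergeom_enrich()].
#' @param top_n Number of top terms shown (default 10).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 10) {
  d <- utils::head(enrichment, top_n)
  d$term <- factor(d$term_id, levels = rev(d$term_id))
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p), .data$term)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::labs(x = "-log10 p", y = NULL) +
    ggplot2::theme_minimal()
}
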