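# Tissue-level DE summaries and the end-to-end pipeline driver.

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarise differential expression across tissues
#'
#' Counts significant up/down features per tissue at `alpha`, the
#' nonredundant union of significant feature IDs across tissues (a
#' feature significant in two tissues counts once), and each tissue's
#' share of that union as a percentage (nearest integer, half away from
#' zero).
#'
#' @param de_tables Named list: tissue -> DE tibble (`feature_id`,
#'   `log2fc`, `adj_p`).
#' @param alpha Significance cutoff on `adj_p` (default 0.05).
#' @return A `sponge_de_summary` tibble with one row per tissue:
#'   `tissue`, `n_up`, `n_down`, `n_total`, `pct_of_union`; the union
#'   size is the attribute `n_nonredundant` (also via `glance()`).
#'   Features with `adj_p < alpha` but `log2fc` exactly 0 are counted as
#'   neither direction, with a warning.
#' @export
summarize_de <- function(de_tables, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, length(names(de_tables)) == length(de_tables))
  sig_ids <- character()
  rows <- purrr::imap_dfr(de_tables, function(d, tis) {
    sig <- dplyr::filter(d, .data$adj_p < alpha)
    n_zero <- sum(sig$log2fc == 0)
    if (n_zero > 0) {
      warn(paste0(n_zero, " significant feature(s) in ", tis,
                  " with log2fc exactly 0 counted as neither up nor down"))
    }
    sig_ids <<- union(sig_ids, sig$feature_id)
    tibble::tibble(
      tissue = tis,
      n_up = sum(sig$log2fc > 0),
      n_down = sum(sig$log2fc < 0),
      n_total = sum(sig$log2fc > 0) + sum(sig$log2fc < 0)
    )
  })
  n_union <- length(sig_ids)
  rows$pct_of_union <- if (n_union > 0) {
    as.integer(.round_half_away(100 * rows$n_total / n_union))
  } else {
    NA_integer_
  }
  structure(rows, n_nonredundant = n_union, alpha = alpha,
            class = c("sponge_de_summary", class(rows)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

.required_input_keys <- c("caller_table_a", "caller_table_b", "circ_fasta",
                          "mirna_fasta", "gene_counts", "metadata",
                          "target_table", "gmt")

#' Run the full sponge-network pipeline
#'
#' Executes consensus calling, per-tissue differential expression of
#' consensus circRNAs and genes, junction-aware seed-site scanning of DE
#' circRNA sequences, miRNA selection, target/DE-gene integration,
#' tripartite network construction, gene-set over-representation and the
#' tissue-level summaries, writing every result table under `outdir`.
#' With `inputs = NULL` a synthetic study is generated from `config`
#' first (deterministic given `config$seed`).
#'
#' @param config A [sim_config()]; used when `inputs` is `NULL`.
#' @param outdir Output directory.
#' @param inputs Optional named list of input paths; required keys:
#'   `caller_table_a`, `caller_table_b`, `circ_fasta`, `mirna_fasta`,
#'   `gene_counts`, `metadata`, `target_table`, `gmt`. A missing key is
#'   an error naming it.
#' @param alpha Significance cutoff (default 0.05).
#' @param min_reads Junction-read support filter on caller B (default 2).
#' @param min_cpm,min_samples Expression filter (defaults 10 CPM in 9
#'   samples).
#' @param min_circ,top_k miRNA selection parameters (defaults 10, 12).
#' @return A `sponge_run` list: `bundle` (when simulated), `consensus`
#'   (count tibble), `detection`, `de_circ`, `de_genes` (per-tissue
#'   lists), `sites`, `selected`, `affected`, `network`, `enrichment`,
#'   `circ_summary`, `gene_summary`, `paths`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("spongerun"),
                         inputs = NULL, alpha = 0.05, min_reads = 2,
                         min_cpm = 10, min_samples = 9,
                         min_circ = 10, top_k = 12) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- NULL
  if (is.null(inputs)) {
    bundle <- .stage("simulate", generate_study(config, file.path(outdir, "inputs")))
    inputs <- bundle[.required_input_keys]
  } else {
    missing_keys <- setdiff(.required_input_keys, names(inputs))
    if (length(missing_keys) > 0) {
      abort(paste0("inputs is missing required key(s): ",
                   paste(missing_keys, collapse = ", ")))
    }
  }

  meta <- .stage("read_inputs", read_metadata(inputs$metadata))
  rec_a <- .stage("read_inputs",
                  read_caller_table(inputs$caller_table_a, "ciri2_like", caller = "A"))
  rec_b <- .stage("read_inputs",
                  read_caller_table(inputs$caller_table_b, "circexplorer2_like", caller = "B"))
  circ_seqs <- .stage("read_inputs", read_fasta(inputs$circ_fasta))
  mirnas <- .stage("read_inputs", mirna_panel(read_fasta(inputs$mirna_fasta)))
  gene_counts <- .stage("read_inputs", read_counts(inputs$gene_counts))
  targets <- .stage("read_inputs", read_targets(inputs$target_table))
  gmt <- .stage("read_inputs", read_gmt(inputs$gmt))

  consensus <- .stage("consensus", {
    recs <- filter_bsj_support(dplyr::bind_rows(rec_a, rec_b),
                               min_reads = min_reads, caller = "B")
    junctions <- intersect_callers(recs[recs$caller == "A", ],
                                   recs[recs$caller == "B", ])
    list(
      junctions = junctions,
      counts = consensus_counts(
        records_to_counts(recs[recs$caller == "A", ], samples = meta$sample_id),
        records_to_counts(recs[recs$caller == "B", ], samples = meta$sample_id),
        junctions
      )
    )
  })

  tissues <- unique(meta$tissue)
  detection <- .stage("detection", purrr::map_dfr(tissues, function(tis) {
    cm <- .counts_matrix(consensus$counts)
    md <- meta[meta$tissue == tis, ]
    detected <- function(ids) rownames(cm)[rowSums(cm[, ids, drop = FALSE] > 0) > 0]
    detection_summary(
      list(case = detected(md$sample_id[md$condition != "control"]),
           control = detected(md$sample_id[md$condition == "control"])),
      tissue = tis, metadata = meta
    )
  }))

  de_one <- function(counts, tis) {
    md <- meta[meta$tissue == tis, ]
    sub <- counts[, c("feature_id", md$sample_id)]
    sub <- filter_by_expression(sub, min_cpm = min_cpm, min_samples = min_samples)
    if (nrow(sub) < 2) abort(paste0("too few features pass the expression filter in ", tis))
    nf <- tmm_factors(sub)
    lc <- log_cpm(sub, nf)
    moderated_de(lc, stats::setNames(md$condition, md$sample_id))
  }
  de_circ <- .stage("diffexp_circ",
                    stats::setNames(lapply(tissues, function(t) de_one(consensus$counts, t)), tissues))
  de_genes <- .stage("diffexp_genes",
                     stats::setNames(lapply(tissues, function(t) de_one(gene_counts, t)), tissues))

  sig <- function(d, dir) d$feature_id[d$adj_p < alpha & sign(d$log2fc) == dir]
  de_circ_up <- purrr::map(de_circ, sig, dir = 1)
  de_circ_all <- purrr::map(de_circ, ~ .x$feature_id[.x$adj_p < alpha & .x$log2fc != 0])
  circ_tissue <- unlist(unname(
    purrr::imap(de_circ_all, ~ stats::setNames(rep(.y, length(.x)), .x))))

  sponge <- .stage("sponge", {
    scan_ids <- unique(unlist(de_circ_all, use.names = FALSE))
    sites <- site_count_table(circ_seqs, mirnas, circ_ids = scan_ids)
    selected <- select_mirnas(sites, de_circ_up, min_circ = min_circ,
                              top_k = top_k, circ_tissue = circ_tissue)
    affected <- integrate_targets(selected, targets, de_genes, alpha = alpha)
    net <- build_network(de_circ_up, selected, sites, affected, targets)
    list(sites = sites, selected = selected, affected = affected, network = net)
  })

  enrichment <- .stage("enrichment", {
    universe <- unique(unlist(purrr::map(de_genes, "feature_id"), use.names = FALSE))
    hypergeom_enrich(sponge$affected$gene_id, gmt, universe)
  })

  circ_summary <- .stage("report", summarize_de(de_circ, alpha = alpha))
  gene_summary <- .stage("report", summarize_de(de_genes, alpha = alpha))

  paths <- .stage("write_outputs", {
    w <- function(x, name) {
      p <- file.path(outdir, name)
      readr::write_tsv(x, p, na = "", progress = FALSE)
      p
    }
    p <- list(
      consensus_counts = w(consensus$counts, "consensus_counts.tsv"),
      detection_summary = w(detection, "detection_summary.tsv"),
      site_counts = w(tibble::as_tibble(sponge$sites), "site_counts.tsv"),
      selected_mirnas = w(sponge$selected, "selected_mirnas.tsv"),
      affected_genes = w(sponge$affected, "affected_genes.tsv"),
      enrichment = w(enrichment, "enrichment.tsv"),
      circ_summary = w(tibble::as_tibble(circ_summary), "circ_de_summary.tsv"),
      gene_summary = w(tibble::as_tibble(gene_summary), "gene_de_summary.tsv"),
      network_edges = file.path(outdir, "network_edges.tsv"),
      network_graphml = file.path(outdir, "network.graphml")
    )
    for (tis in tissues) {
      p[[paste0("de_circ_", tis)]] <-
        w(tibble::as_tibble(de_circ[[tis]]), paste0("de_circ_", tis, ".tsv"))
      p[[paste0("de_genes_", tis)]] <-
        w(tibble::as_tibble(de_genes[[tis]]), paste0("de_genes_", tis, ".tsv"))
    }
    write_network(sponge$network, p$network_edges, "edge_list")
    write_network(sponge$network, p$network_graphml, "graphml_like_xml")
    log_lines <- c(
      paste0("circsponge version: ",
             as.character(utils::packageVersion("circsponge"))),
      paste0("R version: ", R.version$major, ".", R.version$minor),
      paste0("seed: ", config$seed),
      paste0("alpha: ", alpha), paste0("min_reads: ", min_reads),
      paste0("min_cpm: ", min_cpm), paste0("min_samples: ", min_samples),
      paste0("min_circ: ", min_circ), paste0("top_k: ", top_k)
    )
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
    p$run_log <- file.path(outdir, "run_log.txt")
    p
  })

  structure(
    list(bundle = bundle, consensus = consensus$counts,
         junctions = consensus$junctions, detection = detection,
         de_circ = de_circ, de_genes = de_genes,
         sites = sponge$sites, selected = sponge$selected,
         affected = sponge$affected, network = sponge$network,
         enrichment = enrichment, circ_summary = circ_summary,
         gene_summary = gene_summary, paths = paths, outdir = outdir),
    class = "sponge_run"
  )
}
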