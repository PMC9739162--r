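# Synthetic-study generator. Produces every input the pipeline consumes
# (two caller tables, circRNA and miRNA FASTA, circRNA/gene count
# matrices, sample metadata, miRNA->gene target table, GMT collection)
# plus a ground-truth manifest: planted DE features, planted seed sites,
# the planted sponge miRNAs/affected genes and the planted enriched term.
# Background circRNA sequences are made seed-free for the whole miRNA
# panel so that planted-site recovery is exact.

#' Configuration for a synthetic sponge-network study
#'
#' Defaults emulate a three-region spinal-cord case/control cohort
#' (cervical/thoracic/lumbar; roughly 2.6:1 case:control) at desk scale.
#'
#' @param tissues Tissue labels.
#' @param samples_per_group Named list: tissue -> c(case, control)
#'   sample numbers.
#' @param n_circ Number of circRNA junctions per caller.
#' @param n_genes Number of genes.
#' @param n_mirnas miRNA panel size.
#' @param n_sponge_mirnas Number of planted sponge miRNAs.
#' @param frac_de_circ,frac_de_genes Fractions of features planted DE.
#' @param lfc_magnitude Planted |log2 fold change|.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param mean_log_expression Mean of per-feature baseline log2 counts.
#' @param baseline_sd SD of per-feature baseline log2 counts.
#' @param caller_overlap Fraction of `n_circ` junctions reported by both
#'   callers (the consensus set has exactly
#'   `round(caller_overlap * n_circ)` junctions).
#' @param caller_jitter Half-width of the independent multiplicative
#'   jitter between the two callers' read counts for the same junction.
#' @param planted_sites_per_circ Seed sites planted in each DE circRNA.
#' @param circ_len circRNA sequence length (nt).
#' @param mirna_len miRNA length (nt).
#' @param covariate_effects Named fractions of log-expression variance
#'   contributed by RIN, PMI and sex.
#' @param n_affected Planted affected genes (targets of sponge miRNAs
#'   that are also upregulated DE; capped at the number available).
#' @param n_terms Gene sets in the GMT collection (one is the planted
#'   enriched term).
#' @param seed Integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(tissues = c("SCC", "SCT", "SCL"),
                       samples_per_group = list(SCC = c(case = 18, control = 7),
                                                SCT = c(case = 16, control = 6),
                                                SCL = c(case = 16, control = 6)),
                       n_circ = 300, n_genes = 1200,
                       n_mirnas = 40, n_sponge_mirnas = 12,
                       frac_de_circ = 0.15, frac_de_genes = 0.1,
                       lfc_magnitude = 2, nb_dispersion = 0.1,
                       mean_log_expression = 5, baseline_sd = 1.5,
                       caller_overlap = 0.8, caller_jitter = 0.2,
                       planted_sites_per_circ = 12,
                       circ_len = 400, mirna_len = 22,
                       covariate_effects = c(RIN = 0.02, PMI = 0.02, sex = 0.01),
                       n_affected = 37, n_terms = 20, seed = 1L) {
  cfg <- list(
    tissues = tissues, samples_per_group = samples_per_group,
    n_tissues = length(tissues),
    n_circ = n_circ, n_genes = n_genes, n_mirnas = n_mirnas,
    n_sponge_mirnas = n_sponge_mirnas,
    frac_de_circ = frac_de_circ, frac_de_genes = frac_de_genes,
    lfc_magnitude = lfc_magnitude, nb_dispersion = nb_dispersion,
    mean_log_expression = mean_log_expression, baseline_sd = baseline_sd,
    caller_overlap = caller_overlap, caller_jitter = caller_jitter,
    planted_sites_per_circ = planted_sites_per_circ,
    circ_len = circ_len, mirna_len = mirna_len,
    covariate_effects = covariate_effects,
    n_affected = n_affected, n_terms = n_terms, seed = as.integer(seed)
  )
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  frac_fields <- c("frac_de_circ", "frac_de_genes", "caller_overlap")
  for (f in frac_fields) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste0(f, " must lie in [0, 1]"))
  }
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  for (f in c("n_circ", "n_genes", "n_mirnas", "n_terms")) {
    chk(cfg[[f]] >= 1, paste0(f, " must be >= 1"))
  }
  chk(cfg$planted_sites_per_circ >= 0, "planted_sites_per_circ must be >= 0")
  chk(cfg$n_sponge_mirnas <= cfg$n_mirnas, "n_sponge_mirnas must be <= n_mirnas")
  chk(setequal(names(samples_per_group), tissues),
      "samples_per_group must name every tissue")
  chk(all(unlist(samples_per_group) >= 2),
      "every tissue needs >= 2 case and >= 2 control samples")
  chk(cfg$mirna_len >= 8, "mirna_len must be >= 8")
  chk(sum(covariate_effects) < 1, "covariate_effects must sum to < 1")
  n_shared <- round(cfg$caller_overlap * cfg$n_circ)
  chk(round(cfg$frac_de_circ * cfg$n_circ) <= n_shared,
      "planted DE circRNAs must fit inside the caller-shared junction set")
  if (cfg$planted_sites_per_circ > 0) {
    chk(cfg$circ_len >= 30 + 14 * cfg$planted_sites_per_circ,
        "circ_len too short for the requested planted sites (need >= 30 + 14 per site)")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid simulation config:\n- ", paste(problems, collapse = "\n- ")))
  }
  structure(cfg, class = "sim_config")
}

# ---- sequence machinery -----------------------------------------------------

.rand_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Positions (1-based, circular) covered by a planted site whose seed-match
# hexamer starts at `pos`: one flank nucleotide either side.
.site_span <- function(pos, L) {
  ((pos - 2):(pos + 5)) %% L + 1
}

.planted_motif <- function(mirna, site_type) {
  hex <- rna_revcomp(mirna$seed6)
  m8c <- if (is.na(mirna$nt8)) NA_character_ else unname(.rna_complement[mirna$nt8])
  left <- switch(site_type,
    "8mer" = , "7mer-m8" = m8c,
    # a flank that does not pair nt8: first RNA letter different from m8c
    setdiff(c("C", "A", "U"), m8c)[1]
  )
  right <- switch(site_type,
    "8mer" = , "7mer-A1" = "A",
    "C"
  )
  if (is.na(left)) abort("site_type requiring nt8 pairing but miRNA has no nucleotide 8")
  paste0(left, hex, right)
}

#' Plant miRNA seed sites into an RNA sequence
#'
#' Writes, at each requested position, the exact target motif for the
#' requested site type: the reverse complement of the miRNA seed
#' (nucleotides 2-7) with flanking nucleotides set so a scanner
#' classifies the site exactly as requested (position-8 complement
#' and/or 3' adenine present, or explicitly absent). Positions index the
#' start of the seed-match hexamer; circular indexing lets sites span
#' the back-spliced junction. Sequence length is unchanged.
#'
#' @param sequence RNA string.
#' @param mirna One row of [mirna_panel()].
#' @param positions Integer vector of hexamer start positions.
#' @param site_types Character vector (recycled) of site classes among
#'   `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @return The modified sequence. Overlapping planted sites are an
#'   error: they would make the planted truth ambiguous.
#' @export
plant_seed_sites <- function(sequence, mirna, positions,
                             site_types = "8mer") {
  L <- nchar(sequence)
  .check_rna(sequence, "sequence")
  stopifnot(all(site_types %in% c("6mer", "7mer-A1", "7mer-m8", "8mer")))
  if (length(positions) == 0) return(sequence)
  site_types <- rep_len(site_types, length(positions))
  if (any(positions < 1 | positions > L)) {
    abort("positions must lie in [1, sequence length] (wrap handled circularly)")
  }
  spans <- lapply(positions, .site_span, L = L)
  if (anyDuplicated(unlist(spans))) {
    abort("Planted sites overlap; the planted truth would be ambiguous")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_along(positions)) {
    motif <- strsplit(.planted_motif(mirna, site_types[i]), "", fixed = TRUE)[[1]]
    chars[spans[[i]]] <- motif
  }
  paste(chars, collapse = "")
}

# Remove every occurrence (junction-aware) of the panel's seed-match
# hexamers from a sequence, leaving planted spans untouched. Each
# offending window always contains at least one free position because
# planted spans are pairwise non-adjacent and panel seeds are chosen so
# no hexamer hides inside a planted motif.
.scrub_seeds <- function(seq, hexamers, keep = NULL, max_iter = 200) {
  L <- nchar(seq)
  protected <- logical(L)
  truth_hits <- list()
  if (!is.null(keep)) {
    for (i in seq_len(nrow(keep))) {
      protected[.site_span(keep$position[i], L)] <- TRUE
      truth_hits[[paste0(keep$hexamer[i], "@", keep$position[i])]] <- TRUE
    }
  }
  for (iter in seq_len(max_iter)) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    s2 <- paste0(seq, substr(seq, 1, 7))
    dirty <- FALSE
    for (hx in hexamers) {
      starts <- .find_fixed(s2, hx)
      starts <- starts[starts <= L]
      for (q in starts) {
        if (!is.null(truth_hits[[paste0(hx, "@", q)]])) next
        win <- (q - 1):(q + 4) %% L + 1
        free <- win[!protected[win]]
        if (length(free) == 0) next  # guarded against at panel construction
        pos <- free[sample.int(length(free), 1)]
        chars[pos] <- sample(setdiff(c("A", "C", "G", "U"), chars[pos]), 1)
        dirty <- TRUE
      }
      if (dirty) break  # re-scan after each edit round on one hexamer
    }
    if (!dirty) return(seq)
    seq <- paste(chars, collapse = "")
  }
  abort("Could not scrub accidental seed matches from a background sequence")
}

# Draw a miRNA panel whose seed hexamers are pairwise distinct and never
# hidden inside another miRNA's planted 8mer motif (so planted-site truth
# stays exact after planting).
.draw_mirna_panel <- function(n, len, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    seqs <- .rand_rna(n, len)
    panel <- mirna_panel(stats::setNames(seqs, paste0("mir-", sprintf("%03d", seq_len(n)))))
    if (anyDuplicated(panel$seed6)) next
    motifs <- vapply(seq_len(n), function(i) .planted_motif(panel[i, ], "8mer"),
                     character(1))
    # internal 6-windows of each motif other than the seed match itself
    shifted <- unlist(lapply(motifs, function(m) c(substr(m, 1, 6), substr(m, 3, 8))))
    hex <- rna_revcomp(panel$seed6)
    if (any(hex %in% shifted)) next
    return(panel)
  }
  abort("Could not draw a collision-free miRNA panel")
}

# ---- count model ------------------------------------------------------------

#' Simulate negative-binomial counts with planted effects
#'
#' Counts are drawn NB(mu, dispersion) with
#' `log2 mu = baseline + sum(beta_c z_c) + lfc * direction * I(case)`.
#' Covariate coefficients are calibrated so each covariate contributes
#' approximately its requested fraction of log-expression variance
#' relative to the NB noise floor.
#'
#' @param meta Sample metadata tibble (`sample_id`, `condition`, and any
#'   covariate columns named in `covariate_effects`).
#' @param features Character vector of feature IDs, or a named numeric
#'   vector of per-feature baseline log2 means.
#' @param de_up,de_down Feature IDs with planted up/down log2 fold
#'   change `lfc` in case samples.
#' @param lfc Planted |log2 fold change|.
#' @param dispersion NB dispersion (> 0); values below 1e-8 fall back to
#'   Poisson sampling.
#' @param mean_log_expression,baseline_sd Baseline log2-mean
#'   distribution (used when `features` carries no baselines).
#' @param covariate_effects Named variance fractions for metadata
#'   columns (numeric columns standardised; two-level character columns
#'   coded 0/1 then standardised).
#' @return Count tibble (`feature_id` + one column per sample). Uses the
#'   ambient RNG state; set a seed for reproducibility.
#' @export
simulate_counts <- function(meta, features, de_up = character(), de_down = character(),
                            lfc = 2, dispersion = 0.1,
                            mean_log_expression = 5, baseline_sd = 1.5,
                            covariate_effects = NULL) {
  if (dispersion <= 0) abort("dispersion must be > 0")
  cond <- as.character(meta$condition)
  is_case <- cond != "control"
  if (sum(is_case) == 0 || sum(!is_case) == 0) {
    abort("meta must contain both case and control samples")
  }
  if (is.null(names(features))) {
    base <- stats::setNames(
      stats::rnorm(length(features), mean_log_expression, baseline_sd), features)
  } else {
    base <- features
  }
  ids <- names(base)
  stray <- setdiff(c(de_up, de_down), ids)
  if (length(stray) > 0) abort("de_up/de_down reference unknown features")
  n_s <- nrow(meta)
  log2mu <- matrix(base, nrow = length(ids), ncol = n_s,
                   dimnames = list(ids, meta$sample_id))
  if (!is.null(covariate_effects) && length(covariate_effects) > 0) {
    v_res <- 1 - sum(covariate_effects)
    sigma2_nb <- (log2(exp(1)))^2 * (2^-mean_log_expression + dispersion)
    for (cv in names(covariate_effects)) {
      x <- meta[[cv]]
      if (is.null(x)) abort(paste0("metadata lacks covariate column ", cv))
      if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1
      if (stats::var(x) == 0) next
      z <- as.numeric(scale(x))
      beta <- sqrt(covariate_effects[[cv]] * sigma2_nb / v_res)
      # random per-feature sign: covariates push individual features either
      # way, so the effect survives library-size (CPM) normalization
      sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
      log2mu <- log2mu + outer(sgn * beta, z)
    }
  }
  dir <- stats::setNames(rep(0, length(ids)), ids)
  dir[de_up] <- 1; dir[de_down] <- -1
  log2mu <- log2mu + outer(dir * lfc, as.numeric(is_case))
  mu <- 2^log2mu
  counts <- if (dispersion < 1e-8) {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  }
  .counts_tibble(counts)
}

# ---- study assembly ---------------------------------------------------------

.split_blocks <- function(ids, tissues, frac_up = 0.7) {
  n <- length(ids)
  t_n <- length(tissues)
  sizes <- rep(n %/% t_n, t_n) + c(rep(1, n %% t_n), rep(0, t_n - n %% t_n))
  out_up <- out_down <- stats::setNames(vector("list", t_n), tissues)
  at <- 0
  for (i in seq_len(t_n)) {
    blk <- ids[seq_len(sizes[i]) + at]
    at <- at + sizes[i]
    n_up <- round(frac_up * length(blk))
    out_up[[tissues[i]]] <- blk[seq_len(n_up)]
    out_down[[tissues[i]]] <- setdiff(blk, out_up[[tissues[i]]])
  }
  list(up = out_up, down = out_down)
}

.sim_metadata <- function(cfg) {
  purrr::map_dfr(cfg$tissues, function(tis) {
    n <- cfg$samples_per_group[[tis]]
    tibble::tibble(
      sample_id = c(sprintf("%s_ALS_%02d", tis, seq_len(n[["case"]])),
                    sprintf("%s_CTL_%02d", tis, seq_len(n[["control"]]))),
      tissue = tis,
      condition = rep(c("ALS", "control"), n[c("case", "control")]),
      RIN = c(stats::runif(n[["case"]], 7, 9.5),
              stats::runif(n[["control"]], 3.5, 7.3)),
      PMI = c(stats::runif(n[["case"]], 4, 15),
              stats::runif(n[["control"]], 4, 25)),
      sex = sample(c("M", "F"), sum(n), replace = TRUE)
    )
  })
}

.plant_positions <- function(L, n_sites) {
  if (n_sites == 0) return(integer())
  if (n_sites == 1) return(L - 2L)  # single site wraps the junction
  gap <- (L - 30) %/% (n_sites - 1)
  c(7L + (seq_len(n_sites - 1) - 1L) * gap, L - 2L)
}

#' Generate a complete synthetic sponge-network study
#'
#' Writes every pipeline input to `dir` and returns a bundle of paths
#' plus the ground-truth manifest. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A `study_bundle`: list with elements `caller_table_a`,
#'   `caller_table_b`, `circ_fasta`, `mirna_fasta`, `circ_counts`,
#'   `gene_counts`, `metadata`, `target_table`, `gmt`, `truth_json`
#'   (paths), `truth` (the manifest) and `config`.
#' @export
generate_study <- function(config = sim_config(), dir = tempfile("synthstudy")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  meta <- .sim_metadata(cfg)

  # -- junction universe: shared block first, then caller-specific extras
  n_shared <- round(cfg$caller_overlap * cfg$n_circ)
  n_total_j <- 2 * cfg$n_circ - n_shared
  chrom <- sample(paste0("chr", 1:22), n_total_j, replace = TRUE)
  start <- sample.int(2e8, n_total_j)
  len <- sample.int(5e4, n_total_j) + 200
  strand <- sample(c("+", "-"), n_total_j, replace = TRUE)
  jid <- bsj_id(chrom, start, start + len)
  shared <- jid[seq_len(n_shared)]
  a_only <- jid[n_shared + seq_len(cfg$n_circ - n_shared)]
  b_only <- jid[cfg$n_circ + seq_len(cfg$n_circ - n_shared)]

  # -- planted DE assignment (per tissue, disjoint, up-biased)
  n_de_circ <- round(cfg$frac_de_circ * cfg$n_circ)
  de_circ <- .split_blocks(shared[seq_len(n_de_circ)], cfg$tissues)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  n_de_gene <- round(cfg$frac_de_genes * cfg$n_genes)
  de_gene <- .split_blocks(gene_ids[seq_len(n_de_gene)], cfg$tissues)

  # -- miRNA panel and circRNA sequences
  panel <- .draw_mirna_panel(cfg$n_mirnas, cfg$mirna_len)
  sponge_ids <- panel$mirna_id[seq_len(cfg$n_sponge_mirnas)]
  hexamers <- rna_revcomp(panel$seed6)
  de_circ_all <- unlist(c(de_circ$up, de_circ$down), use.names = FALSE)
  circ_seqs <- stats::setNames(.rand_rna(n_shared, cfg$circ_len), shared)
  planted <- tibble::tibble(circ_id = character(), mirna_id = character(),
                            position = integer(), site_type = character(),
                            wraps_junction = logical())
  n_sp <- cfg$planted_sites_per_circ
  for (i in seq_along(shared)) {
    cid <- shared[i]
    is_de <- cid %in% de_circ_all
    if (is_de && n_sp > 0) {
      pos <- .plant_positions(cfg$circ_len, n_sp)
      mi <- sponge_ids[(i + seq_len(n_sp) - 2) %% length(sponge_ids) + 1]
      keep <- tibble::tibble(position = pos, hexamer = hexamers[match(mi, panel$mirna_id)])
      seq <- .scrub_seeds(circ_seqs[[cid]], hexamers)
      for (j in seq_len(n_sp)) {
        seq <- plant_seed_sites(seq, panel[panel$mirna_id == mi[j], ], pos[j], "8mer")
      }
      seq <- .scrub_seeds(seq, hexamers, keep = keep)
      circ_seqs[[cid]] <- seq
      planted <- dplyr::bind_rows(planted, tibble::tibble(
        circ_id = cid, mirna_id = mi, position = pos, site_type = "8mer",
        wraps_junction = pos + 6 > cfg$circ_len
      ))
    } else {
      circ_seqs[[cid]] <- .scrub_seeds(circ_seqs[[cid]], hexamers)
    }
  }

  # -- counts (per tissue so condition effects stay tissue-local)
  sim_tissue <- function(base, up, down) {
    purrr::map(cfg$tissues, function(tis) {
      simulate_counts(
        meta[meta$tissue == tis, ], base,
        de_up = up[[tis]], de_down = down[[tis]],
        lfc = cfg$lfc_magnitude, dispersion = cfg$nb_dispersion,
        covariate_effects = cfg$covariate_effects
      )
    }) |>
      purrr::reduce(\(x, y) dplyr::left_join(x, y, by = "feature_id"))
  }
  base_all_j <- stats::setNames(
    stats::rnorm(n_total_j, cfg$mean_log_expression, cfg$baseline_sd), jid)
  circ_true <- sim_tissue(base_all_j, de_circ$up, de_circ$down)
  base_gene <- stats::setNames(
    stats::rnorm(cfg$n_genes, cfg$mean_log_expression, cfg$baseline_sd), gene_ids)
  gene_counts <- sim_tissue(base_gene, de_gene$up, de_gene$down)

  # -- caller tables with independent multiplicative jitter
  true_m <- .counts_matrix(circ_true)
  jit <- function() matrix(
    stats::runif(length(true_m), 1 - cfg$caller_jitter, 1 + cfg$caller_jitter),
    nrow = nrow(true_m))
  a_m <- round(true_m * jit()); b_m <- round(true_m * jit())
  a_ids <- c(shared, a_only); b_ids <- c(shared, b_only)
  caller_long <- function(m, ids) {
    .counts_tibble(m[ids, , drop = FALSE]) |>
      tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                          values_to = "junction_reads") |>
      dplyr::filter(.data$junction_reads > 0) |>
      dplyr::left_join(
        tibble::tibble(feature_id = jid, chrom = chrom, start = start,
                       end = start + len, strand = strand),
        by = "feature_id")
  }
  a_tbl <- caller_long(a_m, a_ids) |>
    dplyr::transmute(circRNA_ID = .data$feature_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end,
                     junction_reads = .data$junction_reads, strand = .data$strand,
                     sample_id = .data$sample_id)
  b_tbl <- caller_long(b_m, b_ids) |>
    dplyr::transmute(chrom = .data$chrom, start = .data$start - 1L,
                     end = .data$end, name = paste0("circ_", .data$feature_id),
                     junction_reads = .data$junction_reads, strand = .data$strand,
                     sample_id = .data$sample_id)

  # -- targets: sponge miRNAs hit the planted affected genes; their other
  #    targets are planted downregulated genes, which can never be called
  #    significantly upregulated, so the affected-gene truth stays exact
  #    whatever false positives arise among null genes
  de_gene_up_all <- unlist(de_gene$up, use.names = FALSE)
  de_gene_down_all <- unlist(de_gene$down, use.names = FALSE)
  n_aff <- min(cfg$n_affected, length(de_gene_up_all))
  affected <- sort(sample(de_gene_up_all, n_aff))
  non_up <- setdiff(gene_ids, de_gene_up_all)
  target_rows <- list()
  for (i in seq_along(sponge_ids)) {
    mine <- affected[(seq_along(affected) - 1) %% length(sponge_ids) + 1 == i]
    bg <- sample(de_gene_down_all, min(20, length(de_gene_down_all)))
    target_rows[[i]] <- tibble::tibble(mirna_id = sponge_ids[i],
                                       gene_id = c(mine, bg))
  }
  for (m in setdiff(panel$mirna_id, sponge_ids)) {
    target_rows[[length(target_rows) + 1]] <-
      tibble::tibble(mirna_id = m, gene_id = sample(non_up, 10))
  }
  targets <- dplyr::bind_rows(target_rows)
  targets$context_score <- round(stats::runif(nrow(targets), -0.6, -0.05), 3)

  # -- GMT: one planted enriched term, background terms avoid affected genes
  planted_term_genes <- sort(sample(affected, min(20, length(affected))))
  gmt <- tibble::tibble(
    term_id = sprintf("TERM%04d", seq_len(cfg$n_terms)),
    name = c("planted affected-gene module",
             paste0("background set ", seq_len(cfg$n_terms - 1))),
    genes = c(list(planted_term_genes),
              purrr::map(seq_len(cfg$n_terms - 1), function(i) {
                sort(sample(setdiff(gene_ids, affected), sample(15:40, 1)))
              }))
  )

  truth <- list(
    consensus_junctions = shared, caller_a_only = a_only, caller_b_only = b_only,
    de_circ_up = de_circ$up, de_circ_down = de_circ$down,
    de_genes_up = de_gene$up, de_genes_down = de_gene$down,
    planted_sites = planted, sponge_mirnas = sponge_ids,
    affected_genes = affected, enriched_term = "TERM0001",
    covariate_effects = as.list(cfg$covariate_effects)
  )

  paths <- list(
    caller_table_a = file.path(dir, "caller_a.tsv"),
    caller_table_b = file.path(dir, "caller_b.tsv"),
    circ_fasta = file.path(dir, "circ_sequences.fa"),
    mirna_fasta = file.path(dir, "mirna_sequences.fa"),
    circ_counts = file.path(dir, "circ_counts.tsv"),
    gene_counts = file.path(dir, "gene_counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    target_table = file.path(dir, "targets.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth_json = file.path(dir, "truth.json")
  )
  readr::write_tsv(a_tbl, paths$caller_table_a, na = "", progress = FALSE)
  readr::write_tsv(b_tbl, paths$caller_table_b, na = "", progress = FALSE)
  write_fasta(circ_seqs, paths$circ_fasta)
  write_fasta(stats::setNames(panel$sequence, panel$mirna_id), paths$mirna_fasta)
  readr::write_tsv(circ_true[match(shared, circ_true$feature_id), ],
                   paths$circ_counts, progress = FALSE)
  readr::write_tsv(gene_counts, paths$gene_counts, na = "", progress = FALSE)
  readr::write_tsv(meta, paths$metadata, na = "", progress = FALSE)
  readr::write_tsv(targets, paths$target_table, na = "", progress = FALSE)
  write_gmt(gmt, paths$gmt)
  jsonlite::write_json(
    c(truth[setdiff(names(truth), "planted_sites")],
      list(planted_sites = truth$planted_sites)),
    paths$truth_json, auto_unbox = FALSE, digits = NA, pretty = TRUE)

  structure(c(paths, list(truth = truth, config = cfg)), class = "study_bundle")
}
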