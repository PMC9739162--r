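test_that("invalid configurations are rejected with offending fields listed", {
  err <- expect_error(sim_config(frac_de_circ = 1.5, nb_dispersion = -1),
                      "Invalid simulation config")
  expect_match(conditionMessage(err), "frac_de_circ")
  expect_match(conditionMessage(err), "nb_dispersion")
  expect_error(sim_config(n_sponge_mirnas = 50, n_mirnas = 10), "n_sponge")
})

test_that("the same seed yields byte-identical bundle files", {
  cfg <- small_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_study(cfg, d1)
  b2 <- generate_study(cfg, d2)
  for (key in c("caller_table_a", "caller_table_b", "circ_fasta", "mirna_fasta",
                "circ_counts", "gene_counts", "metadata", "target_table",
                "gmt", "truth_json")) {
    expect_identical(unname(tools::md5sum(b1[[key]])),
                     unname(tools::md5sum(b2[[key]])),
                     label = paste("md5 of", key))
  }
})

test_that("caller overlap is controlled exactly", {
  cfg <- small_config(seed = 6, caller_overlap = 1.0, n_circ = 50,
                      frac_de_circ = 0.3, planted_sites_per_circ = 3)
  b <- generate_study(cfg, withr::local_tempdir())
  a <- read_caller_table(b$caller_table_a, "ciri2_like")
  bb <- read_caller_table(b$caller_table_b, "circexplorer2_like")
  expect_length(intersect_callers(a, bb), 50)

  cfg2 <- small_config(seed = 6, caller_overlap = 0.8, n_circ = 60)
  b2 <- generate_study(cfg2, withr::local_tempdir())
  a2 <- read_caller_table(b2$caller_table_a, "ciri2_like")
  bb2 <- read_caller_table(b2$caller_table_b, "circexplorer2_like")
  expect_length(intersect_callers(a2, bb2), round(0.8 * 60))
  expect_setequal(intersect_callers(a2, bb2), b2$truth$consensus_junctions)
})

test_that("planted DE set sizes follow the configured fractions", {
  cfg <- sim_config(n_circ = 200, frac_de_circ = 0.1, n_genes = 300,
                    n_mirnas = 10, n_sponge_mirnas = 4,
                    planted_sites_per_circ = 4)
  b <- generate_study(cfg, withr::local_tempdir())
  tr <- b$truth
  de_all <- unique(unlist(c(tr$de_circ_up, tr$de_circ_down), use.names = FALSE))
  expect_length(de_all, 20)  # round(0.1 * 200)
  # every planted DE feature exists in the consensus count matrix
  counts <- read_counts(b$circ_counts)
  expect_true(all(de_all %in% counts$feature_id))
  de_genes <- unique(unlist(c(tr$de_genes_up, tr$de_genes_down), use.names = FALSE))
  expect_true(all(de_genes %in% read_counts(b$gene_counts)$feature_id))
})

test_that("every planted seed site is recovered, and only planted sites", {
  b <- generate_study(small_config(seed = 9), withr::local_tempdir())
  seqs <- read_fasta(b$circ_fasta)
  panel <- mirna_panel(read_fasta(b$mirna_fasta))
  truth <- b$truth$planted_sites
  de_circ <- unique(truth$circ_id)
  tbl <- site_count_table(seqs, panel, circ_ids = de_circ)
  found <- attr(tbl, "sites")
  # 100% recall and precision against the planted manifest
  expect_setequal(paste(found$circ_id, found$mirna_id, found$start),
                  paste(truth$circ_id, truth$mirna_id, truth$position))
  expect_equal(nrow(found), nrow(truth))
  expect_equal(sort(found$site_type), sort(truth$site_type))
  # wrap flags agree
  m <- match(paste(found$circ_id, found$mirna_id, found$start),
             paste(truth$circ_id, truth$mirna_id, truth$position))
  expect_equal(found$wraps_junction, truth$wraps_junction[m])
  # non-DE consensus circRNAs are seed-free
  bg <- setdiff(names(seqs), de_circ)
  bg_tbl <- site_count_table(seqs, panel, circ_ids = bg)
  expect_true(all(bg_tbl$n_sites == 0))
})

test_that("null counts give approximately uniform moderated-t p-values", {
  withr::local_seed(61)
  meta <- tibble::tibble(sample_id = paste0("s", 1:16),
                         condition = rep(c("case", "control"), each = 8))
  counts <- simulate_counts(meta, paste0("f", 1:2000), lfc = 0, dispersion = 0.1)
  de <- moderated_de(log_cpm(counts), stats::setNames(meta$condition, meta$sample_id))
  ks <- stats::ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  withr::local_seed(67)
  meta <- tibble::tibble(sample_id = paste0("s", 1:40),
                         condition = rep(c("case", "control"), each = 20))
  counts <- simulate_counts(meta, stats::setNames(rep(10, 200), paste0("f", 1:200)),
                            lfc = 0, dispersion = 1e-10)
  m <- as.matrix(counts[-1])
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("a planted twofold-per-unit lfc shows up in the CPM ratio", {
  withr::local_seed(71)
  meta <- tibble::tibble(sample_id = paste0("s", 1:20),
                         condition = rep(c("case", "control"), each = 10))
  up <- paste0("f", 1:30)
  counts <- simulate_counts(meta, paste0("f", 1:400), de_up = up,
                            lfc = 2, dispersion = 0.1)
  cc <- as.matrix(cpm(counts)[-1])[seq_along(up), , drop = FALSE]
  ratios <- rowMeans(cc[, meta$condition == "case"]) /
    rowMeans(cc[, meta$condition == "control"])
  expect_gte(mean(ratios), 2.5)
  expect_lte(mean(ratios), 6.5)
})

test_that("degenerate designs and parameters are rejected", {
  meta <- tibble::tibble(sample_id = "s1", condition = "case")
  expect_error(simulate_counts(meta, "f1"), "case and control")
  meta2 <- tibble::tibble(sample_id = c("s1", "s2"),
                          condition = c("case", "control"))
  expect_error(simulate_counts(meta2, "f1", dispersion = 0), "dispersion")
})
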