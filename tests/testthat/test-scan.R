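mk_mirna <- function(seq, id = "mir-x") mirna_panel(stats::setNames(seq, id))

test_that("a planted seed match is found and classified at the right start", {
  # seed6 = nucleotides 2-7 of the miRNA; target hexamer is its reverse
  # complement, here UAAGCU, present at position 4
  mir <- mk_mirna("CAGCUUAGGGGGGGGGGGGGGG")  # seed6 AGCUUA, nt8 G
  hits <- scan_sites("GGGUAAGCUGGG", mir[1, ])
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4L)
  expect_false(hits$wraps_junction)
  # no match for an absent seed
  none <- scan_sites("AAAAAAAAAAAA", mir[1, ])
  expect_equal(nrow(none), 0)
})

test_that("site classes follow the nt8/A1 flank rules", {
  mir <- mk_mirna("CAGCUUAG")           # seed6 AGCUUA -> hexamer UAAGCU; nt8 G -> pairs C
  expect_equal(scan_sites("GGCUAAGCUAGG", mir[1, ])$site_type, "8mer")
  expect_equal(scan_sites("GGCUAAGCUGGG", mir[1, ])$site_type, "7mer-m8")
  expect_equal(scan_sites("GGGUAAGCUAGG", mir[1, ])$site_type, "7mer-A1")
  expect_equal(scan_sites("GGGUAAGCUGGG", mir[1, ])$site_type, "6mer")
  # an 8mer start is reported once, not double-reported as 7mer/6mer
  hits <- scan_sites("GGCUAAGCUAGG", mir[1, ])
  expect_equal(nrow(hits), 1)
})

test_that("junction-spanning sites are found only in circular mode", {
  mir <- mk_mirna("CAGCUUAGGGGGGGGGGGGGGG")
  # hexamer UAAGCU split across the junction: suffix UA + prefix AGCU
  circ <- "AGCUGGGGGUA"
  circ_hits <- scan_sites(circ, mir[1, ], circular = TRUE)
  expect_equal(nrow(circ_hits), 1)
  expect_true(circ_hits$wraps_junction)
  expect_equal(circ_hits$start, 10L)
  lin_hits <- scan_sites(circ, mir[1, ], circular = FALSE)
  expect_equal(nrow(lin_hits), 0)
})

test_that("scanner agrees with the brute-force doubled-sequence oracle", {
  withr::local_seed(31)
  for (i in 1:300) {
    L <- sample(20:80, 1)
    seq <- random_rna(L)
    mir_seq <- random_rna(sample(7:22, 1))
    panel <- mk_mirna(mir_seq)
    for (circ_mode in c(TRUE, FALSE)) {
      got <- scan_sites(seq, panel[1, ], circular = circ_mode)
      want <- oracle_scan(seq, panel$seed6, panel$nt8, circular = circ_mode)
      expect_equal(got$start, want$start)
      expect_equal(got$site_type, want$site_type)
      expect_equal(got$wraps_junction, want$wraps_junction)
    }
  }
})

test_that("linear-mode sites are a subset of circular-mode sites", {
  withr::local_seed(37)
  for (i in 1:100) {
    seq <- random_rna(sample(15:60, 1))
    panel <- mk_mirna(random_rna(10))
    circ <- scan_sites(seq, panel[1, ], circular = TRUE)
    lin <- scan_sites(seq, panel[1, ], circular = FALSE)
    expect_true(all(lin$start %in% circ$start))
    extra <- circ[!circ$start %in% lin$start, ]
    expect_true(all(extra$wraps_junction))
    # non-wrapping circular sites match linear classification exactly
    shared <- circ[!circ$wraps_junction & circ$start %in% lin$start, ]
    expect_equal(shared$site_type,
                 lin$site_type[match(shared$start, lin$start)])
  }
})

test_that("invalid alphabets are rejected", {
  mir <- mk_mirna("CAGCUUAG")
  expect_error(scan_sites("ACGTNN", mir[1, ]), "RNA alphabet")
  expect_error(mirna_panel(c(m = "ACGTACGT")), "RNA alphabet")
  expect_error(mirna_panel(c(m = "ACGUA")), "at least 7")
})

test_that("planted sites are recovered exactly, including across the junction", {
  mir <- mk_mirna("CAGCUUAG")  # seed6 AGCUUA, nt8 G
  withr::local_seed(41)
  # seed-free background: the hexamer UAAGCU contains G, absent from A/C/U strings
  bg <- paste(sample(c("A", "C", "U"), 30, TRUE), collapse = "")
  planted <- plant_seed_sites(bg, mir[1, ], positions = 4, site_types = "8mer")
  expect_equal(nchar(planted), 30)
  hits <- scan_sites(planted, mir[1, ])
  expect_equal(hits$start, 4L)
  expect_equal(hits$site_type, "8mer")

  # wrap-around plant at position len - 3
  wrapped <- plant_seed_sites(bg, mir[1, ], positions = 27, site_types = "7mer-m8")
  wh <- scan_sites(wrapped, mir[1, ])
  expect_equal(wh$start, 27L)
  expect_equal(wh$site_type, "7mer-m8")
  expect_true(wh$wraps_junction)

  # plant nothing: a seed-free background yields zero sites
  expect_equal(nrow(scan_sites(bg, mir[1, ])), 0)

  # overlapping plants are ambiguous truth
  expect_error(plant_seed_sites(bg, mir[1, ], positions = c(4, 6)),
               "overlap")
})

test_that("site counting aggregates per pair and reports the per-circRNA mean", {
  mir <- mk_mirna("CAGCUUAG")
  withr::local_seed(43)
  bg <- paste(sample(c("A", "C", "U"), 60, TRUE), collapse = "")
  two <- plant_seed_sites(bg, mir[1, ], positions = c(5, 30), site_types = "8mer")
  tbl <- site_count_table(c(c1 = two), mir)
  expect_equal(tbl$n_sites, 2L)
  expect_equal(glance(tbl)$mean_sites_per_circ, 2)

  # empty miRNA panel gives an empty table
  empty <- site_count_table(c(c1 = two),
                            tibble::tibble(mirna_id = character(),
                                           sequence = character()))
  expect_equal(nrow(empty), 0)

  # a missing sequence becomes NA and is excluded from the mean, with warning
  expect_warning(
    tbl2 <- site_count_table(c(c1 = two), mir, circ_ids = c("c1", "ghost")),
    "No sequence")
  expect_true(is.na(tbl2$n_sites[tbl2$circ_id == "ghost"]))
  expect_equal(glance(tbl2)$mean_sites_per_circ, 2)
})
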