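# Circular-aware miRNA seed-site scanning. A site is an occurrence on the
# circRNA (scanned 5'->3') of the reverse complement of the miRNA seed
# (nucleotides 2-7), classified by two flanking features: pairing of
# miRNA nucleotide 8 immediately 5' of the seed match, and an adenine
# immediately 3' of it. Because a circRNA has no ends, the scan wraps
# across the back-spliced junction.

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA string
#'
#' @param x RNA string(s) over `A`, `C`, `G`, `U`.
#' @return Reverse complement string(s).
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.check_rna <- function(s, what) {
  if (grepl("[^ACGU]", s)) {
    abort(paste0(what, " contains characters outside the RNA alphabet A/C/G/U"))
  }
}

#' Build a miRNA panel with seed annotations
#'
#' @param mirnas Named character vector of miRNA sequences (5'->3', RNA
#'   alphabet), or a tibble with `mirna_id` and `sequence`.
#' @return Tibble: `mirna_id`, `sequence`, `seed6` (nucleotides 2-7),
#'   `nt8` (position 8, `NA` when the miRNA is shorter than 8 nt).
#' @export
mirna_panel <- function(mirnas) {
  if (is.character(mirnas)) {
    stopifnot(!is.null(names(mirnas)))
    mirnas <- tibble::tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  stopifnot(all(c("mirna_id", "sequence") %in% names(mirnas)))
  if (any(nchar(mirnas$sequence) < 7)) {
    abort("miRNA sequences must be at least 7 nt (seed requires nucleotides 2-7)")
  }
  purrr::walk2(mirnas$sequence, mirnas$mirna_id, ~ .check_rna(.x, paste0("miRNA ", .y)))
  dplyr::mutate(
    mirnas,
    seed6 = substr(.data$sequence, 2, 7),
    nt8 = ifelse(nchar(.data$sequence) >= 8, substr(.data$sequence, 8, 8), NA_character_)
  )
}

#' Scan a circRNA sequence for seed sites of one miRNA
#'
#' Finds every occurrence of the reverse complement of the miRNA seed
#' (nucleotides 2-7) and classifies it: `8mer` when the target also pairs
#' miRNA nucleotide 8 immediately 5' of the seed match and carries an `A`
#' immediately 3' of it, `7mer-m8` with only the position-8 pairing,
#' `7mer-A1` with only the adenine, else `6mer`. Each start position is
#' reported once with its best class. In circular mode the sequence is
#' treated as closed: matches may span the back-spliced junction and are
#' flagged `wraps_junction`.
#'
#' @param circ_seq circRNA sequence (RNA alphabet).
#' @param mirna One row of [mirna_panel()] (or a list with `mirna_id`,
#'   `seed6`, `nt8`).
#' @param circular Scan across the back-spliced junction (default TRUE).
#' @param circ_id Label attached to the output.
#' @return Tibble of sites: `circ_id`, `mirna_id`, `start` (1-based on
#'   the circular sequence), `site_type`, `wraps_junction`.
#' @export
scan_sites <- function(circ_seq, mirna, circular = TRUE, circ_id = NA_character_) {
  L <- nchar(circ_seq)
  if (L < 6) abort("circRNA sequence must be at least 6 nt")
  .check_rna(circ_seq, "circRNA sequence")
  hex <- rna_revcomp(mirna$seed6)
  nt8 <- mirna$nt8
  m8_target <- if (is.na(nt8)) NA_character_ else unname(.rna_complement[nt8])
  empty <- tibble::tibble(
    circ_id = character(), mirna_id = character(), start = integer(),
    site_type = character(), wraps_junction = logical()
  )
  if (circular) {
    s2 <- paste0(circ_seq, substr(circ_seq, 1, 7))
    starts <- .find_fixed(s2, hex)
    starts <- starts[starts <= L]
  } else {
    starts <- .find_fixed(circ_seq, hex)
  }
  if (length(starts) == 0) return(empty)
  site <- purrr::map(starts, function(q) {
    if (circular) {
      left <- if (q >= 2) substr(circ_seq, q - 1, q - 1) else substr(circ_seq, L, L)
      right <- substr(s2, q + 6, q + 6)
    } else {
      left <- if (q >= 2) substr(circ_seq, q - 1, q - 1) else NA_character_
      right <- if (q + 6 <= L) substr(circ_seq, q + 6, q + 6) else NA_character_
    }
    m8 <- !is.na(m8_target) && !is.na(left) && left == m8_target
    a1 <- !is.na(right) && right == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
    wraps <- circular && ((q + (6 + a1) - 1 > L) || (m8 && q == 1))
    list(type = type, wraps = wraps)
  })
  tibble::tibble(
    circ_id = circ_id,
    mirna_id = mirna$mirna_id,
    start = as.integer(starts),
    site_type = purrr::map_chr(site, "type"),
    wraps_junction = purrr::map_lgl(site, "wraps")
  )
}

.find_fixed <- function(s, pattern) {
  hits <- stringr::str_locate_all(s, .overlapping_regex(pattern))[[1]]
  as.integer(hits[, 1])
}

# lookahead so overlapping occurrences are all reported
.overlapping_regex <- function(pattern) {
  paste0("(?=", stringr::str_escape(pattern), ")")
}

#' Count seed sites for every circRNA-miRNA pair
#'
#' @param circ_seqs Named character vector of circRNA sequences.
#' @param mirnas miRNA panel ([mirna_panel()] input forms accepted).
#' @param circ_ids circRNAs to scan (default: all of `circ_seqs`).
#'   Requested IDs with no sequence get `NA` counts, are excluded from
#'   the per-circRNA average, and trigger a warning.
#' @param circular Junction-aware scanning (default TRUE).
#' @param site_classes Site classes counted (default all four).
#' @return A `sponge_sites` tibble with one row per (circRNA, miRNA)
#'   pair: `circ_id`, `mirna_id`, `n_sites`. The full site list and the
#'   mean total site count per circRNA are attached as attributes
#'   `sites` and `mean_sites_per_circ` (also via `glance()`).
#' @export
site_count_table <- function(circ_seqs, mirnas, circ_ids = names(circ_seqs),
                             circular = TRUE,
                             site_classes = c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
  panel <- mirna_panel(mirnas)
  missing_ids <- setdiff(circ_ids, names(circ_seqs))
  if (length(missing_ids) > 0) {
    warn(paste0("No sequence for circRNA(s): ",
                paste(utils::head(missing_ids, 5), collapse = ", "),
                "; their counts are reported as NA"))
  }
  have <- intersect(circ_ids, names(circ_seqs))
  empty_sites <- tibble::tibble(
    circ_id = character(), mirna_id = character(), start = integer(),
    site_type = character(), wraps_junction = logical()
  )
  sites <- dplyr::bind_rows(empty_sites, purrr::map_dfr(have, function(cid) {
    purrr::map_dfr(seq_len(nrow(panel)), function(i) {
      scan_sites(circ_seqs[[cid]], panel[i, ], circular = circular, circ_id = cid)
    })
  }))
  sites <- dplyr::filter(sites, .data$site_type %in% site_classes)
  grid <- tidyr::expand_grid(circ_id = circ_ids, mirna_id = panel$mirna_id)
  counts <- sites |>
    dplyr::count(.data$circ_id, .data$mirna_id, name = "n_sites") |>
    dplyr::right_join(grid, by = c("circ_id", "mirna_id")) |>
    dplyr::mutate(n_sites = dplyr::if_else(
      .data$circ_id %in% have, dplyr::coalesce(.data$n_sites, 0L), NA_integer_
    )) |>
    dplyr::arrange(match(.data$circ_id, circ_ids), match(.data$mirna_id, panel$mirna_id))
  per_circ_total <- counts |>
    dplyr::filter(.data$circ_id %in% have) |>
    dplyr::group_by(.data$circ_id) |>
    dplyr::summarise(total = sum(.data$n_sites), .groups = "drop")
  mean_sites <- if (nrow(per_circ_total) > 0) mean(per_circ_total$total) else NA_real_
  structure(counts, sites = sites, mean_sites_per_circ = mean_sites,
            class = c("sponge_sites", class(counts)))
}
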