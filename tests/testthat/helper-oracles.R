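# Independent oracles used across the suite. These deliberately avoid the
# package's scanning/statistics code paths: plain loops and substring
# comparisons only.

comp1 <- c(A = "U", C = "G", G = "C", U = "A")

oracle_revcomp <- function(s) {
  paste(rev(comp1[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force seed-site scan: test every start position of the doubled
# sequence, classify from the literal neighbours.
oracle_scan <- function(seq, seed6, nt8 = NA_character_, circular = TRUE) {
  L <- nchar(seq)
  hex <- oracle_revcomp(seed6)
  s2 <- paste0(seq, seq)
  m8c <- if (is.na(nt8)) NA_character_ else unname(comp1[nt8])
  out <- data.frame(start = integer(), site_type = character(),
                    wraps_junction = logical())
  max_start <- if (circular) L else L - 5
  for (p in seq_len(max(max_start, 0))) {
    if (substr(s2, p, p + 5) != hex) next
    if (circular) {
      left <- substr(s2, if (p > 1) p - 1 else 2 * L, if (p > 1) p - 1 else 2 * L)
      right <- substr(s2, p + 6, p + 6)
    } else {
      left <- if (p > 1) substr(seq, p - 1, p - 1) else NA
      right <- if (p + 6 <= L) substr(seq, p + 6, p + 6) else NA
    }
    m8 <- !is.na(m8c) && !is.na(left) && left == m8c
    a1 <- !is.na(right) && right == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-A1" else "6mer"
    wraps <- circular && ((p + 5 + a1 > L) || (m8 && p == 1))
    out <- rbind(out, data.frame(start = p, site_type = type,
                                 wraps_junction = wraps))
  }
  out
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# small default-shaped config for fast end-to-end tests
small_config <- function(...) {
  defaults <- list(
    n_circ = 60, n_genes = 240, n_mirnas = 12, n_sponge_mirnas = 5,
    planted_sites_per_circ = 5, n_affected = 12, n_terms = 8,
    samples_per_group = list(SCC = c(case = 6, control = 4),
                             SCT = c(case = 6, control = 4),
                             SCL = c(case = 6, control = 4))
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# tissue-labelled DE tibble with the requested numbers of significant
# up/down features, IDs drawn from a given pool
made_de_table <- function(ids_up, ids_down, n_null = 0) {
  tibble::tibble(
    feature_id = c(ids_up, ids_down, sprintf("null%06d", seq_len(n_null))),
    log2fc = c(rep(1, length(ids_up)), rep(-1, length(ids_down)), rep(0.1, n_null)),
    adj_p = c(rep(0.01, length(ids_up) + length(ids_down)), rep(0.9, n_null))
  )
}
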