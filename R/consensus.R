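# Consensus circRNA calling: a junction is bona fide when both callers
# report it. Caller A is the CIRI2-style workflow, caller B the
# CIRCexplorer2-style one; only B's candidates are subject to the
# >= 2 junction-read support filter before intersection.

#' Filter caller records on back-spliced-junction read support
#'
#' Only records from the named caller are filtered; the other caller's
#' records pass through unchanged. The default reflects the usual practice
#' of requiring two or more junction-spanning reads from the
#' CIRCexplorer2-style caller (caller `"B"`) while taking the other
#' caller's candidate list as-is.
#'
#' @param records Caller record tibble from [read_caller_table()].
#' @param min_reads Minimum junction reads to retain a record (default 2).
#' @param caller Which caller the filter applies to (default `"B"`).
#' @return The filtered record tibble.
#' @export
filter_bsj_support <- function(records, min_reads = 2, caller = "B") {
  stopifnot(min_reads >= 0)
  dplyr::filter(records, .data$caller != !!caller | .data$junction_reads >= min_reads)
}

.junction_ids <- function(x) {
  if (is.character(x)) unique(x)
  else if (is.data.frame(x) && "circ_id" %in% names(x)) unique(x$circ_id)
  else abort("Expected a character vector of junction IDs or a tibble with circ_id")
}

#' Intersect the candidate junction sets of two callers
#'
#' Identity is the canonical `(chrom, start, end)` key; strand is ignored
#' (see [bsj_id()]). Accepts caller record tibbles or plain ID vectors.
#'
#' @param a,b Junction sets: character vectors of canonical IDs, or
#'   tibbles with a `circ_id` column.
#' @return Character vector of junction IDs present in both, in the order
#'   they appear in `a`.
#' @export
intersect_callers <- function(a, b) {
  intersect(.junction_ids(a), .junction_ids(b))
}

.counts_matrix <- function(tbl) {
  m <- as.matrix(tbl[, setdiff(names(tbl), "feature_id"), drop = FALSE])
  rownames(m) <- tbl$feature_id
  storage.mode(m) <- "double"
  m
}

.counts_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

#' Pivot caller records to a junction-by-sample count tibble
#'
#' @param records Caller record tibble (one caller).
#' @param samples Optional sample IDs fixing the column set/order; samples
#'   with no records get all-zero columns.
#' @return Count tibble: `feature_id` (junction ID) plus one column per
#'   sample holding junction read counts (0 where the junction was not
#'   reported for that sample).
#' @export
records_to_counts <- function(records, samples = NULL) {
  wide <- records |>
    dplyr::group_by(.data$circ_id, .data$sample_id) |>
    dplyr::summarise(junction_reads = sum(.data$junction_reads), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "junction_reads", values_fill = 0
    ) |>
    dplyr::rename(feature_id = "circ_id")
  if (!is.null(samples)) {
    for (s in setdiff(samples, names(wide))) wide[[s]] <- 0
    wide <- wide[, c("feature_id", samples)]
  }
  wide
}

#' Average the two callers' counts over consensus junctions
#'
#' For each consensus junction and sample the consensus count is the
#' arithmetic mean of the two callers' junction read counts, kept
#' fractional. A junction absent from one caller in a given sample
#' contributes 0 for that caller: consensus membership is decided at the
#' junction level, not per sample.
#'
#' @param a,b Count tibbles (one per caller) over the same samples.
#' @param junctions Character vector of consensus junction IDs.
#' @return Count tibble restricted to `junctions` (in the given order).
#' @export
consensus_counts <- function(a, b, junctions) {
  sa <- setdiff(names(a), "feature_id")
  sb <- setdiff(names(b), "feature_id")
  if (!setequal(sa, sb)) {
    abort(paste0(
      "Caller count tables cover different samples: only in A: ",
      paste(setdiff(sa, sb), collapse = ", "), "; only in B: ",
      paste(setdiff(sb, sa), collapse = ", ")
    ))
  }
  ma <- .counts_matrix(a)[, sa, drop = FALSE]
  mb <- .counts_matrix(b)[, sa, drop = FALSE]
  pick <- function(m, ids) {
    out <- matrix(0, nrow = length(ids), ncol = ncol(m),
                  dimnames = list(ids, colnames(m)))
    hit <- intersect(ids, rownames(m))
    out[hit, ] <- m[hit, , drop = FALSE]
    out
  }
  .counts_tibble((pick(ma, junctions) + pick(mb, junctions)) / 2)
}

#' Tissue-level detection summary (case vs control)
#'
#' Counts junctions detected in each condition, the common set, and the
#' condition-unique sets, mirroring the usual detection table for a
#' case/control cohort. "Detected in a condition" means present (after
#' all filters) in at least one sample of that condition.
#'
#' @param detected Named list with exactly the elements `case` and
#'   `control`, each a junction ID set (character vector or tibble with
#'   `circ_id`).
#' @param tissue Tissue label for the output row.
#' @param metadata Optional sample metadata tibble; when supplied, the
#'   numbers of case/control samples for `tissue` are reported.
#' @return One-row tibble: `tissue`, `n_case`, `n_control`,
#'   `detected_case`, `detected_control`, `common`, `unique_case`,
#'   `unique_control`.
#' @export
detection_summary <- function(detected, tissue = NA_character_, metadata = NULL) {
  if (!setequal(names(detected), c("case", "control"))) {
    abort(paste0(
      "`detected` must have exactly the conditions 'case' and 'control', got: ",
      paste(names(detected), collapse = ", ")
    ))
  }
  case <- .junction_ids(detected$case)
  control <- .junction_ids(detected$control)
  common <- length(intersect(case, control))
  n_case <- n_control <- NA_integer_
  if (!is.null(metadata)) {
    md <- dplyr::filter(metadata, .data$tissue == !!tissue)
    n_case <- sum(md$condition != "control")
    n_control <- sum(md$condition == "control")
  }
  tibble::tibble(
    tissue = tissue,
    n_case = n_case,
    n_control = n_control,
    detected_case = length(case),
    detected_control = length(control),
    common = common,
    unique_case = length(case) - common,
    unique_control = length(control) - common
  )
}
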