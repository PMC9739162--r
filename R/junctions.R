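#' Canonical back-spliced junction identifiers
#'
#' A circRNA is identified throughout the package by its back-spliced
#' junction (BSJ): chromosome plus 1-based, inclusive start and end of the
#' back-spliced span, formatted `"chrom:start|end"`. Strand is carried along
#' in records but deliberately excluded from the identity: the two supported
#' caller dialects disagree on strand for a fraction of events, and the
#' `chr:start|end` key maximises agreement between them.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 1-based inclusive junction coordinates.
#' @return A character vector of canonical junction IDs.
#' @examples
#' bsj_id("chr1", 100, 200)
#' @export
bsj_id <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  paste0(chrom, ":", start, "|", end)
}

#' Parse canonical junction IDs back into coordinates
#'
#' @param id Character vector of `"chrom:start|end"` IDs.
#' @return A tibble with columns `circ_id`, `chrom`, `start`, `end`.
#' @export
parse_bsj_id <- function(id) {
  m <- stringr::str_match(id, "^(.+):(\\d+)\\|(\\d+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed junction ID(s): ",
      paste(utils::head(id[bad], 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    circ_id = id,
    chrom = m[, 2],
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4])
  )
}
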