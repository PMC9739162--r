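# Readers/writers for the external formats the pipeline touches. TSVs are
# tab-delimited with a header row; empty string is NA and '.' is forbidden
# as an NA marker.

caller_dialects <- c("ciri2_like", "circexplorer2_like")

.read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path, col_types = col_types, na = "", progress = FALSE)
}

#' Read a circRNA caller output table
#'
#' Supports two dialects. `ciri2_like` tables carry a ready-made
#' `chr:start|end` ID with 1-based inclusive coordinates;
#' `circexplorer2_like` tables are BED-derived, with 0-based half-open
#' coordinates that are converted to the canonical 1-based inclusive
#' convention on read. An optional `sample_id` column attributes rows to
#' samples; when absent, all rows are assigned to `sample_id`.
#'
#' @param path Path to a tab-separated caller table with a header row.
#'   `ciri2_like` columns: `circRNA_ID`, `chrom`, `start`, `end`,
#'   `junction_reads`, `strand`; `circexplorer2_like` columns: `chrom`,
#'   `start`, `end`, `name`, `junction_reads`, `strand`.
#' @param dialect One of `"ciri2_like"`, `"circexplorer2_like"`.
#' @param caller Caller label attached to each record (`"A"` or `"B"`).
#' @param sample_id Fallback sample label when the table has no
#'   `sample_id` column.
#' @return A tibble of circRNA records: `circ_id` (canonical
#'   `chrom:start|end`), `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `sample_id`, `junction_reads`, `caller`. Malformed rows
#'   raise an error naming the offending line.
#' @export
read_caller_table <- function(path, dialect = c("ciri2_like", "circexplorer2_like"),
                              caller = if (dialect == "ciri2_like") "A" else "B",
                              sample_id = "sample1") {
  dialect <- match.arg(dialect)
  tbl <- .read_tsv_strict(path, col_types = readr::cols(.default = readr::col_character()))
  need <- if (dialect == "ciri2_like") {
    c("circRNA_ID", "chrom", "start", "end", "junction_reads", "strand")
  } else {
    c("chrom", "start", "end", "name", "junction_reads", "strand")
  }
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Caller table ", path, " (", dialect, ") is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  n <- nrow(tbl)
  start <- suppressWarnings(as.numeric(tbl$start))
  end <- suppressWarnings(as.numeric(tbl$end))
  reads <- suppressWarnings(as.numeric(tbl$junction_reads))
  bad <- which(is.na(start) | is.na(end) | is.na(reads))
  if (length(bad) > 0) {
    abort(paste0(
      "Non-numeric coordinates or read counts in ", path,
      " at data row(s): ", paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (dialect == "circexplorer2_like") {
    # BED convention: 0-based half-open [start, end) -> 1-based inclusive
    start <- start + 1
  }
  bad <- which(start > end)
  if (length(bad) > 0) {
    abort(paste0(
      "start > end after coordinate conversion in ", path,
      " at data row(s): ", paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (any(reads < 0)) abort(paste0("Negative junction_reads in ", path))
  sid <- if ("sample_id" %in% names(tbl)) tbl$sample_id else rep(sample_id, n)
  out <- tibble::tibble(
    circ_id = bsj_id(tbl$chrom, as.integer(start), as.integer(end)),
    chrom = tbl$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = tbl$strand,
    sample_id = sid,
    junction_reads = reads,
    caller = caller
  )
  if (dialect == "ciri2_like") {
    stated <- tbl$circRNA_ID
    mism <- which(stated != out$circ_id)
    if (length(mism) > 0) {
      abort(paste0(
        "circRNA_ID does not match chrom:start|end in ", path,
        " at data row(s): ", paste(utils::head(mism, 5), collapse = ", ")
      ))
    }
  }
  out
}

#' Read a FASTA file as a named RNA sequence vector
#'
#' Sequences are upper-cased and DNA `T` is converted to RNA `U`: seed
#' matching downstream is defined on the RNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one RNA sequence per record, in file
#'   order. Duplicate IDs or empty sequences raise an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)  # keep the ID token only
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate FASTA ID(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(paste0(
      "Empty sequence(s) in ", path, ": ",
      paste(ids[nchar(seqs) == 0], collapse = ", ")
    ))
  }
  seqs <- chartr("T", "U", seqs)
  stats::setNames(seqs, ids)
}

#' Write a named sequence vector to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file: one gene set per line, tab-separated
#'   `term_id`, `name`, then member gene IDs.
#' @return A tibble with columns `term_id`, `name` and a list-column
#'   `genes` (duplicates within a line stored once). Lines with fewer than
#'   three fields raise an error naming the line.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(term_id = character(), name = character(), genes = list()))
  }
  fields <- stringr::str_split(lines, "\t")
  short <- which(purrr::map_int(fields, length) < 3)
  if (length(short) > 0) {
    abort(paste0(
      "GMT line(s) with fewer than 3 tab-separated fields in ", path, ": line ",
      paste(utils::head(short, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    term_id = purrr::map_chr(fields, 1),
    name = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, ~ unique(.x[-(1:2)]))
  )
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets Tibble with `term_id`, `name`, list-column `genes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- purrr::pmap_chr(gene_sets, function(term_id, name, genes, ...) {
    paste(c(term_id, name, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-by-sample count matrix TSV
#'
#' @param path TSV with a `feature_id` column followed by one numeric
#'   column per sample.
#' @return A tibble, `feature_id` first.
#' @export
read_counts <- function(path) {
  tbl <- .read_tsv_strict(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!"feature_id" %in% names(tbl)) {
    abort(paste0("Count table ", path, " has no feature_id column"))
  }
  tbl
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `tissue`, `condition`,
#'   `RIN`, `PMI`, `sex`.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  tbl <- .read_tsv_strict(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    tissue = readr::col_character(),
    condition = readr::col_character(),
    RIN = readr::col_double(),
    PMI = readr::col_double(),
    sex = readr::col_character()
  ))
  need <- c("sample_id", "tissue", "condition", "RIN", "PMI", "sex")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata ", path, " missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl
}

#' Read a miRNA-to-gene target table
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `context_score`
#'   (more negative = stronger predicted repression).
#' @return A tibble.
#' @export
read_targets <- function(path) {
  tbl <- .read_tsv_strict(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    gene_id = readr::col_character(),
    context_score = readr::col_double()
  ))
  need <- c("mirna_id", "gene_id", "context_score")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Target table ", path, " missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl
}

.nodes_path <- function(path) {
  sub("(\\.[^.]+)?$", "_nodes\\1", path)
}

#' Write a sponge network to disk
#'
#' The `edge_list` format writes two TSVs: the edge list at `path`
#' (columns `source_id`, `source_class`, `target_id`, `target_class`,
#' `tissue_of_origin`, `mirna_color_key`) and the node table (with the
#' `log2_size` display attribute, the log2 of each node's interaction
#' count) at the same path with `_nodes` inserted before the extension.
#' The `graphml_like_xml` format writes a single minimal GraphML-style
#' XML document with node attributes inlined.
#'
#' @param net A `sponge_network` as built by [build_network()].
#' @param path Output path.
#' @param format `"edge_list"` or `"graphml_like_xml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "graphml_like_xml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "sponge_network"))
  nodes <- net$nodes
  edges <- net$edges
  unknown <- setdiff(unique(c(edges$source_id, edges$target_id)), nodes$id)
  if (length(unknown) > 0) {
    abort(paste0("Edge references unknown node(s): ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  if (format == "edge_list") {
    readr::write_tsv(edges, path, na = "", progress = FALSE)
    readr::write_tsv(nodes, .nodes_path(path), na = "", progress = FALSE)
  } else {
    doc <- xml2::xml_new_root("graphml")
    graph <- xml2::xml_add_child(doc, "graph", id = "sponge", edgedefault = "directed")
    for (i in seq_len(nrow(nodes))) {
      xml2::xml_add_child(
        graph, "node",
        id = nodes$id[i], class = nodes$class[i],
        tissue_of_origin = ifelse(is.na(nodes$tissue_of_origin[i]), "",
                                  nodes$tissue_of_origin[i]),
        degree = as.character(nodes$degree[i]),
        log2_size = as.character(nodes$log2_size[i])
      )
    }
    for (i in seq_len(nrow(edges))) {
      xml2::xml_add_child(
        graph, "edge",
        source = edges$source_id[i], target = edges$target_id[i],
        mirna_color_key = edges$mirna_color_key[i]
      )
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read a sponge network written in edge-list format
#'
#' @param path Path previously given to [write_network()] with
#'   `format = "edge_list"`.
#' @return A `sponge_network` object.
#' @export
read_network <- function(path) {
  edges <- .read_tsv_strict(path, col_types = readr::cols(
    source_id = readr::col_character(), source_class = readr::col_character(),
    target_id = readr::col_character(), target_class = readr::col_character(),
    tissue_of_origin = readr::col_character(),
    mirna_color_key = readr::col_character()
  ))
  nodes <- .read_tsv_strict(.nodes_path(path), col_types = readr::cols(
    id = readr::col_character(), class = readr::col_character(),
    tissue_of_origin = readr::col_character(),
    degree = readr::col_integer(), log2_size = readr::col_double()
  ))
  structure(list(nodes = nodes, edges = edges), class = "sponge_network")
}
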