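# Readers and writers for the tabular input formats: edge lists, gene ->
# transcript -> domain annotations, domain-domain interactions, transcript
# expression with sample metadata, and one-id-per-line lists.
#
# Dialect: UTF-8, tab-separated, '\n' or '\r\n' line endings, '#'-prefixed
# comment lines skipped, blank lines skipped. Malformed rows are rejected
# with their line number.

read_tsv_rows <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(
    fields = strsplit(lines[keep], "\t", fixed = TRUE),
    lineno = which(keep)
  )
}

is_header_row <- function(fields, known) {
  length(fields) >= 1L && all(tolower(fields) %in% known)
}

#' Read a global PPIN from a two-column edge list
#'
#' Parses a TSV with two node-identifier columns (optional header,
#' `#`-comments ignored), canonicalizes and deduplicates the edges, and
#' drops self-loop rows with a warning (interactome exports routinely
#' contain homodimers, but perturbation codes are defined on
#' distinct-endpoint edges).
#'
#' @param path Path to the edge-list TSV.
#' @return A [ppin].
#' @export
read_edge_list <- function(path) {
  rows <- read_tsv_rows(path)
  fields <- rows$fields
  header_names <- c("node_a", "node_b", "protein_a", "protein_b",
                    "gene_a", "gene_b", "interactor_a", "interactor_b",
                    "source", "target")
  if (length(fields) > 0L && length(fields[[1L]]) == 2L &&
      is_header_row(fields[[1L]], header_names)) {
    fields <- fields[-1L]
    rows$lineno <- rows$lineno[-1L]
  }
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop("line ", rows$lineno[bad[1L]], ": expected 2 fields, got ",
         length(fields[[bad[1L]]]))
  }
  if (length(fields) == 0L) return(ppin())
  m <- do.call(rbind, fields)
  ppin(data.frame(a = m[, 1L], b = m[, 2L], stringsAsFactors = FALSE),
       drop_self_loops = TRUE)
}

#' Write a network as a two-column edge list
#'
#' @param net A [ppin].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("node_a\tnode_b", con)
  if (nrow(net$edges) > 0L) {
    writeLines(paste(net$edges$a, net$edges$b, sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a gene/transcript/domain annotation set
#'
#' Maps every transcript to exactly one gene and to a (possibly empty) set
#' of protein domain accessions carried by its product. Transcript order
#' within a gene follows first appearance.
#'
#' @param gene Character vector of gene ids (one per transcript row).
#' @param transcript Character vector of transcript ids.
#' @param domains List of character vectors of domain accessions (or `NULL`
#'   for all-empty).
#' @return Object of class `annotation_set` with elements
#'   `gene_of_transcript` (named character), `transcripts_of_gene` (named
#'   list, file order preserved) and `domains_of_transcript` (named list).
#' @export
annotation_set <- function(gene, transcript, domains = NULL) {
  gene <- as.character(gene)
  transcript <- as.character(transcript)
  stopifnot(length(gene) == length(transcript))
  if (is.null(domains)) domains <- rep(list(character()), length(transcript))
  stopifnot(length(domains) == length(transcript))

  first <- !duplicated(transcript)
  g1 <- gene[first]
  names(g1) <- transcript[first]
  conflict <- gene != g1[transcript]
  if (any(conflict)) {
    stop("transcript '", transcript[conflict][1L],
         "' assigned to more than one gene")
  }
  dom <- rep(list(character()), sum(first))
  names(dom) <- transcript[first]
  for (i in seq_along(transcript)) {
    d <- domains[[i]]
    d <- d[nzchar(d)]
    if (length(d) > 0L) {
      dom[[transcript[i]]] <- unique(c(dom[[transcript[i]]], d))
    }
  }
  tx_of_gene <- split(transcript[first], g1)[unique(g1)]
  structure(
    list(
      gene_of_transcript = g1,
      transcripts_of_gene = tx_of_gene,
      domains_of_transcript = dom
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("AnnotationSet: ", length(x$transcripts_of_gene), " genes, ",
      length(x$gene_of_transcript), " transcripts\n", sep = "")
  invisible(x)
}

#' Read gene/transcript/domain annotations
#'
#' Parses a TSV with columns `gene_id`, `transcript_id`, `domains`
#' (comma-separated accessions; empty allowed). Duplicate
#' (gene, transcript) rows union their domains; a transcript assigned to
#' two different genes is an error.
#'
#' @param path Path to the annotation TSV.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path) {
  rows <- read_tsv_rows(path)
  fields <- rows$fields
  if (length(fields) > 0L &&
      is_header_row(fields[[1L]][1:2],
                    c("gene_id", "transcript_id", "gene", "transcript"))) {
    fields <- fields[-1L]
    rows$lineno <- rows$lineno[-1L]
  }
  bad <- which(!lengths(fields) %in% c(2L, 3L))
  if (length(bad) > 0L) {
    stop("line ", rows$lineno[bad[1L]], ": expected 2-3 fields, got ",
         length(fields[[bad[1L]]]))
  }
  gene <- vapply(fields, `[[`, character(1), 1L)
  tx <- vapply(fields, `[[`, character(1), 2L)
  doms <- lapply(fields, function(f) {
    if (length(f) < 3L || !nzchar(f[[3L]])) character() else
      strsplit(f[[3L]], ",", fixed = TRUE)[[1L]]
  })
  annotation_set(gene, tx, doms)
}

#' Construct a domain-domain interaction map
#'
#' Stores an unordered set of interacting domain-type pairs (homotypic
#' self-pairs allowed), queried symmetrically.
#'
#' @param d1,d2 Character vectors of domain accessions (parallel).
#' @return Object of class `ddi_map`.
#' @export
ddi_map <- function(d1 = character(), d2 = character()) {
  d1 <- as.character(d1)
  d2 <- as.character(d2)
  stopifnot(length(d1) == length(d2))
  if (length(d1) == 0L) {
    keys <- character()
  } else {
    lev <- radix_sort(unique(c(d1, d2)))
    swap <- match(d1, lev) > match(d2, lev)
    keys <- unique(paste(ifelse(swap, d2, d1), ifelse(swap, d1, d2), sep = "|"))
  }
  structure(list(keys = keys), class = "ddi_map")
}

#' @export
print.ddi_map <- function(x, ...) {
  cat("DDIMap: ", length(x$keys), " domain pair(s)\n", sep = "")
  invisible(x)
}

#' Query a DDI map
#'
#' @param map A [ddi_map].
#' @param d1,d2 Domain accessions (vectorized, parallel).
#' @return Logical vector: is the unordered pair in the map?
#' @export
ddi_contains <- function(map, d1, d2) {
  if (length(map$keys) == 0L) return(rep(FALSE, length(d1)))
  paste(pmin_chr(d1, d2), pmax_chr(d1, d2), sep = "|") %in% map$keys
}

# byte-order character pmin/pmax
pmin_chr <- function(a, b) {
  lev <- radix_sort(unique(c(a, b)))
  ifelse(match(a, lev) <= match(b, lev), a, b)
}
pmax_chr <- function(a, b) {
  lev <- radix_sort(unique(c(a, b)))
  ifelse(match(a, lev) <= match(b, lev), b, a)
}

# TRUE if any cross pair between two domain sets is in the map.
sets_interact <- function(map, set1, set2) {
  if (length(map$keys) == 0L || length(set1) == 0L || length(set2) == 0L) {
    return(FALSE)
  }
  g <- expand.grid(d1 = set1, d2 = set2,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  any(ddi_contains(map, g$d1, g$d2))
}

#' Read a domain-domain interaction TSV
#'
#' Two domain-accession columns; symmetric duplicates collapse to one pair.
#'
#' @param path Path to the DDI TSV.
#' @return A [ddi_map].
#' @export
read_ddi <- function(path) {
  rows <- read_tsv_rows(path)
  fields <- rows$fields
  if (length(fields) > 0L && length(fields[[1L]]) == 2L &&
      is_header_row(fields[[1L]], c("domain_a", "domain_b"))) {
    fields <- fields[-1L]
    rows$lineno <- rows$lineno[-1L]
  }
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop("line ", rows$lineno[bad[1L]], ": expected 2 fields, got ",
         length(fields[[bad[1L]]]))
  }
  if (length(fields) == 0L) return(ddi_map())
  m <- do.call(rbind, fields)
  ddi_map(m[, 1L], m[, 2L])
}

#' Construct an expression matrix with sample metadata
#'
#' Holds non-negative transcript-level abundance estimates (RSEM-like
#' units) for a cohort of paired healthy/tumor samples.
#'
#' @param values Numeric matrix, transcripts (rows) by samples (columns),
#'   with dimnames.
#' @param meta Data.frame with columns `sample`, `patient`, `condition`
#'   (`"healthy"` or `"tumor"`), `cohort` and optionally `stage`.
#' @return Object of class `expr_matrix` with elements `values` and `meta`.
#' @export
expression_matrix <- function(values, meta) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("missing expression cell(s); no imputation is done")
  if (any(values < 0)) stop("negative expression value")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry transcript rownames and sample colnames")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample", "patient", "condition", "cohort")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (!"stage" %in% names(meta)) meta$stage <- NA_character_
  if (!all(meta$condition %in% c("healthy", "tumor"))) {
    stop("condition must be 'healthy' or 'tumor'")
  }
  missing_meta <- setdiff(colnames(values), meta$sample)
  if (length(missing_meta) > 0L) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  if (anyDuplicated(meta[, c("patient", "condition", "cohort")])) {
    stop("duplicated (patient, condition) within a cohort")
  }
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " transcripts x ",
      ncol(x$values), " samples (",
      sum(x$meta$condition == "healthy"), " healthy, ",
      sum(x$meta$condition == "tumor"), " tumor)\n", sep = "")
  invisible(x)
}

#' Read transcript expression values and sample metadata
#'
#' The values TSV has a header row of sample ids with the transcript id in
#' the first column; the metadata TSV has columns `sample`, `patient`,
#' `condition`, `cohort` and optionally `stage`. Missing cells and negative
#' values are errors, as are samples without metadata.
#'
#' @param values_path Path to the expression TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @return An [expression_matrix].
#' @export
read_expression <- function(values_path, meta_path) {
  vals <- utils::read.delim(values_path, check.names = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(vals) < 2L) stop("expression table needs >= 1 sample column")
  tx <- as.character(vals[[1L]])
  if (anyDuplicated(tx)) stop("duplicated transcript id in expression table")
  m <- as.matrix(vals[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value")
  rownames(m) <- tx
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
  expression_matrix(m, meta)
}

#' Write transcript expression values and metadata
#'
#' @param expr An [expression_matrix].
#' @param values_path,meta_path Output paths.
#' @return Invisibly, `values_path`.
#' @export
write_expression <- function(expr, values_path, meta_path) {
  df <- data.frame(transcript = rownames(expr$values),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' Read a one-identifier-per-line list
#'
#' Used for node whitelists (abundance filters) and significantly mutated
#' gene lists. Blank lines and `#`-comments are skipped.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  trimws(lines[nzchar(lines) & !startsWith(lines, "#")])
}
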