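#' Read an expression table and its sample design sheet
#'
#' The counts file is a TSV with a `gene_id` column (or row names in the
#' first column) and one numeric column per sample; the design file is a
#' TSV with columns `sample_id`, `condition` (one of `pH74`, `pH74_LPS`,
#' `pH65`, `pH65_LPS`) and `replicate_set`.  Validation errors name the
#' offending sample or condition.
#'
#' @param counts_path path to the counts TSV.
#' @param design_path path to the design TSV.
#' @param normalize rescale samples to 10 million on read.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(counts_path, design_path, normalize = FALSE) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  id_col <- if ("gene_id" %in% names(tab)) "gene_id" else names(tab)[1]
  ids <- as.character(tab[[id_col]])
  mat <- as.matrix(tab[, setdiff(names(tab), id_col), drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in counts table")
  rownames(mat) <- ids
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(design$sample_id, colnames(mat))
  if (length(missing_cols))
    stop("design references missing sample column(s): ",
         paste(missing_cols, collapse = ", "))
  em <- expression_matrix(mat[, design$sample_id, drop = FALSE], design)
  if (normalize) em <- normalize_matrix(em) else em
}

#' Write an expression matrix and design sheet as TSV
#'
#' @param x an [expression_matrix()].
#' @param counts_path,design_path output paths.
#' @return invisibly, `x`.
#' @export
write_expression <- function(x, counts_path, design_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  out <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Collapse a transcript-level table to gene level by summation
#'
#' Sums transcript rows per gene (the convention used when gene totals
#' are derived from transcript-level quantification).  Gene order follows
#' first appearance; unmapped transcripts are dropped with a message.
#'
#' @param counts numeric matrix with transcript ids as row names.
#' @param map data.frame with columns `transcript_id`, `gene_id`.
#' @return gene-level numeric matrix.
#' @export
collapse_transcripts <- function(counts, map) {
  counts <- as.matrix(counts)
  gene <- map$gene_id[match(rownames(counts), map$transcript_id)]
  mapped <- !is.na(gene)
  if (!any(mapped)) stop("no transcripts map to genes")
  if (any(!mapped))
    message(sum(!mapped), " unmapped transcript(s) dropped")
  g <- gene[mapped]
  out <- rowsum(counts[mapped, , drop = FALSE], group = g, reorder = FALSE)
  out[unique(g), , drop = FALSE]
}

#' Read a protein FASTA file
#'
#' UniProt-style headers (`sp|ACC|NAME desc` / `tr|ACC|NAME desc`) yield
#' `ACC` as the accession; plain `>id desc` headers use `id`.  Sequences
#' are uppercased; records with empty sequences are skipped with a
#' warning.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `description`,
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) {
    warning("no FASTA records in ", path)
    return(data.frame(accession = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(aa)
  first <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  acc <- ifelse(grepl("^(sp|tr)\\|", first),
                vapply(strsplit(first, "\\|"), `[`, character(1), 2L),
                first)
  seqs <- toupper(as.character(aa))
  keep <- nchar(seqs) > 0
  if (any(!keep))
    warning("skipped ", sum(!keep), " empty-sequence record(s)")
  data.frame(accession = acc[keep], description = desc[keep],
             sequence = unname(seqs[keep]), stringsAsFactors = FALSE)
}

#' Write proteins to FASTA (60-column wrapping)
#'
#' @param proteins data.frame with columns `accession`, `description`,
#'   `sequence`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nchar(proteins$description) > 0,
                      paste(proteins$accession, proteins$description),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a per-residue disorder sidecar table
#'
#' @param path TSV with columns `protein_id`, `position`, `score`.
#' @return data.frame, scores validated to lie in `[0, 1]`.
#' @export
read_disorder <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "score") %in% names(tab)))
  if (any(tab$score < 0 | tab$score > 1))
    stop("disorder scores must lie in [0, 1]")
  tab
}

#' Write a disorder sidecar table
#'
#' @param sidecar data.frame with `protein_id`, `position`, `score`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_disorder <- function(sidecar, path) {
  utils::write.table(sidecar, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run summary
#'
#' Serialises filter-funnel counts, the resolved configuration, seed and
#' package version to JSON (stable key order, unboxed scalars).
#'
#' @param counts named list of per-stage counts.
#' @param config named list echoing the resolved configuration.
#' @param seed integer seed of the run (or `NA`).
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @param inputs optional character vector of input files; their md5
#'   hashes are recorded.
#' @return the JSON string, invisibly when written to `path`.
#' @export
run_summary <- function(counts = list(), config = list(), seed = NA,
                        path = NULL, inputs = NULL) {
  hashes <- if (!is.null(inputs))
    as.list(tools::md5sum(inputs)) else NULL
  obj <- list(package = "phdeconv",
              version = as.character(utils::packageVersion("phdeconv")),
              seed = seed, counts = counts, config = config,
              input_md5 = hashes)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# stable TSV writer for result tables (unix newlines, no quoting)
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
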