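#' Construct an ExpressionMatrix
#'
#' Bundles a gene-by-sample count matrix with a sample design sheet mapping
#' each sample to one of the four conditions (`pH74`, `pH74_LPS`, `pH65`,
#' `pH65_LPS`) and a replicate set.  Every replicate set must contain each
#' condition exactly once.
#'
#' @param counts numeric matrix, genes in rows, samples in columns;
#'   column names must match `design$sample_id`.
#' @param design data.frame with columns `sample_id`, `condition`,
#'   `replicate_set`.
#' @param normalized logical; `TRUE` once each sample has been rescaled to
#'   a common library size (see [normalize_matrix()]).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts`, `design`, `normalized`.
#' @seealso [normalize_matrix()], [read_expression()]
#' @export
expression_matrix <- function(counts, design, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample_id", "condition", "replicate_set")
  if (!all(req %in% names(design)))
    stop("design must have columns sample_id, condition, replicate_set")
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  bad <- setdiff(design$condition, PH_CONDITIONS)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (is.null(colnames(counts)))
    stop("counts must have sample column names")
  if (!setequal(colnames(counts), design$sample_id))
    stop("counts columns and design sample_id do not match")
  # one sample per condition per replicate set
  for (rs in unique(design$replicate_set)) {
    conds <- design$condition[design$replicate_set == rs]
    for (cc in PH_CONDITIONS) {
      k <- sum(conds == cc)
      if (k != 1L)
        stop("replicate set ", rs, " has ", k, " samples for condition ",
             cc, " (need exactly 1)")
    }
  }
  counts <- counts[, design$sample_id, drop = FALSE]
  structure(list(counts = counts, design = design, normalized = normalized),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", length(unique(x$design$replicate_set)),
      "replicate set(s);", if (x$normalized) "normalized" else "raw", "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Rescale each sample to a common library size
#'
#' Multiplies every column by `target / colsum` so that each sample's total
#' count equals `target` (10 million by default, the convention used for
#' bulk RNA-seq of bone-marrow-derived macrophages here).
#'
#' @param x an [expression_matrix()] object.
#' @param target total count per sample after scaling.
#' @return The rescaled `ExpressionMatrix` with `normalized = TRUE`.
#' @export
normalize_matrix <- function(x, target = 1e7) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cs <- colSums(x$counts)
  if (any(cs == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x$counts)[cs == 0], collapse = ", "))
  x$counts <- sweep(x$counts, 2, target / cs, `*`)
  x$normalized <- TRUE
  x
}

# counts of one gene arranged as a 4 x R matrix (condition x replicate set)
.condition_counts <- function(x, gene) {
  sets <- sort(unique(x$design$replicate_set))
  out <- matrix(NA_real_, 4L, length(sets),
                dimnames = list(PH_CONDITIONS, as.character(sets)))
  for (j in seq_along(sets)) {
    sel <- x$design$replicate_set == sets[j]
    out[x$design$condition[sel], j] <- x$counts[gene, x$design$sample_id[sel]]
  }
  out
}
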