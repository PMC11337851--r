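# A count table is a plain numeric matrix, taxa in rows and samples in
# columns, with both dimensions named. All operations validate through
# validate_count_table() so downstream code can assume a well-formed table.

#' Validate a taxon-by-sample count table
#'
#' Checks the invariants every pipeline stage relies on: numeric matrix,
#' named rows (taxa) and columns (samples) without duplicates, no negative
#' or missing entries, and at least one positive entry per sample column.
#'
#' @param x numeric matrix, taxa in rows, samples in columns.
#' @param require_positive_columns if `TRUE` (default), every sample column
#'   must contain at least one positive entry.
#' @return `x`, invisibly, if valid; otherwise an error locating the
#'   offending label or cell.
#' @export
validate_count_table <- function(x, require_positive_columns = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have taxon row names and sample column names")
  dup_t <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_t))
    stop("duplicate taxon label(s): ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(x))
    stop("count table contains missing values")
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative entry %g at taxon '%s', sample '%s'",
                 x[idx[1], idx[2]], rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  if (require_positive_columns) {
    zero <- colSums(x) <= 0
    if (any(zero))
      stop("sample(s) with no positive entries: ",
           paste(colnames(x)[zero], collapse = ", "))
  }
  invisible(x)
}

#' Read a count table from a tab-separated file
#'
#' The canonical on-disk format is TSV with a header row; the first column
#' is named `taxon` and holds the labels, the remaining columns are samples.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with taxon row names and sample column names, in
#'   file order.
#' @seealso [write_count_table()] for the loss-free inverse.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("count table needs a 'taxon' column plus at least one sample column")
  if (names(df)[1] != "taxon")
    stop("first column must be named 'taxon', found '", names(df)[1], "'")
  labs <- as.character(df[[1]])
  body <- df[-1]
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric sample column(s): ", paste(names(body)[bad], collapse = ", "))
  x <- as.matrix(body)
  rownames(x) <- labs
  validate_count_table(x)
  x
}

#' Write a count table as tab-separated text
#'
#' @param x validated count table matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  validate_count_table(x, require_positive_columns = FALSE)
  df <- data.frame(taxon = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each sample column by its total so columns sum to one. The
#' transformation is idempotent and preserves within-column ratios.
#'
#' @param x count table matrix (counts or already-normalized fractions).
#' @return matrix of the same shape with columns summing to 1.
#' @export
relative_abundance <- function(x) {
  validate_count_table(x, require_positive_columns = FALSE)
  tot <- colSums(x)
  zero <- tot <= 0
  if (any(zero))
    stop("cannot normalize all-zero sample(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  sweep(x, 2, tot, "/")
}

#' Read a phylogenetic tree in newick format
#'
#' Thin wrapper around [ape::read.tree()] enforcing the contract the
#' downstream patristic-distance computations need: every edge has a
#' nonnegative branch length and leaf labels are unique. Unrooted
#' multifurcations are accepted.
#'
#' @param path newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("could not parse newick tree: ", path)
  n_edge <- nrow(tr$edge)
  if (is.null(tr$edge.length) || length(tr$edge.length) != n_edge ||
      anyNA(tr$edge.length))
    stop("tree must have a branch length on every edge (no defaults assumed)")
  if (any(tr$edge.length < 0))
    stop("negative branch length in tree")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  tr
}
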