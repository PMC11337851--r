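# Abundance-weighted phylogenetic beta-diversity between samples: the mean
# pairwise patristic distance (MPD, comdist-style) and the mean nearest
# taxon distance (MNTD, comdistnt-style), both over a patristic distance
# matrix derived from a reference tree.

#' Patristic distance matrix of a tree's leaves
#'
#' Entry (x, y) is the sum of branch lengths along the unique tree path
#' between leaves x and y.
#'
#' @param tree an [ape::phylo] tree with branch lengths (see [read_tree()]).
#' @param taxa optional character vector; if given, the matrix is restricted
#'   to (and ordered by) these leaves, and leaves missing from the tree are
#'   an error.
#' @return square symmetric matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree, taxa = NULL) {
  m <- stats::cophenetic(tree)
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, rownames(m))
    if (length(miss))
      stop("taxa missing from tree: ", paste(miss, collapse = ", "))
    m <- m[taxa, taxa, drop = FALSE]
  }
  m
}

.weights_for_phylo <- function(x, pat) {
  validate_count_table(x, require_positive_columns = FALSE)
  miss <- setdiff(rownames(x), rownames(pat))
  if (length(miss))
    stop("taxa missing from patristic matrix: ", paste(miss, collapse = ", "))
  empty <- colSums(x) == 0
  if (any(empty))
    stop("empty sample(s): ", paste(colnames(x)[empty], collapse = ", "))
  p <- relative_abundance(x)  # renormalized over the tree-covered taxa
  list(p = p, pat = pat[rownames(x), rownames(x), drop = FALSE])
}

#' Abundance-weighted mean pairwise phylogenetic distance (MPD) between samples
#'
#' MPD(A, B) = sum_i sum_j p_iA p_jB pat(i, j), with p the within-sample
#' relative abundances. The diagonal is computed by the same formula (the
#' expected distance between two random reads of the same sample) and may
#' be positive; downstream permutation tests ignore it.
#'
#' @param x count table; taxa must all be leaves of the patristic matrix.
#' @param pat patristic matrix from [patristic_matrix()].
#' @return symmetric matrix over samples with `"flavor"` attribute `"mpd"`.
#' @export
comdist_weighted <- function(x, pat) {
  w <- .weights_for_phylo(x, pat)
  d <- crossprod(w$p, w$pat %*% w$p)
  d <- (d + t(d)) / 2  # exact symmetry against rounding
  attr(d, "flavor") <- "mpd"
  d
}

#' Abundance-weighted mean nearest taxon distance (MNTD) between samples
#'
#' Directional term D(A -> B) = sum_i p_iA min_{j in B} pat(i, j), the
#' abundance-weighted distance from each taxon of A to its nearest taxon
#' present in B; the reported value is the symmetric average
#' (D(A -> B) + D(B -> A)) / 2. A taxon present in both samples has a
#' nearest distance of zero (conspecifics are not excluded).
#'
#' @inheritParams comdist_weighted
#' @param symmetric if `FALSE`, return the directional matrix D(row ->
#'   column) instead of the symmetric average.
#' @return matrix over samples with `"flavor"` attribute `"mntd"`.
#' @export
comdistnt_weighted <- function(x, pat, symmetric = TRUE) {
  w <- .weights_for_phylo(x, pat)
  p <- w$p
  # nn[i, B]: distance from taxon i to its nearest taxon present in B
  nn <- vapply(seq_len(ncol(p)), function(b) {
    pres <- p[, b] > 0
    apply(w$pat[, pres, drop = FALSE], 1, min)
  }, numeric(nrow(p)))
  d <- crossprod(p, nn)  # d[A, B] = D(A -> B)
  dimnames(d) <- list(colnames(p), colnames(p))
  if (symmetric) d <- (d + t(d)) / 2
  attr(d, "flavor") <- "mntd"
  d
}
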