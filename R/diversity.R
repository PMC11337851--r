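# Taxonomic beta-diversity (Bray-Curtis), principal coordinates
# ordination, and analytic rarefaction.

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' BC(A,B) = sum|a_i - b_i| / sum(a_i + b_i), abundance-weighted, in
#' [0, 1]. Computed with [vegan::vegdist()].
#'
#' @param x count table (counts or relative abundances).
#' @return square symmetric matrix over samples with zero diagonal and a
#'   `"flavor"` attribute `"bray-curtis"`.
#' @export
bray_curtis_matrix <- function(x) {
  validate_count_table(x, require_positive_columns = FALSE)
  if (ncol(x) < 2) stop("need at least 2 samples")
  zero <- colSums(x) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(x)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  diag(d) <- 0
  attr(d, "flavor") <- "bray-curtis"
  d
}

#' Principal coordinates ordination of a distance matrix
#'
#' Classical metric scaling (Gower double-centering + eigendecomposition),
#' delegated to [ape::pcoa()], the routine the field's standard workflow
#' uses. Axes with negative eigenvalues are reported in `eigenvalues` but
#' excluded from the coordinates; no Cailliez/Lingoes correction is applied
#' unless requested.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param axes number of coordinate axes to return (truncated with a
#'   recorded warning if it exceeds the number of positive eigenvalues).
#' @param correction `"none"` (default), `"cailliez"` or `"lingoes"`,
#'   passed to [ape::pcoa()].
#' @return list of class `pcoa_ordination`: `ids`, `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending),
#'   `proportion_explained` (per returned axis, over the positive-
#'   eigenvalue total) and `warnings`.
#' @export
pcoa_ordination <- function(d, axes = 2, correction = "none") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-9 ||
      max(abs(diag(d))) > 1e-9)
    stop("input must be a square symmetric zero-diagonal distance matrix")
  ids <- rownames(d)
  warnings <- character(0)
  if (max(d) == 0) {
    coords <- matrix(0, nrow(d), 0, dimnames = list(ids, NULL))
    return(structure(list(ids = ids, coordinates = coords,
                          eigenvalues = rep(0, nrow(d)),
                          proportion_explained = numeric(0),
                          warnings = "all distances zero; no positive axes"),
                     class = "pcoa_ordination"))
  }
  p <- ape::pcoa(stats::as.dist(d), correction = correction)
  eig <- p$values$Eigenvalues
  npos <- sum(eig > 1e-9 * max(abs(eig)))
  k <- min(axes, npos, ncol(p$vectors))
  if (axes > k)
    warnings <- c(warnings, sprintf(
      "requested %d axes but only %d positive eigenvalues; truncated", axes, k))
  coords <- p$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- ids
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(ids = ids, coordinates = coords, eigenvalues = eig,
                 proportion_explained = eig[seq_len(k)] / sum(eig[eig > 0]),
                 warnings = warnings),
            class = "pcoa_ordination")
}

#' Expected rarefied richness of one sample
#'
#' Hypergeometric expectation of the number of distinct taxa seen in a
#' random subsample of `depth` reads:
#' E[S] = sum_i (1 - C(N - N_i, depth) / C(N, depth)), evaluated with
#' log-gamma arithmetic ([lchoose()]) for numerical stability.
#'
#' @param counts integer count vector for one sample.
#' @param depth subsample size, between 1 and `sum(counts)`.
#' @return expected richness (numeric scalar).
#' @export
rarefy_richness <- function(counts, depth) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  N <- sum(counts)
  if (depth > N) stop("depth (", depth, ") exceeds total counts (", N, ")")
  if (depth < 1) stop("depth must be at least 1")
  ni <- counts[counts > 0]
  # lchoose(m, k) is -Inf for m < k, giving probability 0 of missing taxon i
  sum(1 - exp(lchoose(N - ni, depth) - lchoose(N, depth)))
}
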