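# The LRD (log2 RNA:DNA) activity index. For taxon i and treatment j the
# index is the mean over timepoints t of log2(r_ijt / d_ijt), where r is
# the metatranscriptomic relative abundance and d the 16S rDNA relative
# abundance, both on the post-merge label space. Taxa are then classified:
# Group I (mean LRD > 3.5, high relative synthetic capacity), Group II
# (|mean LRD| <= 3.5), Group III (mean LRD < -3.5).

#' Average replicate samples onto the treatment-by-timepoint grid
#'
#' Converts a sample-level count table to relative abundances and averages
#' replicate columns within each (treatment, timepoint) cell; since the
#' mean is linear, averaged columns still sum to one.
#'
#' @param x count table with one column per sample in `design`.
#' @param design sample design data frame (see [validate_sample_design()]);
#'   must cover exactly the columns of `x`.
#' @return matrix with one column per (treatment, timepoint) cell, named
#'   `<treatment>.t<index>`, carrying a `"grid"` attribute (data frame:
#'   column, treatment, t_index, n_replicates).
#' @export
average_replicates <- function(x, design) {
  validate_count_table(x)
  validate_sample_design(design)
  if (!setequal(colnames(x), design$sample_id))
    stop("design does not cover the table's samples; differ on: ",
         paste(union(setdiff(colnames(x), design$sample_id),
                     setdiff(design$sample_id, colnames(x))), collapse = ", "))
  design <- design[match(colnames(x), design$sample_id), ]
  rel <- relative_abundance(x)
  cell <- paste0(design$treatment, ".t", design$t_index)
  cells <- unique(cell)
  out <- vapply(cells, function(cl)
    rowMeans(rel[, cell == cl, drop = FALSE]), numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), cells))
  grid <- data.frame(column = cells,
                     treatment = design$treatment[match(cells, cell)],
                     t_index = design$t_index[match(cells, cell)],
                     n_replicates = as.integer(table(cell)[cells]),
                     stringsAsFactors = FALSE)
  attr(out, "grid") <- grid
  out
}

#' Compute the LRD activity index
#'
#' For every taxon and treatment, takes the log2 ratio of metatranscriptomic
#' to 16S relative abundance at each timepoint present in both tables for
#' that treatment, and averages the admissible ratios. The mean runs over
#' the timepoints the treatment actually has (CEWAFN contributes three, the
#' others five, in the default design), so n is per (taxon, treatment).
#'
#' @param rna metatranscriptomic count table (sample-level).
#' @param dna 16S rRNA gene count table (sample-level, replicated).
#' @param rna_design,dna_design sample designs for the two tables.
#' @param zero_policy `"drop"` (default): timepoints where either side is
#'   zero contribute nothing and `n_used` shrinks; rows with no admissible
#'   timepoint are omitted and listed in `$skipped`. `"pseudocount"`:
#'   zeros are replaced by half the smallest nonzero relative abundance of
#'   the respective table, so every timepoint is admissible.
#' @return object of class `lrd_table`: list with `summary` (data frame
#'   taxon, treatment, lrd_mean, n_used, group, sorted by descending
#'   lrd_mean), `per_time` (long data frame of per-timepoint log2 ratios)
#'   and `skipped` (rows with no admissible timepoint).
#' @export
compute_lrd <- function(rna, dna, rna_design, dna_design,
                        zero_policy = c("drop", "pseudocount")) {
  zero_policy <- match.arg(zero_policy)
  r <- average_replicates(rna, rna_design)
  d <- average_replicates(dna, dna_design)
  if (!setequal(rownames(r), rownames(d))) {
    stop("taxon label sets differ between rna and dna tables: ",
         paste(union(setdiff(rownames(r), rownames(d)),
                     setdiff(rownames(d), rownames(r))), collapse = ", "))
  }
  gr <- attr(r, "grid"); gd <- attr(d, "grid")
  d <- d[rownames(r), , drop = FALSE]
  grid <- merge(gr[c("column", "treatment", "t_index")],
                gd[c("column", "treatment", "t_index")],
                by = c("treatment", "t_index"), suffixes = c("_r", "_d"))
  grid <- grid[order(match(grid$treatment, gr$treatment), grid$t_index), ]
  if (!nrow(grid))
    stop("rna and dna tables share no (treatment, timepoint) cell")

  if (zero_policy == "pseudocount") {
    pc <- function(m) { m[m == 0] <- min(m[m > 0]) / 2; m }
    r <- pc(r); d <- pc(d)
  }

  per_time <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    rv <- r[, grid$column_r[k]]
    dv <- d[, grid$column_d[k]]
    ok <- rv > 0 & dv > 0
    data.frame(taxon = rownames(r)[ok],
               treatment = grid$treatment[k],
               t_index = grid$t_index[k],
               log2_ratio = log2(rv[ok] / dv[ok]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  all_rows <- expand.grid(taxon = rownames(r),
                          treatment = unique(grid$treatment),
                          stringsAsFactors = FALSE)
  key <- paste(per_time$taxon, per_time$treatment, sep = "\r")
  means <- tapply(per_time$log2_ratio, key, mean)
  nused <- tapply(per_time$log2_ratio, key, length)
  akey <- paste(all_rows$taxon, all_rows$treatment, sep = "\r")
  summary <- data.frame(all_rows,
                        lrd_mean = as.numeric(means[akey]),
                        n_used = as.integer(nused[akey]),
                        stringsAsFactors = FALSE)
  skipped <- summary[is.na(summary$lrd_mean), c("taxon", "treatment")]
  summary <- summary[!is.na(summary$lrd_mean), ]
  summary$group <- classify_lrd_groups(summary$lrd_mean)
  summary <- summary[order(-summary$lrd_mean, summary$taxon,
                           summary$treatment), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, per_time = per_time,
                 skipped = skipped, zero_policy = zero_policy),
            class = "lrd_table")
}

#' Classify mean LRD scores into activity groups
#'
#' Group I: mean LRD > 3.5 (greatest expected biosynthetic capacity);
#' Group II: |mean LRD| <= 3.5 (boundaries inclusive); Group III:
#' mean LRD < -3.5.
#'
#' @param lrd_mean numeric vector of finite mean LRD scores.
#' @return factor with levels I, II, III.
#' @export
classify_lrd_groups <- function(lrd_mean) {
  if (any(!is.finite(lrd_mean)))
    stop("lrd_mean must be finite")
  factor(ifelse(lrd_mean > 3.5, "I", ifelse(lrd_mean < -3.5, "III", "II")),
         levels = c("I", "II", "III"))
}

#' @export
print.lrd_table <- function(x, ...) {
  cat("LRD table:", nrow(x$summary), "(taxon, treatment) rows;",
      "groups:", paste(sprintf("%s=%d", levels(x$summary$group),
                               table(x$summary$group)), collapse = " "),
      "\n")
  print(utils::head(x$summary, 10))
  invisible(x)
}
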