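# Sample metadata for the microcosm design: oil (O), dispersant (D),
# nutrients (N) presence flags plus an ordinal timepoint. The five named
# treatments are fixed functions of the three flags.

.treatment_flags <- data.frame(
  treatment = c("BC", "DISP", "WAF", "CEWAF", "CEWAFN"),
  O = c(0L, 0L, 1L, 1L, 1L),
  D = c(0L, 1L, 0L, 1L, 1L),
  N = c(0L, 0L, 0L, 0L, 1L),
  stringsAsFactors = FALSE
)

.day_of_timepoint <- c(0, 7, 17, 28, 42)

#' Treatment label from the oil/dispersant/nutrient flags
#'
#' BC = (0,0,0), DISP = (0,1,0), WAF = (1,0,0), CEWAF = (1,1,0),
#' CEWAFN = (1,1,1). Any other combination is rejected: the microcosm
#' design contains no other condition.
#'
#' @param O,D,N 0/1 vectors (oil water-accommodated fraction, Corexit
#'   dispersant, inorganic nutrients).
#' @return character vector of treatment labels.
#' @export
treatment_label <- function(O, D, N) {
  key <- paste(as.integer(O), as.integer(D), as.integer(N))
  ref <- paste(.treatment_flags$O, .treatment_flags$D, .treatment_flags$N)
  hit <- match(key, ref)
  if (anyNA(hit))
    stop("no treatment corresponds to flags (O,D,N) = (",
         paste(key[which(is.na(hit))[1]]), ")")
  .treatment_flags$treatment[hit]
}

#' Validate a sample design table
#'
#' @param design data frame with columns `sample_id`, `treatment`, `O`,
#'   `D`, `N`, `t_index`, `day`, `replicate`.
#' @return `design`, invisibly.
#' @export
validate_sample_design <- function(design) {
  need <- c("sample_id", "treatment", "O", "D", "N", "t_index", "day",
            "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("sample design missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  bad <- is.na(design$O) | is.na(design$D) | is.na(design$N) |
    is.na(design$t_index)
  if (any(bad))
    stop("missing factor value for sample(s): ",
         paste(design$sample_id[bad], collapse = ", "))
  lab <- treatment_label(design$O, design$D, design$N)
  if (any(lab != design$treatment)) {
    off <- which(lab != design$treatment)[1]
    stop(sprintf("sample '%s': treatment '%s' inconsistent with flags (%d,%d,%d)",
                 design$sample_id[off], design$treatment[off],
                 design$O[off], design$D[off], design$N[off]))
  }
  invisible(design)
}

#' Read / write a sample design TSV
#'
#' Columns: sample_id, treatment, O, D, N, t_index, day, replicate.
#' @param path TSV file.
#' @return data frame (read) or `path` invisibly (write).
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_design(df)
  df
}

#' @rdname read_sample_design
#' @param design validated design data frame.
#' @export
write_sample_design <- function(design, path) {
  validate_sample_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
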