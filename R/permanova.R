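# Permutational multivariate ANOVA on a distance matrix with sequential
# (Type I) sums of squares, in the fixed term order of the microcosm
# testing model:
#
#   U = O + D + O:D + O:D:N + t + O:t + D:t + O:D:t + O:D:N:t
#
# with O (oil), D (dispersant), N (nutrients) binary factors and t the
# timepoint as a categorical factor. The machinery is general: any
# formula over a data frame of factors/numerics can be tested. Sums of
# squares are traces of the Gower-centered inner-product matrix against
# projection (hat) matrices; significance comes from freely permuting
# sample identities (rows/columns of the distance matrix).

.study_formula <- ~ O + D + O:D + O:D:N + t + O:t + D:t + O:D:t + O:D:N:t

#' Build the testing-model design from sample metadata
#'
#' Converts the O/D/N flags and the timepoint index into factors and
#' attaches the study's model formula with its terms in printed order.
#' Time is categorical (one level per timepoint) unless `time_linear`.
#'
#' @param design sample design data frame ([validate_sample_design()]).
#' @param time_linear treat time as a numeric covariate instead of a
#'   factor.
#' @return list with `data` (model frame, rownames = sample ids) and
#'   `formula` (terms in model order).
#' @export
build_design <- function(design, time_linear = FALSE) {
  validate_sample_design(design)
  data <- data.frame(
    O = factor(design$O, levels = sort(unique(design$O))),
    D = factor(design$D, levels = sort(unique(design$D))),
    N = factor(design$N, levels = sort(unique(design$N))),
    t = if (time_linear) as.numeric(design$day)
        else factor(design$t_index, levels = sort(unique(design$t_index))),
    row.names = design$sample_id)
  list(data = data, formula = .study_formula)
}

# Columns for one variable: treatment-contrast dummies for factors (none
# if the factor is constant), the centered values for numerics.
.var_columns <- function(v) {
  if (is.factor(v)) {
    lev <- levels(droplevels(v))
    if (length(lev) < 2)
      return(matrix(numeric(0), length(v), 0))
    m <- vapply(lev[-1], function(l) as.numeric(v == l), numeric(length(v)))
    matrix(m, nrow = length(v))
  } else {
    matrix(as.numeric(v), ncol = 1)
  }
}

# Columns for a term label like "O:D:t": all pairwise products of the
# component variables' columns.
.term_columns <- function(label, data) {
  vars <- strsplit(label, ":", fixed = TRUE)[[1]]
  cols <- lapply(vars, function(v) {
    if (!v %in% names(data)) stop("unknown model variable: ", v)
    .var_columns(data[[v]])
  })
  out <- cols[[1]]
  for (k in seq_along(cols)[-1]) {
    if (ncol(out) == 0 || ncol(cols[[k]]) == 0)
      return(matrix(numeric(0), nrow(data), 0))
    out <- do.call(cbind, lapply(seq_len(ncol(cols[[k]])),
                                 function(j) out * cols[[k]][, j]))
  }
  out
}

#' Sequential-SS PERMANOVA on a distance matrix
#'
#' Squared distances are Gower-double-centered into an inner-product
#' matrix G; the total sum of squares is tr(G) = sum(d^2)/n. Each model
#' term, in formula order, contributes SS_term = tr((H_k - H_{k-1}) G)
#' where H_k projects onto the column space of the intercept plus the
#' first k terms (sequential / Type I decomposition). The pseudo-F for a
#' term is (SS_term/df_term) / (SS_resid/df_resid), and its p-value is
#' (1 + #\{permutations with F* >= F\}) / (1 + n_perm) under free
#' permutation of sample identities. A term whose columns are aliased by
#' earlier terms (for example O:D:N, which reduces to N when nutrients
#' occur only in CEWAFN) keeps the degrees of freedom that survive; a term
#' adding no rank at all is reported with 0 df and no test.
#'
#' @param d square symmetric distance matrix over the design's samples.
#' @param data model frame (e.g. `build_design(design)$data`), rows
#'   aligned with `d`.
#' @param formula model formula; terms are kept in the order written.
#'   Defaults to the study model when `data` has O, D, N and t.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream; the global RNG
#'   state is restored on exit.
#' @return object of class `permanova`: data frame `$table` with one row
#'   per term plus Residual and Total (df, SS, R2 = SS/SS_total, pseudo-F,
#'   p), and fields `n_perm`, `seed`, `aliased` (labels of 0-df terms).
#' @export
permanova_sequential <- function(d, data, formula = .study_formula,
                                 n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n || max(abs(d - t(d))) > 1e-9)
    stop("distance matrix must be square and symmetric")
  if (nrow(data) != n)
    stop("design has ", nrow(data), " rows but distance matrix has ", n)
  real_rn <- !is.null(rownames(data)) &&
    !identical(rownames(data), as.character(seq_len(nrow(data))))
  if (!is.null(rownames(d)) && real_rn &&
      !identical(rownames(d), rownames(data)))
    stop("sample order of distance matrix and design differ")
  if (n_perm < 1) stop("n_perm must be >= 1")

  labels <- attr(stats::terms(formula, keep.order = TRUE), "term.labels")

  # Gower centering of -d^2/2
  A <- -0.5 * d^2
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  ss_total <- sum(diag(G))

  # incremental orthonormal basis; Hdiff per term
  Q <- matrix(1 / sqrt(n), n, 1)  # intercept
  hdiff <- vector("list", length(labels))
  df <- integer(length(labels))
  for (k in seq_along(labels)) {
    Xk <- .term_columns(labels[k], data)
    if (ncol(Xk)) {
      R <- Xk - Q %*% crossprod(Q, Xk)
      R <- R - Q %*% crossprod(Q, R)  # re-orthogonalize
      qr_k <- qr(R, tol = 1e-7)
      if (qr_k$rank > 0) {
        Qk <- qr.Q(qr_k)[, seq_len(qr_k$rank), drop = FALSE]
        hdiff[[k]] <- tcrossprod(Qk)
        Q <- cbind(Q, Qk)
        df[k] <- qr_k$rank
      }
    }
  }
  df_model <- sum(df)
  df_res <- n - 1L - df_model
  tested <- df > 0

  degenerate <- ss_total <= 1e-12  # all distances zero: nothing to partition
  if (degenerate) tested[] <- FALSE
  ss <- vapply(seq_along(labels), function(k)
    if (tested[k]) sum(hdiff[[k]] * G) else 0, numeric(1))
  ss_res <- ss_total - sum(ss)
  f_obs <- ifelse(tested & df_res > 0,
                  (ss / pmax(df, 1)) / (ss_res / df_res), NA_real_)

  # permutations: fixed hats, permuted G
  p_count <- integer(length(labels))
  if (any(tested) && df_res > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old_seed, globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    idx_t <- which(tested)
    for (b in seq_len(n_perm)) {
      prm <- sample.int(n)
      Gp <- G[prm, prm]
      ssp <- vapply(idx_t, function(k) sum(hdiff[[k]] * Gp), numeric(1))
      ssp_all <- numeric(length(labels)); ssp_all[idx_t] <- ssp
      ss_resp <- ss_total - sum(ssp_all)
      fp <- (ssp / df[idx_t]) / (ss_resp / df_res)
      p_count[idx_t] <- p_count[idx_t] + (fp >= f_obs[idx_t] - 1e-12)
    }
  }
  pval <- ifelse(tested & df_res > 0,
                 (1 + p_count) / (1 + n_perm), NA_real_)

  table <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    R2 = if (degenerate) NA_real_ else c(ss, ss_res, ss_total) / ss_total,
    pseudo_F = c(f_obs, NA, NA),
    p_value = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = table, n_perm = n_perm, seed = seed,
                 aliased = labels[df == 0], degenerate = degenerate),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS, ", x$n_perm, " permutations",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  tb <- x$table
  tb$SS <- signif(tb$SS, 5); tb$R2 <- signif(tb$R2, 4)
  tb$pseudo_F <- signif(tb$pseudo_F, 5)
  print(tb, row.names = FALSE)
  if (isTRUE(x$degenerate))
    cat("all distances are zero; no variance to partition\n")
  if (length(x$aliased))
    cat("aliased term(s) with 0 df, not tested:",
        paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}
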