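# End-to-end driver: (simulate or load) paired count tables -> threshold
# merge -> LRD -> Bray-Curtis / MPD / MNTD -> PCoA -> PERMANOVA, writing
# every artifact plus a checksummed manifest. Identical config + seed give
# byte-identical outputs.

.write_square_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a square distance matrix written by the pipeline
#' @param path TSV with a `sample_id` column followed by one column per id.
#' @return numeric matrix.
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

.required_config_keys <- c("seed", "threshold", "permutations")

#' Run the full microcosm analysis pipeline
#'
#' @param config a list, or path to a YAML file, with keys:
#'   \describe{
#'     \item{seed}{integer; drives simulation, tree and permutations.}
#'     \item{threshold}{relative-abundance merge resolution (e.g. 0.04).}
#'     \item{permutations}{PERMANOVA permutation count (e.g. 999).}
#'     \item{synthetic}{`TRUE` to simulate inputs; otherwise supply paths
#'       `rna`, `dna`, `rna_design`, `dna_design`, `taxonomy`, and
#'       optionally `tree`.}
#'     \item{sim}{optional sublist of [sim_config()] overrides
#'       (depth_rna, depth_dna, concentration, replicates_16s).}
#'     \item{retention, zero_policy, axes}{optional; defaults
#'       `"any_sample"`, `"drop"`, 2.}
#'   }
#' @param out_dir output directory (created if needed).
#' @return data frame manifest (file, md5, bytes), invisibly; also written
#'   as `manifest.tsv`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  miss <- setdiff(.required_config_keys, names(config))
  if (length(miss))
    stop("config missing key(s): ", paste(miss, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  retention <- config$retention %||% "any_sample"
  zero_policy <- config$zero_policy %||% "drop"
  axes <- config$axes %||% 2
  artifacts <- character(0)
  put <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(out_dir, name)
  }

  if (isTRUE(config$synthetic)) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_experiment(cfg)
    rna <- sim$rna; dna <- sim$dna
    rna_design <- sim$rna_design; dna_design <- sim$dna_design
    ref_table <- cfg$taxonomy
    write_count_table(rna, put("rna_counts.tsv"))
    write_count_table(dna, put("dna_counts.tsv"))
    write_sample_design(rna_design, put("rna_design.tsv"))
    write_sample_design(dna_design, put("dna_design.tsv"))
    utils::write.table(ref_table, put("taxonomy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, put("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tree <- NULL  # built over the merged label space below
  } else {
    for (key in c("rna", "dna", "rna_design", "dna_design", "taxonomy"))
      if (is.null(config[[key]]))
        stop("config missing key(s): ", key)
    rna <- read_count_table(config$rna)
    dna <- read_count_table(config$dna)
    rna_design <- read_sample_design(config$rna_design)
    dna_design <- read_sample_design(config$dna_design)
    ref_table <- utils::read.delim(config$taxonomy, check.names = FALSE,
                                   stringsAsFactors = FALSE,
                                   colClasses = "character")
    tree <- if (!is.null(config$tree)) read_tree(config$tree) else NULL
  }
  ref <- taxonomy_ref(ref_table)

  # one merge mapping shared by both tables: threshold on the combined
  # sample set so RNA and DNA end up on an identical label space
  stopifnot(identical(rownames(rna), rownames(dna)))
  merged <- merge_to_threshold(cbind(rna, dna), ref,
                               threshold = config$threshold,
                               retention_rule = retention)
  rna_m <- merged$table[, colnames(rna), drop = FALSE]
  dna_m <- merged$table[, colnames(dna), drop = FALSE]
  write_count_table(rna_m, put("merged_rna.tsv"))
  write_count_table(dna_m, put("merged_dna.tsv"))
  utils::write.table(merged$report$mapping, put("merge_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lrd <- compute_lrd(rna_m, dna_m, rna_design, dna_design,
                     zero_policy = zero_policy)
  utils::write.table(lrd$summary, put("lrd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lrd$per_time, put("lrd_per_time.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (is.null(tree)) tree <- simulate_tree(rownames(rna_m), seed = seed + 1L)
  ape::write.tree(tree, put("tree.nwk"))
  pat <- patristic_matrix(tree, taxa = rownames(rna_m))

  bc <- bray_curtis_matrix(rna_m)
  mpd <- comdist_weighted(rna_m, pat)
  mntd <- comdistnt_weighted(rna_m, pat)
  .write_square_matrix(bc, put("dist_bray_curtis.tsv"))
  .write_square_matrix(mpd, put("dist_mpd.tsv"))
  .write_square_matrix(mntd, put("dist_mntd.tsv"))

  ord <- pcoa_ordination(bc, axes = axes)
  utils::write.table(
    data.frame(sample_id = ord$ids, ord$coordinates, check.names = FALSE),
    put("pcoa_coordinates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(axis = seq_along(ord$eigenvalues),
               eigenvalue = ord$eigenvalues),
    put("pcoa_eigenvalues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  des <- build_design(rna_design)
  for (dd in list(list(bc, "bray_curtis"), list(mpd, "mpd"),
                  list(mntd, "mntd"))) {
    m <- as.matrix(dd[[1]])
    diag(m) <- 0  # self-comparison is reported but not tested
    m <- m[rna_design$sample_id, rna_design$sample_id]
    fit <- permanova_sequential(m, des$data, des$formula,
                                n_perm = config$permutations, seed = seed)
    utils::write.table(fit$table, put(paste0("permanova_", dd[[2]], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  paths <- file.path(out_dir, artifacts)
  manifest <- data.frame(file = artifacts,
                         md5 = unname(tools::md5sum(paths)),
                         bytes = file.size(paths),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
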