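# Dirichlet-multinomial simulator of the oil/dispersant microcosm design.
#
# Each (treatment, timepoint) cell is one microcosm bottle: a latent
# community composition is drawn once per cell from a Dirichlet whose mean
# is the (treatment-adjusted) base community and whose concentration
# parameter controls between-bottle overdispersion. The 16S libraries are
# replicate multinomial resamplings of that composition; the paired
# metatranscriptomic library resamples the same composition tilted by the
# planted per-taxon log2 RNA enrichments (then renormalized), so the
# RNA:DNA contrast within a bottle is exactly the planted signal plus
# sampling noise. Treatment effects on the DNA side are abundance
# fold-changes applied to the Dirichlet mean.

.default_lineages <- list(
  Bermanella        = c("Pseudomonadota", "Gammaproteobacteria", "Oceanospirillales", "Oceanospirillaceae"),
  Amphritea         = c("Pseudomonadota", "Gammaproteobacteria", "Oceanospirillales", "Oceanospirillaceae"),
  Balneatrix        = c("Pseudomonadota", "Gammaproteobacteria", "Oceanospirillales", "Oceanospirillaceae"),
  Pseudospirillum   = c("Pseudomonadota", "Gammaproteobacteria", "Oceanospirillales", "Oceanospirillaceae"),
  Alcanivorax       = c("Pseudomonadota", "Gammaproteobacteria", "Oceanospirillales", "Alcanivoracaceae"),
  Oleiphilus        = c("Pseudomonadota", "Gammaproteobacteria", "Oceanospirillales", "Oleiphilaceae"),
  Colwellia         = c("Pseudomonadota", "Gammaproteobacteria", "Alteromonadales", "Colwelliaceae"),
  Marinobacter      = c("Pseudomonadota", "Gammaproteobacteria", "Alteromonadales", "Marinobacteraceae"),
  Alteromonas       = c("Pseudomonadota", "Gammaproteobacteria", "Alteromonadales", "Alteromonadaceae"),
  Pseudomonas       = c("Pseudomonadota", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae"),
  Methylophaga      = c("Pseudomonadota", "Gammaproteobacteria", "Thiotrichales", "Piscirickettsiaceae"),
  Cycloclasticus    = c("Pseudomonadota", "Gammaproteobacteria", "Thiotrichales", "Piscirickettsiaceae"),
  Methylobacter     = c("Pseudomonadota", "Gammaproteobacteria", "Methylococcales", "Methylococcaceae"),
  Porticoccus       = c("Pseudomonadota", "Gammaproteobacteria", "Cellvibrionales", "Porticoccaceae"),
  Parvibaculum      = c("Pseudomonadota", "Alphaproteobacteria", "Hyphomicrobiales", "Parvibaculaceae"),
  Paracoccus        = c("Pseudomonadota", "Alphaproteobacteria", "Rhodobacterales", "Paracoccaceae"),
  Kordia            = c("Bacteroidota", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae"),
  Polaribacter      = c("Bacteroidota", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae"),
  Winogradskyella   = c("Bacteroidota", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae"),
  Halobacteriovorax = c("Bdellovibrionota", "Bdellovibrionia", "Bdellovibrionales", "Pseudobdellovibrionaceae")
)

.default_base <- c(
  Colwellia = 0.17, Marinobacter = 0.14, Alteromonas = 0.08,
  Pseudomonas = 0.07, Alcanivorax = 0.06, Polaribacter = 0.06,
  Kordia = 0.05, Winogradskyella = 0.05, Paracoccus = 0.05,
  Oleiphilus = 0.04, Cycloclasticus = 0.04, Porticoccus = 0.035,
  Balneatrix = 0.03, Pseudospirillum = 0.03, Amphritea = 0.025,
  Methylobacter = 0.02, Bermanella = 0.02, Halobacteriovorax = 0.015,
  Parvibaculum = 0.01, Methylophaga = 0.005)

#' Toy taxonomy reference for the default simulated community
#'
#' Twenty marine genera (hydrocarbon degraders, methylotrophs,
#' Flavobacteriaceae, a predatory Bdellovibrionota) with full
#' domain-to-genus lineages, plus a few synonym rows
#' (Proteobacteria/Pseudomonadota, Bacteroidetes/Bacteroidota,
#' Rhodobacteraceae/Paracoccaceae). Entirely synthetic in its abundance
#' structure; the lineages follow current nomenclature.
#'
#' @return data frame (label, canonical, rank, parent) suitable for
#'   [taxonomy_ref()].
#' @export
default_taxonomy_table <- function() {
  ranks <- c("phylum", "class", "order", "family")
  rows <- list(data.frame(label = "Bacteria", canonical = "Bacteria",
                          rank = "domain", parent = "",
                          stringsAsFactors = FALSE))
  seen <- character(0)
  for (g in names(.default_lineages)) {
    lin <- .default_lineages[[g]]
    parent <- "Bacteria"
    for (k in seq_along(lin)) {
      if (!(lin[k] %in% seen)) {
        rows[[length(rows) + 1]] <- data.frame(
          label = lin[k], canonical = lin[k], rank = ranks[k],
          parent = parent, stringsAsFactors = FALSE)
        seen <- c(seen, lin[k])
      }
      parent <- lin[k]
    }
    rows[[length(rows) + 1]] <- data.frame(
      label = g, canonical = g, rank = "genus", parent = parent,
      stringsAsFactors = FALSE)
  }
  syn <- data.frame(
    label = c("Proteobacteria", "Bacteroidetes", "Rhodobacteraceae"),
    canonical = c("Pseudomonadota", "Bacteroidota", "Paracoccaceae"),
    rank = c("phylum", "phylum", "family"),
    parent = c("", "", "Rhodobacterales"),
    stringsAsFactors = FALSE)
  # synonym rows must agree with the canonical node's own rank/parent
  nodes <- do.call(rbind, rows)
  syn$rank <- nodes$rank[match(syn$canonical, nodes$canonical)]
  syn$parent <- nodes$parent[match(syn$canonical, nodes$canonical)]
  rbind(nodes, syn)
}

.default_effects <- function() {
  data.frame(
    taxon = c("Colwellia", "Colwellia", "Colwellia",
              "Marinobacter", "Marinobacter",
              "Methylophaga", "Bermanella", "Amphritea"),
    treatment = c("DISP", "CEWAF", "CEWAFN",
                  "WAF", "DISP",
                  "CEWAF", "WAF", "CEWAF"),
    L = c(1, 1, 1, 1, 0, 4, 4, -4),
    fold = c(6, 6, 6, 6, 0.3, 1, 1, 1),
    t_min = 1L,
    stringsAsFactors = FALSE)
}

.default_cells <- function() {
  cells <- expand.grid(t_index = 0:4,
                       treatment = c("BC", "DISP", "WAF", "CEWAF"),
                       stringsAsFactors = FALSE)[, 2:1]
  cells <- rbind(cells, data.frame(treatment = "CEWAFN",
                                   t_index = c(0L, 1L, 4L)))
  flags <- .treatment_flags[match(cells$treatment, .treatment_flags$treatment), ]
  data.frame(treatment = cells$treatment, O = flags$O, D = flags$D,
             N = flags$N, t_index = as.integer(cells$t_index),
             day = .day_of_timepoint[cells$t_index + 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Configuration for the microcosm simulator
#'
#' Defaults mirror the study layout: treatments BC, DISP, WAF, CEWAF at
#' five timepoints (days 0, 7, 17, 28, 42) and CEWAFN at t0/t1/t4 only;
#' triplicate 16S libraries and one metatranscriptomic library per cell.
#'
#' @param seed integer seed controlling every random draw.
#' @param base named numeric vector of baseline community proportions
#'   (renormalized to sum to 1).
#' @param taxonomy taxonomy table (data frame) covering the taxa.
#' @param cells data frame (treatment, O, D, N, t_index, day) listing the
#'   microcosm cells to simulate.
#' @param effects data frame (taxon, treatment, L, fold, t_min): planted
#'   log2 RNA enrichment `L` and DNA abundance fold-change `fold`,
#'   applied from timepoint `t_min` on.
#' @param replicates_16s 16S replicates per cell (default 3).
#' @param replicates_rna metatranscriptomic libraries per cell (default 1).
#' @param depth_rna,depth_dna library sizes (reads); at least 1000.
#' @param concentration Dirichlet concentration (overdispersion knob;
#'   larger = less between-bottle variation).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       base = .default_base,
                       taxonomy = default_taxonomy_table(),
                       cells = .default_cells(),
                       effects = .default_effects(),
                       replicates_16s = 3,
                       replicates_rna = 1,
                       depth_rna = 1e4,
                       depth_dna = 1e4,
                       concentration = 500) {
  if (is.null(names(base)) || any(base <= 0))
    stop("base must be a named vector of positive proportions")
  base <- base / sum(base)
  if (depth_rna < 1e3 || depth_dna < 1e3)
    stop("sequencing depths must be at least 1000 reads")
  if (nrow(effects)) {
    bad_t <- setdiff(effects$taxon, names(base))
    if (length(bad_t))
      stop("effect references absent taxon: ", paste(bad_t, collapse = ", "))
    bad_j <- setdiff(effects$treatment, cells$treatment)
    if (length(bad_j))
      stop("effect references absent treatment: ",
           paste(bad_j, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), base = base, taxonomy = taxonomy,
                 cells = cells, effects = effects,
                 replicates_16s = as.integer(replicates_16s),
                 replicates_rna = as.integer(replicates_rna),
                 depth_rna = as.integer(depth_rna),
                 depth_dna = as.integer(depth_dna),
                 concentration = concentration),
            class = "sim_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Simulate a paired metatranscriptomic + 16S microcosm experiment
#'
#' See the package vignette for the generative model. With a fixed seed
#' the output is reproducible draw-for-draw.
#'
#' @param cfg a [sim_config()] object.
#' @return list: `rna` and `dna` count tables, `rna_design` and
#'   `dna_design` sample designs, `truth` (the planted effect table) and
#'   `config`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  taxa <- names(cfg$base)
  k <- length(taxa)
  cells <- cfg$cells
  eff <- cfg$effects

  rna_cols <- list(); dna_cols <- list()
  rna_meta <- list(); dna_meta <- list()
  for (i in seq_len(nrow(cells))) {
    trt <- cells$treatment[i]; ti <- cells$t_index[i]
    adj <- cfg$base
    lvec <- stats::setNames(rep(0, k), taxa)
    if (nrow(eff)) {
      hit <- eff$treatment == trt & ti >= eff$t_min
      for (e in which(hit)) {
        adj[eff$taxon[e]] <- adj[eff$taxon[e]] * eff$fold[e]
        lvec[eff$taxon[e]] <- lvec[eff$taxon[e]] + eff$L[e]
      }
    }
    adj <- adj / sum(adj)
    q <- .rdirichlet1(cfg$concentration * adj)

    for (r in seq_len(cfg$replicates_16s)) {
      id <- sprintf("DNA_%s_t%d_r%d", trt, ti, r)
      dna_cols[[id]] <- stats::rmultinom(1, cfg$depth_dna, q)[, 1]
      dna_meta[[id]] <- data.frame(sample_id = id, treatment = trt,
                                   O = cells$O[i], D = cells$D[i],
                                   N = cells$N[i], t_index = ti,
                                   day = cells$day[i], replicate = r,
                                   stringsAsFactors = FALSE)
    }
    rna_p <- q * 2^lvec
    rna_p <- rna_p / sum(rna_p)
    for (r in seq_len(cfg$replicates_rna)) {
      id <- sprintf("RNA_%s_t%d_r%d", trt, ti, r)
      rna_cols[[id]] <- stats::rmultinom(1, cfg$depth_rna, rna_p)[, 1]
      rna_meta[[id]] <- data.frame(sample_id = id, treatment = trt,
                                   O = cells$O[i], D = cells$D[i],
                                   N = cells$N[i], t_index = ti,
                                   day = cells$day[i], replicate = r,
                                   stringsAsFactors = FALSE)
    }
  }
  rna <- do.call(cbind, rna_cols); rownames(rna) <- taxa
  dna <- do.call(cbind, dna_cols); rownames(dna) <- taxa
  list(rna = rna, dna = dna,
       rna_design = do.call(rbind, c(rna_meta, make.row.names = FALSE)),
       dna_design = do.call(rbind, c(dna_meta, make.row.names = FALSE)),
       truth = eff, config = cfg)
}

#' Simulate a random binary tree over a set of taxa
#'
#' Random rooted binary topology ([ape::rtree()]) with uniform positive
#' branch lengths; the leaves are exactly the given labels.
#'
#' @param taxa character vector of at least two leaf labels.
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(taxa, seed = 1) {
  if (length(taxa) < 2) stop("need at least 2 taxa for a tree")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  set.seed(seed)
  ape::rtree(length(taxa), tip.label = taxa)
}
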