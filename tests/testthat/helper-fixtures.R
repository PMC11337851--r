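# Shared fixtures and independent oracles, built in code at test time.

# --- small fixed taxonomy: one domain, two families, four genera ----------
toy_taxonomy <- function() {
  taxonomy_ref(data.frame(
    label     = c("Bacteria", "Gammaproteobacteria", "Oceanospirillaceae",
                  "Colwelliaceae", "Colwellia", "colwellia_syn",
                  "Bermanella", "Amphritea", "Thalassolituus"),
    canonical = c("Bacteria", "Gammaproteobacteria", "Oceanospirillaceae",
                  "Colwelliaceae", "Colwellia", "Colwellia",
                  "Bermanella", "Amphritea", "Thalassolituus"),
    rank      = c("domain", "class", "family", "family", "genus", "genus",
                  "genus", "genus", "genus"),
    parent    = c("", "Bacteria", "Gammaproteobacteria",
                  "Gammaproteobacteria", "Colwelliaceae", "Colwelliaceae",
                  "Oceanospirillaceae", "Oceanospirillaceae",
                  "Oceanospirillaceae"),
    stringsAsFactors = FALSE))
}

make_table <- function(m, taxa, samples) {
  matrix(m, nrow = length(taxa), dimnames = list(taxa, samples))
}

# --- random taxonomy + table generator for oracle comparisons -------------
# depth <= 4 ranks below the root-most level; <= 10 leaf taxa.
random_taxonomy_and_table <- function(seed) {
  set.seed(seed)
  n_rank <- sample(2:4, 1)
  ranks <- paste0("rank", seq_len(n_rank))
  nodes <- data.frame(label = "Dom1", canonical = "Dom1", rank = ranks[1],
                      parent = "", stringsAsFactors = FALSE)
  level_nodes <- "Dom1"
  for (r in ranks[-1]) {
    kids <- character(0)
    for (p in level_nodes) {
      for (k in seq_len(sample(1:3, 1))) {
        nm <- paste0(p, "_", substr(r, 5, 5), k)
        nodes <- rbind(nodes, data.frame(label = nm, canonical = nm,
                                         rank = r, parent = p,
                                         stringsAsFactors = FALSE))
        kids <- c(kids, nm)
      }
    }
    level_nodes <- kids
  }
  leaves <- nodes$canonical[nodes$rank == ranks[n_rank]]
  leaves <- sample(leaves, min(length(leaves), sample(2:10, 1)))
  n_s <- sample(2:4, 1)
  counts <- matrix(rpois(length(leaves) * n_s, lambda = 20) +
                     rbinom(length(leaves) * n_s, 1, 0.7),
                   nrow = length(leaves),
                   dimnames = list(leaves, paste0("S", seq_len(n_s))))
  for (s in which(colSums(counts) == 0)) counts[1, s] <- 1
  list(ref = taxonomy_ref(nodes), table = counts)
}

# Brute-force merge oracle: for each row, walk the lineage from leaf to
# root and stop at the deepest node whose whole subtree (computed by
# scanning every row) meets the retention rule.
oracle_merge_labels <- function(x, ref, threshold) {
  rel <- sweep(x, 2, colSums(x), "/")
  lins <- lapply(rownames(x), function(l) canonicalize_label(l, ref))
  subtree_ab <- function(node) {
    in_sub <- vapply(lins, function(p) node %in% p, logical(1))
    colSums(rel[in_sub, , drop = FALSE])
  }
  finals <- vapply(seq_len(nrow(x)), function(i) {
    path <- rev(lins[[i]])  # leaf first
    for (node in path) {
      if (node == "Root") return("Root")
      if (max(subtree_ab(node)) >= threshold - 1e-12) return(node)
    }
    "Root"
  }, character(1))
  finals
}

# --- naive MPD / MNTD loops ----------------------------------------------
naive_mpd <- function(x, pat) {
  p <- sweep(x, 2, colSums(x), "/")
  s <- colnames(x)
  out <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (a in s) for (b in s) {
    acc <- 0
    for (i in rownames(x)) for (j in rownames(x))
      acc <- acc + p[i, a] * p[j, b] * pat[i, j]
    out[a, b] <- acc
  }
  out
}

naive_mntd <- function(x, pat) {
  p <- sweep(x, 2, colSums(x), "/")
  s <- colnames(x)
  dir <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (a in s) for (b in s) {
    pres_b <- rownames(x)[p[, b] > 0]
    acc <- 0
    for (i in rownames(x))
      acc <- acc + p[i, a] * min(pat[i, pres_b])
    dir[a, b] <- acc
  }
  (dir + t(dir)) / 2
}

# random tree + abundance table over its leaves
random_phylo_instance <- function(seed) {
  set.seed(seed)
  n_taxa <- sample(2:8, 1)
  taxa <- paste0("t", seq_len(n_taxa))
  tr <- ape::rtree(n_taxa, tip.label = taxa)
  n_s <- sample(2:6, 1)
  x <- matrix(rpois(n_taxa * n_s, 5), nrow = n_taxa,
              dimnames = list(taxa, paste0("S", seq_len(n_s))))
  for (s in seq_len(n_s)) if (sum(x[, s]) == 0) x[sample(n_taxa, 1), s] <- 1
  list(tree = tr, table = x)
}

# design table helper for LRD tests
grid_design <- function(treatments, t_indices, reps = 1, prefix = "S") {
  rows <- expand.grid(replicate = seq_len(reps), t_index = t_indices,
                      treatment = treatments, stringsAsFactors = FALSE)
  fl <- lrdmeta:::.treatment_flags
  i <- match(rows$treatment, fl$treatment)
  data.frame(sample_id = sprintf("%s_%s_t%d_r%d", prefix, rows$treatment,
                                 rows$t_index, rows$replicate),
             treatment = rows$treatment, O = fl$O[i], D = fl$D[i],
             N = fl$N[i], t_index = rows$t_index,
             day = c(0, 7, 17, 28, 42)[rows$t_index + 1],
             replicate = rows$replicate, stringsAsFactors = FALSE)
}
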