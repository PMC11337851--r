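#!/usr/bin/env Rscript
# Step 5 — PERMANOVA of each distance matrix against the factorial model
#
#   U = O + D + O:D + O:D:N + t + O:t + D:t + O:D:t + O:D:N:t
#
# with sequential (Type I) sums of squares, 999 free permutations of the
# sample identities, and time as a categorical factor. O:D:N is aliased
# down to the nutrient contrast (N varies only within CEWAF) and is
# reported with the degrees of freedom that survive.

library(lrdmeta)

rna_design <- read_sample_design("results/data/rna_design.tsv")
b <- build_design(rna_design)

for (flavor in c("bray_curtis", "mpd", "mntd")) {
  d <- read_square_matrix(sprintf("results/dist_%s.tsv", flavor))
  diag(d) <- 0  # self-comparisons (MPD/MNTD may report > 0) are not tested
  d <- d[rna_design$sample_id, rna_design$sample_id]
  fit <- permanova_sequential(d, b$data, b$formula, n_perm = 999,
                              seed = 20260929)
  write.table(fit$table, sprintf("results/permanova_%s.tsv", flavor),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\n==", flavor, "==\n")
  print(fit)
}
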