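# The LRD activity index: replicate averaging, the log2 ratio mean, group
# classification, and its invariances.

two_trt_tables <- function(rvals, dvals, taxa = c("A", "B")) {
  # one treatment (BC), two timepoints, single libraries
  des_r <- grid_design("BC", 0:1, prefix = "R")
  des_d <- grid_design("BC", 0:1, prefix = "D")
  rna <- make_table(rvals, taxa, des_r$sample_id)
  dna <- make_table(dvals, taxa, des_d$sample_id)
  list(rna = rna, dna = dna, des_r = des_r, des_d = des_d)
}

test_that("replicate averaging is the arithmetic mean on the grid", {
  des <- grid_design("BC", 0, reps = 3)
  x <- make_table(c(2, 8, 4, 6, 6, 4), c("A", "B"), des$sample_id)
  # relative abundances per replicate: A = .2/.4/.6
  avg <- average_replicates(x, des)
  expect_equal(unname(avg["A", 1]), 0.4)
  expect_equal(colSums(avg), stats::setNames(1, colnames(avg)),
               tolerance = 1e-9)
  y <- make_table(rep(c(3, 7), 3), c("A", "B"), des$sample_id)
  expect_equal(unname(average_replicates(y, des)[, 1]), c(0.3, 0.7))
  expect_error(average_replicates(x, des[-1, ]), "differ")
})

test_that("LRD equals the mean log2 ratio over timepoints", {
  tt <- two_trt_tables(c(1, 3, 1, 3), c(1, 3, 1, 3))
  l0 <- compute_lrd(tt$rna, tt$dna, tt$des_r, tt$des_d)
  expect_equal(l0$summary$lrd_mean, c(0, 0))       # r = d -> 0

  tt2 <- two_trt_tables(c(2, 3, 2, 3), c(1, 4, 1, 4))
  l2 <- compute_lrd(tt2$rna, tt2$dna, tt2$des_r, tt2$des_d)
  # taxon A: r = 0.4, d = 0.2 at both timepoints -> log2 2 = 1
  expect_equal(l2$summary$lrd_mean[l2$summary$taxon == "A"], 1.0)

  # worked two-timepoint case: r = (0.08, 0.16), d = (0.02, 0.02)
  tt3 <- two_trt_tables(c(8, 92, 16, 84), c(2, 98, 2, 98))
  l3 <- compute_lrd(tt3$rna, tt3$dna, tt3$des_r, tt3$des_d)
  a <- l3$summary[l3$summary$taxon == "A", ]
  expect_equal(a$lrd_mean, mean(c(log2(4), log2(8))))
  expect_equal(a$lrd_mean, 2.5)
  expect_equal(a$n_used, 2L)
})

test_that("swapping rna and dna negates every LRD mean", {
  set.seed(5)
  des_r <- grid_design(c("BC", "WAF"), 0:2, prefix = "R")
  des_d <- grid_design(c("BC", "WAF"), 0:2, reps = 3, prefix = "D")
  taxa <- paste0("tx", 1:6)
  rna <- matrix(rpois(6 * nrow(des_r), 50) + 1, 6,
                dimnames = list(taxa, des_r$sample_id))
  dna <- matrix(rpois(6 * nrow(des_d), 50) + 1, 6,
                dimnames = list(taxa, des_d$sample_id))
  fwd <- compute_lrd(rna, dna, des_r, des_d)$summary
  rev <- compute_lrd(dna, rna, des_d, des_r)$summary
  key <- function(s) s[order(s$taxon, s$treatment), ]
  expect_equal(key(fwd)$lrd_mean, -key(rev)$lrd_mean, tolerance = 1e-12)
})

test_that("LRD is invariant to a common rescaling of the counts", {
  tt <- two_trt_tables(c(5, 15, 10, 10), c(4, 16, 12, 8))
  l1 <- compute_lrd(tt$rna, tt$dna, tt$des_r, tt$des_d)$summary
  l2 <- compute_lrd(tt$rna * 7, tt$dna * 3, tt$des_r, tt$des_d)$summary
  expect_equal(l1$lrd_mean, l2$lrd_mean, tolerance = 1e-12)
})

test_that("group boundaries sit at +/-3.5 with Group II inclusive", {
  g <- classify_lrd_groups(c(3.6, 3.5, 0, -3.5, -3.6))
  expect_equal(as.character(g), c("I", "II", "II", "II", "III"))
  expect_error(classify_lrd_groups(c(1, Inf)), "finite")
})

test_that("zero policies: drop shrinks n_used, pseudocount keeps the row", {
  tt <- two_trt_tables(c(0, 10, 5, 5), c(5, 5, 5, 5))
  ld <- compute_lrd(tt$rna, tt$dna, tt$des_r, tt$des_d, zero_policy = "drop")
  a <- ld$summary[ld$summary$taxon == "A", ]
  expect_equal(a$n_used, 1L)       # t0 dropped for taxon A
  expect_equal(a$lrd_mean, 0)      # t1: r = d = 0.5

  tt2 <- two_trt_tables(c(0, 4, 6, 0, 4, 6), c(5, 2, 3, 5, 2, 3),
                        taxa = c("A", "B", "C"))
  ld2 <- compute_lrd(tt2$rna, tt2$dna, tt2$des_r, tt2$des_d,
                     zero_policy = "drop")
  expect_false("A" %in% ld2$summary$taxon)
  expect_true("A" %in% ld2$skipped$taxon)
  lp <- compute_lrd(tt2$rna, tt2$dna, tt2$des_r, tt2$des_d,
                    zero_policy = "pseudocount")
  expect_true("A" %in% lp$summary$taxon)
  # A's zero RNA side becomes half the table's smallest nonzero fraction
  # (0.2), against a DNA fraction of 0.5
  expect_equal(lp$summary$lrd_mean[lp$summary$taxon == "A"], log2(0.2 / 0.5))
})

test_that("label-set mismatch is reported with the symmetric difference", {
  tt <- two_trt_tables(c(1, 3, 1, 3), c(1, 3, 1, 3))
  dna2 <- tt$dna
  rownames(dna2) <- c("A", "Z")
  expect_error(compute_lrd(tt$rna, dna2, tt$des_r, tt$des_d), "B.*Z|Z.*B")
})

test_that("planted log2 enrichments are recovered at high depth", {
  base <- c(A = 0.30, B = 0.25, C = 0.20, D = 0.12, E = 0.08,
            X = 0.002, Y = 0.002, Z = 0.046)
  cells <- lrdmeta:::.default_cells()
  cells <- cells[cells$treatment %in% c("BC", "DISP"), ]
  eff <- data.frame(taxon = c("X", "Y"), treatment = "DISP",
                    L = c(4, -4), fold = 1, t_min = 0L)
  est <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, base = base, effects = eff, cells = cells,
                      depth_rna = 1e5, depth_dna = 1e5, concentration = 500)
    sim <- simulate_experiment(cfg)
    l <- compute_lrd(sim$rna, sim$dna, sim$rna_design, sim$dna_design)$summary
    c(l$lrd_mean[l$taxon == "X" & l$treatment == "DISP"],
      l$lrd_mean[l$taxon == "Y" & l$treatment == "DISP"],
      l$lrd_mean[l$taxon == "Z" & l$treatment == "DISP"])
  }, numeric(3))
  bias <- rowMeans(est) - c(4, -4, 0)
  expect_lt(max(abs(bias)), 0.1)
})
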