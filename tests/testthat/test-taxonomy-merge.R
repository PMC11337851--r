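# Label canonicalization and abundance-threshold aggregation.

test_that("labels resolve case/whitespace variants and synonyms to one path", {
  ref <- toy_taxonomy()
  p <- canonicalize_label("Colwellia", ref)
  expect_identical(p, c("Root", "Bacteria", "Gammaproteobacteria",
                        "Colwelliaceae", "Colwellia"))
  expect_identical(canonicalize_label(" colwellia ", ref), p)
  expect_identical(canonicalize_label("COLWELLIA_SYN", ref), p)
  expect_error(canonicalize_label("NotARealTaxon", ref,
                                  unknown_policy = "error"),
               "not in taxonomy")
  expect_identical(canonicalize_label("NotARealTaxon", ref,
                                      unknown_policy = "bucket"),
                   c("Root", "Unclassified"))
})

test_that("reference validation rejects orphans and cycles", {
  expect_error(taxonomy_ref(data.frame(
    label = "A", canonical = "A", rank = "genus", parent = "Ghost")),
    "parent not in reference")
  expect_error(taxonomy_ref(data.frame(
    label = c("A", "B"), canonical = c("A", "B"),
    rank = c("family", "genus"), parent = c("B", "A"))),
    "cycle")
})

test_that("low-abundance siblings merge to their family at the threshold", {
  ref <- toy_taxonomy()
  # Bermanella 2% and Amphritea 3% everywhere, under Oceanospirillaceae;
  # Colwellia carries the rest
  x <- make_table(c(2, 3, 95, 2, 3, 95), c("Bermanella", "Amphritea",
                                           "Colwellia"), c("S1", "S2"))
  m <- merge_to_threshold(x, ref, threshold = 0.04)
  expect_setequal(rownames(m$table), c("Oceanospirillaceae", "Colwellia"))
  expect_equal(unname(m$table["Oceanospirillaceae", ]), c(5, 5))
  expect_equal(m$report$mapping$final_label[
    m$report$mapping$raw_label == "Bermanella"], "Oceanospirillaceae")
})

test_that("a taxon over threshold in any one sample keeps its own rank", {
  ref <- toy_taxonomy()
  x <- make_table(c(50, 50, 0, 100), c("Bermanella", "Colwellia"),
                  c("S1", "S2"))
  m <- merge_to_threshold(x, ref, threshold = 0.04)
  expect_true("Bermanella" %in% rownames(m$table))
  expect_equal(unname(m$table["Bermanella", ]), c(50, 0))
})

test_that("uniformly rare taxa under a star taxonomy collapse to the root", {
  stars <- taxonomy_ref(data.frame(
    label = c("Dom", paste0("g", 1:100)),
    canonical = c("Dom", paste0("g", 1:100)),
    rank = c("domain", rep("genus", 100)),
    parent = c("", rep("Dom", 100))))
  x <- matrix(1, 100, 2, dimnames = list(paste0("g", 1:100), c("S1", "S2")))
  m <- merge_to_threshold(x, stars, threshold = 0.04)
  # 1% each: no genus reaches 4%, but the domain subtree holds 100%
  expect_identical(rownames(m$table), "Dom")
  expect_equal(unname(m$table[1, ]), c(100, 100))
})

test_that("merge conserves per-sample totals exactly and is idempotent", {
  for (seed in 1:25) {
    inst <- random_taxonomy_and_table(seed)
    thr <- sample(c(0.02, 0.05, 0.1, 0.2), 1)
    m <- merge_to_threshold(inst$table, inst$ref, threshold = thr)
    expect_identical(colSums(m$table), colSums(inst$table))
    expect_true(all(m$table == round(m$table)))
    m2 <- merge_to_threshold(m$table, inst$ref, threshold = thr)
    expect_identical(m2$table, m$table)
  }
})

test_that("raising the threshold never increases the number of labels", {
  for (seed in 26:40) {
    inst <- random_taxonomy_and_table(seed)
    sizes <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(thr)
      nrow(merge_to_threshold(inst$table, inst$ref, threshold = thr)$table),
      numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("merge matches the brute-force ancestor-walk oracle", {
  for (seed in 41:80) {
    inst <- random_taxonomy_and_table(seed)
    thr <- sample(seq(0.02, 0.2, by = 0.02), 1)
    m <- merge_to_threshold(inst$table, inst$ref, threshold = thr)
    finals <- oracle_merge_labels(inst$table, inst$ref, thr)
    expect_setequal(rownames(m$table), unique(finals))
    oracle_tab <- rowsum(inst$table, finals)
    expect_equal(m$table[rownames(oracle_tab), , drop = FALSE],
                 oracle_tab, ignore_attr = TRUE)
  }
})

test_that("per-sample retention aggregates each sample by its own mapping", {
  ref <- toy_taxonomy()
  # Bermanella passes 4% only in S1; under per_sample its S2 mass merges up
  x <- make_table(c(10, 90, 2, 98), c("Bermanella", "Colwellia"),
                  c("S1", "S2"))
  m <- merge_to_threshold(x, ref, threshold = 0.04,
                          retention_rule = "per_sample")
  expect_equal(colSums(m$table), colSums(x))
  expect_equal(unname(m$table["Bermanella", "S1"]), 10)
  expect_equal(unname(m$table["Bermanella", "S2"]), 0)
  # in S2 the walk passes the 2% family and stops at the class (100%)
  expect_equal(unname(m$table["Gammaproteobacteria", "S2"]), 2)
})

test_that("unknown labels bucket under Unclassified and can still merge", {
  ref <- toy_taxonomy()
  x <- make_table(c(2, 98, 2, 98), c("Mystery", "Colwellia"),
                  c("S1", "S2"))
  m <- merge_to_threshold(x, ref, threshold = 0.04)
  expect_setequal(rownames(m$table), c("Root", "Colwellia"))
  m2 <- merge_to_threshold(x, ref, threshold = 0.01)
  expect_true("Unclassified" %in% rownames(m2$table))
})
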