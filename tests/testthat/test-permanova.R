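# Sequential-SS PERMANOVA: design construction, algebraic identities,
# permutation p-values, and calibration under the null.

euclid <- function(y) {
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("s", seq_len(nrow(d))),
                      paste0("s", seq_len(nrow(d))))
  d
}

test_that("design construction encodes the treatment flags and time factor", {
  des <- grid_design(c("BC", "CEWAFN"), c(0, 1))
  b <- build_design(des)
  expect_identical(attr(stats::terms(b$formula, keep.order = TRUE),
                        "term.labels"),
                   c("O", "D", "O:D", "O:D:N", "t", "O:t", "D:t", "O:D:t",
                     "O:D:N:t"))
  cewafn <- des$treatment == "CEWAFN"
  expect_true(all(b$data$O[cewafn] == "1" & b$data$D[cewafn] == "1" &
                    b$data$N[cewafn] == "1"))
  bc <- des$treatment == "BC"
  expect_true(all(b$data$O[bc] == "0" & b$data$D[bc] == "0" &
                    b$data$N[bc] == "0"))
  expect_true(is.factor(b$data$t))
  # two timepoints -> 1 df for t
  set.seed(20)
  g <- euclid(rnorm(nrow(des)))
  dimnames(g) <- list(des$sample_id, des$sample_id)
  fit <- permanova_sequential(g, b$data, b$formula, n_perm = 9, seed = 1)
  expect_equal(fit$table$df[fit$table$term == "t"], 1)
  expect_error(treatment_label(1, 0, 1), "no treatment")
})

test_that("pseudo-F on Euclidean distances equals the classical ANOVA F", {
  set.seed(21)
  g <- factor(rep(c("a", "b", "c"), times = c(7, 6, 8)))
  y <- rnorm(length(g), mean = as.integer(g))
  fit <- permanova_sequential(euclid(y), data.frame(g = g), ~ g,
                              n_perm = 9, seed = 1)
  f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(fit$table$pseudo_F[1], f_classic, tolerance = 1e-9)
  expect_equal(fit$table$df[1:2], c(2, length(y) - 3))
})

test_that("sequential SS decomposes the total (Gower identity)", {
  set.seed(22)
  des <- grid_design(c("BC", "DISP", "WAF", "CEWAF", "CEWAFN"), 0:1,
                     reps = 2)
  y <- matrix(rnorm(nrow(des) * 3), ncol = 3)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(des$sample_id, des$sample_id)
  b <- build_design(des)
  fit <- permanova_sequential(d, b$data, b$formula, n_perm = 19, seed = 2)
  tb <- fit$table
  ss_total <- tb$SS[tb$term == "Total"]
  expect_equal(sum(tb$SS[!(tb$term %in% "Total")]), ss_total,
               tolerance = 1e-9)
  expect_equal(ss_total, sum(d^2) / (2 * nrow(d)), tolerance = 1e-9)
  expect_true(all(tb$R2[tb$df > 0] >= -1e-12 & tb$R2[tb$df > 0] <= 1 + 1e-12))
  expect_equal(sum(tb$df), 2 * (nrow(d) - 1))  # terms+resid and total
})

test_that("results agree with vegan's adonis2 on a generic design", {
  set.seed(23)
  n <- 24
  data <- data.frame(g = factor(rep(c("a", "b"), each = n / 2)),
                     h = factor(rep(c("x", "y", "z"), times = n / 3)))
  y <- matrix(rnorm(n * 4), ncol = 4)
  y[data$g == "b", 1] <- y[data$g == "b", 1] + 1.5
  d <- as.matrix(dist(y)); dimnames(d) <- list(NULL, NULL)
  fit <- permanova_sequential(d, data, ~ g + h + g:h, n_perm = 99, seed = 3)
  ref <- vegan::adonis2(as.dist(d) ~ g + h + g:h, data = data,
                        permutations = 99, by = "terms")
  expect_equal(fit$table$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(fit$table$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(fit$table$df[1:4], ref$Df[1:4])
})

test_that("complete separation attains the minimum p of 1/(n_perm+1)", {
  set.seed(24)
  g <- factor(rep(c("a", "b"), each = 10))
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
  fit <- permanova_sequential(euclid(y), data.frame(g = g), ~ g,
                              n_perm = 999, seed = 4)
  expect_equal(fit$table$p_value[1], 1 / 1000)
})

test_that("aliased terms get 0 df and no test, without crashing", {
  # no CEWAFN samples: N is constant, so O:D:N and O:D:N:t are untestable
  des <- grid_design(c("BC", "DISP", "WAF", "CEWAF"), 0:1, reps = 2)
  set.seed(25)
  y <- rnorm(nrow(des))
  d <- euclid(y); dimnames(d) <- list(des$sample_id, des$sample_id)
  b <- build_design(des)
  fit <- permanova_sequential(d, b$data, b$formula, n_perm = 19, seed = 5)
  tb <- fit$table
  expect_equal(tb$df[tb$term == "O:D:N"], 0)
  expect_true(is.na(tb$p_value[tb$term == "O:D:N"]))
  expect_setequal(fit$aliased, c("O:D:N", "O:D:N:t"))
  # with CEWAFN present, O:D:N carries the 1 df that N contributes
  des2 <- grid_design(c("BC", "DISP", "WAF", "CEWAF", "CEWAFN"), 0:1,
                      reps = 2)
  set.seed(26)
  d2 <- euclid(rnorm(nrow(des2)))
  dimnames(d2) <- list(des2$sample_id, des2$sample_id)
  b2 <- build_design(des2)
  fit2 <- permanova_sequential(d2, b2$data, b2$formula, n_perm = 19,
                               seed = 6)
  expect_equal(fit2$table$df[fit2$table$term == "O:D:N"], 1)
})

test_that("fixed seed reproduces p-values; total SS is permutation-invariant", {
  set.seed(27)
  g <- factor(rep(c("a", "b"), each = 8))
  y <- rnorm(16, as.integer(g) / 2)
  d <- euclid(y)
  f1 <- permanova_sequential(d, data.frame(g = g), ~ g, n_perm = 99,
                             seed = 11)
  f2 <- permanova_sequential(d, data.frame(g = g), ~ g, n_perm = 99,
                             seed = 11)
  expect_identical(f1$table, f2$table)
  prm <- sample(16)
  f3 <- permanova_sequential(d[prm, prm], data.frame(g = g[prm]), ~ g,
                             n_perm = 9, seed = 1)
  expect_equal(f3$table$SS[f3$table$term == "Total"],
               f1$table$SS[f1$table$term == "Total"], tolerance = 1e-9)
})

test_that("type-I error under the null sits at the nominal level", {
  n <- 20
  g <- factor(rep(c("a", "b"), each = n / 2))
  rej <- vapply(1:500, function(s) {
    set.seed(1000 + s)
    y <- rnorm(n)
    fit <- permanova_sequential(euclid(y), data.frame(g = g), ~ g,
                                n_perm = 199, seed = 2000 + s)
    fit$table$p_value[1] <= 0.05
  }, logical(1))
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
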