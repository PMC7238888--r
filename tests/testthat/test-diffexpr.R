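test_that("identical groups give null DE results", {
  set.seed(3)
  base <- matrix(rnbinom(50 * 4, mu = 200, size = 10), 50, 4)
  m <- toy_counts(cbind(base, base), 50, 8)
  s <- toy_samples(rep(c("Control", "Hot"), each = 4))
  d <- de_test(m, s, "Control", "Hot", method = "nb_exact", min_cpm = 0)
  expect_true(all(d$p > 1 - 1e-6))
  expect_true(all(d$log2fc == 0))
  expect_true(all(d$direction == "ns"))
})

test_that("nb_exact with dispersion 0 reduces to the conditional binomial tail", {
  # A-group counts all 10, B-group all 30, equal library sizes via balanced
  # filler genes; per-gene conditional p must equal the two-sided binomial
  # tail Pr(|X - 20| >= 10), X ~ Bin(40, 1/2)
  g1 <- c(4L, 3L, 3L, 10L, 10L, 10L)          # group sums 10 and 30
  balancer <- 810L - g1                        # keeps every library equal
  flat <- matrix(700L, 20, 6)                  # constant genes pin TMM at 1
  m <- toy_counts(rbind(g1, balancer, flat), 22, 6)
  stopifnot(length(unique(colSums(m))) == 1)   # equal library sizes
  s <- toy_samples(rep(c("Control", "Hot"), each = 3))
  d <- de_test(m, s, "Control", "Hot", method = "nb_exact", min_cpm = 0)
  oracle <- sum(dbinom(0:40, 40, 0.5)[abs(0:40 - 20) >= 10])
  phat <- d$p[d$gene == "g001"]
  expect_equal(phat, oracle, tolerance = 1e-8)
})

test_that("welch caller agrees with stats::t.test gene by gene", {
  set.seed(11)
  m <- toy_counts(matrix(rnbinom(30 * 10, mu = 150, size = 5), 30, 10))
  s <- toy_samples(rep(c("Control", "Dry"), each = 5))
  d <- de_test(m, s, "Control", "Dry", min_cpm = 0)
  lc <- cpm(m[d$gene, ], tmm_factors(m[d$gene, ]), log2 = TRUE)$values
  for (i in c(1, 7, 19)) {
    ref <- t.test(lc[i, 6:10], lc[i, 1:5])
    expect_equal(d$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(d$statistic[i], unname(ref$statistic), tolerance = 1e-10)
  }
  expect_true(all(d$direction[d$q <= 0.05] ==
                    ifelse(d$log2fc[d$q <= 0.05] > 0, "up", "down")))
})

test_that("DE power: strong responsive genes are recovered at 5% FDR", {
  cfg <- sim_config(n_families = 15, n_per_family_condition = 3, n_genes = 600,
                    frac_responsive = 0.5, effect_size_logfc = 2,
                    nb_dispersion = 0.05, seed = 17)
  ds <- simulate_dataset(cfg)
  d <- de_test(ds$counts, ds$samples, "Control", "Hot")
  tr <- ds$truth
  hot_resp <- tr$archetype$gene[tr$condition_logfc[, "Hot"] != 0]
  hot_resp <- intersect(hot_resp, d$gene)
  hit <- d$gene[d$direction != "ns"]
  expect_gt(mean(hot_resp %in% hit), 0.9)
  # realized FDR among discoveries stays controlled
  null_genes <- tr$archetype$gene[tr$condition_logfc[, "Hot"] == 0]
  fdr <- mean(hit %in% null_genes)
  expect_lt(fdr, 0.05 + 3 * sqrt(0.05 * 0.95 / max(length(hit), 1)))
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  # hand oracle on an unsorted vector
  p <- c(0.04, 0.001, 0.9, 0.02)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(sort(p) * 4 / seq_len(4)))))
  expect_equal(bh_adjust(p)[o], q_sorted)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("DE-count permutation: null symmetric treatments are not significant", {
  cfg <- sim_config(n_families = 8, n_per_family_condition = 2, n_genes = 300,
                    frac_responsive = 0, seed = 23)
  ds <- simulate_dataset(cfg)
  r <- de_count_permutation(ds$counts, ds$samples, "Dry", "Hot",
                            n_perm = 60, seed = 5)
  expect_gt(r$p, 0.05)
  expect_error(de_count_permutation(ds$counts, ds$samples, "Dry", "Hot",
                                    n_perm = 0), "n_perm")
})

test_that("DE-count permutation detects a one-sided true response", {
  # Hot responds strongly, Dry not at all: the observed |difference in DE
  # counts| should be extreme among permutations
  cfg <- sim_config(n_families = 8, n_per_family_condition = 3, n_genes = 400,
                    frac_responsive = 0.5, effect_size_logfc = 2,
                    archetype_mixture = c(independent = 1), seed = 29)
  ds <- simulate_dataset(cfg)
  r <- de_count_permutation(ds$counts, ds$samples, "Dry", "Hot",
                            n_perm = 40, seed = 6)
  expect_lte(r$p, 2 / 41)
})

test_that("magnitude permutation: trivial and exhaustive cases", {
  r_same <- magnitude_permutation(rep(1.5, 6), rep(1.5, 6), n_perm = 50,
                                  seed = 1)
  expect_gt(r_same$p, 0.9)

  r_ext <- magnitude_permutation(c(0, 0, 0), c(5, 5, 5), exact = TRUE)
  expect_equal(r_ext$p, 2 / choose(6, 3))  # minimum attainable two-sided

  set.seed(8)
  a <- runif(4); b <- runif(4) + 0.3
  r <- magnitude_permutation(a, b, exact = TRUE)
  oracle <- exhaustive_perm_p(b, a, function(x, y) mean(x) - mean(y))
  expect_equal(r$p, oracle)

  # Monte-Carlo agrees with exhaustive within sampling error
  r_mc <- magnitude_permutation(a, b, n_perm = 4000, seed = 2)
  expect_lt(abs(r_mc$p - oracle), 3 * sqrt(oracle * (1 - oracle) / 4000) + 1e-3)

  expect_error(magnitude_permutation(numeric(0), 1), "non-empty")
})

test_that("magnitude permutation detects a mean shift at scale", {
  set.seed(13)
  a <- abs(rnorm(2000, 0, 0.5))
  b <- abs(rnorm(2000, 0, 0.5)) + 0.2
  r <- magnitude_permutation(a, b, n_perm = 400, seed = 3)
  expect_lt(r$p, 0.05)
})

test_that("overlap test matches a hand-computed 2x2 chi-square", {
  u <- 100
  s1 <- sprintf("g%03d", 1:20)
  s2 <- sprintf("g%03d", 11:40)   # overlap 10
  r <- overlap_test(s1, s2, u)
  tab <- matrix(c(10, 10, 20, 60), 2, 2)
  e <- outer(rowSums(tab), colSums(tab)) / 100
  oracle <- sum((tab - e)^2 / e)
  expect_equal(r$chisq, oracle, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_equal(r$overlap, 10L)

  dir1 <- setNames(rep(c("up", "down"), 10), s1)
  dir2 <- setNames(rep("up", 30), s2)
  r2 <- overlap_test(s1, s2, u, dir1, dir2)
  expect_equal(r2$same_direction + r2$opposite_direction, 10L)

  # disjoint sets covering the universe: maximal negative association
  r3 <- overlap_test(sprintf("g%d", 1:5), sprintf("g%d", 6:10), 10)
  expect_equal(r3$overlap, 0L)
  expect_error(overlap_test(s1, s2, 10), "universe")
})
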