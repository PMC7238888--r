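test_that("design arithmetic: every family appears in all four conditions", {
  cfg <- sim_config(n_families = 10, n_per_family_condition = 1, n_genes = 0,
                    seed = 1)
  d <- simulate_design(cfg)
  expect_equal(nrow(d), 40L)
  tab <- table(d$family_f, d$condition)
  expect_true(all(tab == 1L))
  expect_equal(anyDuplicated(d$sample_id), 0L)

  expect_error(sim_config(n_families = 1), "n_families")
  expect_error(sim_config(n_per_family_condition = 0), "n_families|condition")
})

test_that("reproduction flags follow the configured probabilities", {
  cfg_all <- sim_config(n_families = 4, n_per_family_condition = 2,
                        n_genes = 0,
                        repro_prob = c(Control = 1, Dry = 1, Hot = 1,
                                       `Hot-Dry` = 1), seed = 2)
  expect_true(all(simulate_design(cfg_all)$reproduced))

  # published per-condition reproduction fractions, full assay size
  cfg <- sim_config(n_fitness_only = 1500, seed = 3)
  d <- simulate_fitness_assay(cfg)
  for (cc in conditions()) {
    p_hat <- mean(d$reproduced[d$condition == cc])
    p <- cfg$repro_prob[cc]
    se <- sqrt(p * (1 - p) / sum(d$condition == cc))
    expect_lt(abs(p_hat - p), 3 * se + 1e-12)
  }
})

test_that("archetype profiles print the right condition fold changes", {
  cfg <- tiny_config(frac_responsive = 1, n_genes = 60, effect_size_logfc = 1.5)
  out <- simulate_counts(simulate_design(cfg), cfg)
  tr <- out$truth
  # an independent-(H,HD,up) gene must carry profile (0, 0, +d, +d)
  idx <- which(tr$archetype$profile == "independent_CT0_D+0_H+1_HD+1")
  expect_gt(length(idx), 0L)
  expect_equal(unname(tr$condition_logfc[idx[1], ]), c(0, 0, 1.5, 1.5))
  # non-responsive genes have all-zero condition effects
  cfg0 <- tiny_config(frac_responsive = 0)
  tr0 <- simulate_counts(simulate_design(cfg0), cfg0)$truth
  expect_true(all(tr0$condition_logfc == 0))
  # unknown category is rejected
  expect_error(tiny_config(archetype_mixture = c(bogus = 1)), "bogus")
})

test_that("condition-mean log-CPM of responsive genes shifts by the profile effect", {
  cfg <- sim_config(n_families = 30, n_per_family_condition = 3, n_genes = 200,
                    frac_responsive = 1, effect_size_logfc = 2,
                    nb_dispersion = 0.01, family_sd = 0.05,
                    plasticity_family_sd = 0.02, seed = 9)
  ds <- simulate_dataset(cfg)
  # compare depth-normalized count means directly (all genes responsive, so
  # composition normalization like TMM is not meaningful here)
  rate <- sweep(ds$counts, 2, colSums(ds$counts), "/")
  cond <- as.character(ds$samples$condition)
  up_h <- which(ds$truth$archetype$profile == "independent_CT0_D+0_H+1_HD+1")
  lmean <- function(cc) log2(rowMeans(rate[up_h, cond == cc, drop = FALSE]))
  shift_h <- mean(lmean("Hot") - lmean("Control"))
  shift_d <- mean(lmean("Dry") - lmean("Control"))
  # the Hot shift is Delta up to the common composition offset; the Dry
  # shift isolates that offset
  expect_equal(shift_h - shift_d, 2, tolerance = 0.15)
})

test_that("Poisson limit: dispersion 0 without family effects gives variance ~ mean", {
  cfg <- sim_config(n_families = 25, n_per_family_condition = 4, n_genes = 300,
                    frac_responsive = 0, nb_dispersion = 0,
                    family_sd = 0, plasticity_family_sd = 0,
                    lib_size_spread = 0, seed = 5)
  out <- simulate_counts(simulate_design(cfg), cfg)
  y <- out$counts
  m <- rowMeans(y)
  v <- apply(y, 1, var)
  ratio <- v / m
  # mean variance/mean ratio within Monte-Carlo error of 1
  n <- ncol(y)
  mc_se <- sd(ratio) / sqrt(nrow(y))
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se)
})

test_that("fitness generator: exact means without noise, calibrated means with", {
  cfg <- sim_config(n_families = 50, n_per_family_condition = 2, n_genes = 0,
                    fitness_family_sd = 0,
                    fitness_total_sd = c(Control = 1e-6, Dry = 1e-6,
                                         Hot = 1e-6, `Hot-Dry` = 1e-6),
                    repro_prob = c(Control = 1, Dry = 1, Hot = 1,
                                   `Hot-Dry` = 1),
                    seed = 4)
  d <- simulate_fitness(simulate_design(cfg), NULL, cfg)
  for (cc in conditions()) {
    expect_equal(mean(d$offspring[d$condition == cc]),
                 round(cfg$fitness_means[[cc]]), tolerance = 1e-9)
  }
})

test_that("single-gene selection: regression on z recovers the generating gradient", {
  # one gene with beta* = 0.3 through the literal sum channel
  n_fam <- 400
  cfg <- sim_config(n_families = n_fam, n_per_family_condition = 1,
                    n_genes = 1, frac_responsive = 0,
                    fitness_family_sd = 0, seed = 12)
  d <- simulate_design(cfg)
  set.seed(77)
  z <- matrix(rnorm(nrow(d)), 1, nrow(d),
              dimnames = list("g1", d$sample_id))
  for (cc in conditions()) {   # standardize within condition
    j <- as.character(d$condition) == cc
    z[1, j] <- (z[1, j] - mean(z[1, j])) / sd(z[1, j])
  }
  truth <- list(gradients = matrix(0.3, 1, 4,
                                   dimnames = list("g1", conditions())),
                fitness_channel = "sum")
  d2 <- simulate_fitness(d, z, cfg, truth = truth)
  keep <- d2$condition == "Control" & d2$offspring > 0
  w <- relative_fitness(d2$offspring[keep])
  fit <- lm(w ~ z[1, keep])
  est <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(est - 0.3), 3 * se)
})

test_that("same seed regenerates the dataset bit-identically", {
  a <- tiny_dataset(seed = 31)
  b <- tiny_dataset(seed = 31)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$condition_logfc, b$truth$condition_logfc)
  c <- tiny_dataset(seed = 32)
  expect_false(identical(a$counts, c$counts))
})

test_that("null generator is null: no DE discoveries, centred gradients", {
  cfg <- sim_config(n_families = 10, n_per_family_condition = 2, n_genes = 500,
                    frac_responsive = 0, seed = 21)
  ds <- simulate_dataset(cfg)
  de <- de_test(ds$counts, ds$samples, "Control", "Hot")
  expect_lt(sum(de$direction != "ns"), 0.01 * nrow(de) + 3)
  norm <- cpm(ds$counts, tmm_factors(ds$counts))
  keep <- ds$samples$sample_id[ds$samples$condition == "Control" &
                                 ds$samples$offspring > 0]
  z <- zscore_by_gene(norm, ds$samples, "Control", subset = keep)
  w <- relative_fitness(
    ds$samples$offspring[match(colnames(z$values), ds$samples$sample_id)])
  sg <- selection_gradients(z, w, "Control")
  expect_lt(abs(mean(sg$beta)), 3 * sd(sg$beta) / sqrt(nrow(sg)))
  expect_lt(sum(sg$q <= 0.05), 0.01 * nrow(sg) + 3)
})

test_that("cross-condition gradient correlations are attenuated at small n and approach truth as n grows", {
  st <- selection_truth(fitness_channel = "latent")
  r_at <- function(fams, per, genes, seed) {
    cfg <- sim_config(n_families = fams, n_per_family_condition = per,
                      n_genes = genes, frac_responsive = 0,
                      selection_truth = st, seed = seed)
    ds <- simulate_dataset(cfg)
    norm <- cpm(ds$counts, tmm_factors(ds$counts))
    sel <- list()
    for (cc in c("Hot", "Hot-Dry")) {
      keep <- ds$samples$sample_id[ds$samples$condition == cc &
                                     ds$samples$offspring > 0]
      z <- zscore_by_gene(norm, ds$samples, cc, subset = keep)
      w <- relative_fitness(
        ds$samples$offspring[match(colnames(z$values), ds$samples$sample_id)])
      sel[[cc]] <- selection_gradients(z, w, cc)
    }
    cross_condition_correlation(sel$Hot, sel$`Hot-Dry`)$r
  }
  r_small <- r_at(12, 4, 400, 61)   # ~45 females/condition
  r_large <- r_at(100, 4, 400, 62)  # 400 females/condition
  rho <- st$gradient_corr["Hot", "Hot-Dry"]
  expect_lt(r_small, rho)           # attenuation toward zero
  expect_gt(r_large, r_small)       # monotone approach
  expect_lt(abs(r_large - rho), 0.12)
})
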