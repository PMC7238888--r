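test_that("relative fitness normalizes to mean one", {
  expect_equal(relative_fitness(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(relative_fitness(rep(7, 5)), rep(1, 5))
  set.seed(1)
  w <- rpois(50, 30)
  expect_equal(mean(relative_fitness(w)), 1, tolerance = 1e-12)
  expect_error(relative_fitness(rep(0, 3)), "positive mean")
})

test_that("selection gradients equal the normal-equations solution and the covariance identity", {
  z4 <- matrix(c(-1.161, -0.387, 0.387, 1.161), 1, 4,
               dimnames = list("g1", paste0("s", 1:4)))
  z4 <- z4 / sd(z4)                      # unit SD predictor
  w <- c(0.8, 0.9, 1.1, 1.2)
  r <- selection_gradients(z4, w, "Control")
  # independent least-squares oracle
  oracle <- unname(coef(lm(w ~ z4[1, ]))[2])
  expect_equal(r$beta, oracle, tolerance = 1e-10)
  expect_equal(r$se, summary(lm(w ~ z4[1, ]))$coefficients[2, 2],
               tolerance = 1e-10)
  # beta = cov(w', z) when the predictor is standardized
  expect_equal(r$beta, cov(w, z4[1, ]), tolerance = 1e-10)

  # orthogonal predictor gives beta = 0
  z0 <- matrix(c(-1, 1, -1, 1), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  z0 <- z0 / sd(z0)
  w0 <- c(1.1, 1.1, 0.9, 0.9)
  expect_lt(abs(selection_gradients(z0, w0, "Control")$beta), 1e-10)
})

test_that("beta = cov(w', z) identity holds across a simulated dataset", {
  ds <- tiny_dataset(seed = 55)
  norm <- cpm(ds$counts, tmm_factors(ds$counts))
  keep <- ds$samples$sample_id[ds$samples$condition == "Dry" &
                                 ds$samples$offspring > 0]
  z <- zscore_by_gene(norm, ds$samples, "Dry", subset = keep)
  w <- relative_fitness(
    ds$samples$offspring[match(colnames(z$values), ds$samples$sample_id)])
  r <- selection_gradients(z, w, "Dry")
  covs <- apply(z$values, 1, function(zz) cov(w, zz))
  expect_equal(r$beta, unname(covs[r$gene]), tolerance = 1e-8)
  # and equivalently beta = cor(w', z) * sd(w')
  cors <- apply(z$values, 1, function(zz) cor(w, zz))
  expect_equal(r$beta, unname(cors[r$gene]) * sd(w), tolerance = 1e-8)
  expect_error(selection_gradients(z, w[-1], "Dry"), "match")
})

test_that("selection summaries report medians, signs and Kruskal-Wallis", {
  mk <- function(betas, cond) {
    structure(data.frame(gene = paste0("g", seq_along(betas)), beta = betas,
                         se = 0.1, p = 0.5, q = 0.5),
              class = c("selection_result", "data.frame"),
              condition = cond, n = 10L)
  }
  s1 <- selection_summary(mk(c(-1, 0, 1), "Control"))
  expect_equal(s1$median_abs_beta, 1)
  s2 <- selection_summary(mk(c(-0.2, -0.4, -0.1), "Dry"))
  expect_equal(s2$prop_negative, 1)
  both <- selection_summary(list(mk(rnorm(30), "Control"),
                                 mk(rnorm(30, 0.5), "Hot")))
  expect_s3_class(attr(both, "kruskal"), "htest")
  expect_equal(attr(both, "kruskal")$parameter[["df"]], 1)
})

test_that("cross-condition correlation: identity, sign flip, Fisher CI", {
  mk <- function(betas, cond) {
    structure(data.frame(gene = paste0("g", seq_along(betas)), beta = betas,
                         se = 0.1, p = 0.5, q = 0.5),
              class = c("selection_result", "data.frame"),
              condition = cond, n = 10L)
  }
  set.seed(3)
  b <- rnorm(50)
  a <- mk(b, "Control")
  expect_equal(cross_condition_correlation(a, mk(b, "Dry"))$r, 1)
  expect_equal(cross_condition_correlation(a, mk(-b, "Dry"))$r, -1)
  r <- cross_condition_correlation(a, mk(b + rnorm(50), "Hot"))
  z <- atanh(r$r)
  expect_equal(r$ci,
               tanh(z + qnorm(c(0.025, 0.975)) / sqrt(50 - 3)),
               tolerance = 1e-12)
  expect_error(cross_condition_correlation(mk(1:2, "a"), mk(1:2, "b")),
               "3 shared")
})

test_that("sign-switch analysis counts switchers and their direction", {
  mk <- function(betas, cond) {
    structure(data.frame(gene = paste0("g", seq_along(betas)), beta = betas,
                         se = 0.1, p = 0.5, q = 0.5),
              class = c("selection_result", "data.frame"),
              condition = cond, n = 10L)
  }
  same <- sign_switch_analysis(mk(c(-1, 2, 3), "Control"), mk(c(-1, 2, 3), "Hot"))
  expect_equal(same$n_switching, 0L)
  flip <- sign_switch_analysis(mk(rep(-0.1, 5), "Control"),
                               mk(rep(0.1, 5), "Hot"))
  expect_equal(flip$n_switching, 5L)
  expect_equal(flip$prop_neg_to_pos, 1)
  expect_equal(flip$median_abs_delta, 0.2)
})

test_that("DE-selection shift test: exhaustive agreement and power", {
  mk_sel <- function(betas) {
    structure(data.frame(gene = paste0("g", seq_along(betas)), beta = betas,
                         se = 0.1, p = 0.5, q = 0.5),
              class = c("selection_result", "data.frame"),
              condition = "Hot", n = 10L)
  }
  mk_de <- function(dirs) {
    structure(data.frame(gene = paste0("g", seq_along(dirs)),
                         log2fc = ifelse(dirs == "up", 1,
                                         ifelse(dirs == "down", -1, 0)),
                         statistic = 0, p = 0.5,
                         q = ifelse(dirs == "ns", 0.9, 0.01),
                         direction = dirs),
              class = c("de_result", "data.frame"),
              contrast = "Hot vs Control", method = "welch_logcpm",
              alpha = 0.05)
  }
  # 6-gene instance: exhaustive enumeration against the independent oracle
  betas <- c(0.30, 0.25, -0.05, 0.00, 0.10, -0.10)
  dirs <- c("up", "up", "ns", "ns", "ns", "ns")
  r <- de_selection_shift_test(mk_sel(betas), mk_de(dirs), "up", exact = TRUE)
  oracle <- exhaustive_perm_p(betas[1:2], betas[3:6],
                              function(g, ns) mean(g) - mean(ns),
                              two_sided = FALSE)
  expect_equal(r$p, oracle)
  expect_equal(r$delta_mean, mean(betas[1:2]) - mean(betas[3:6]))

  # a +0.1 shift of the up-group over many genes is detected
  set.seed(9)
  b2 <- c(rnorm(300, 0.1, 0.05), rnorm(3000, 0, 0.05))
  d2 <- c(rep("up", 300), rep("ns", 3000))
  r2 <- de_selection_shift_test(mk_sel(b2), mk_de(d2), "up", n_perm = 500,
                                seed = 4)
  expect_lt(r2$p, 0.01)

  # identically distributed groups: no systematic rejection
  set.seed(10)
  b3 <- rnorm(200, 0, 0.05)
  d3 <- c(rep("down", 40), rep("ns", 160))
  r3 <- de_selection_shift_test(mk_sel(b3), mk_de(d3), "down", n_perm = 300,
                                seed = 5)
  expect_gt(r3$p, 0.01)
  expect_error(de_selection_shift_test(mk_sel(b3), mk_de(rep("ns", 200)),
                                       "up"), "up")
})
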