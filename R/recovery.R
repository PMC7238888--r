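# Parameter-recovery experiments: each function simulates a dataset under
# the generator's calibrated conditions, runs the corresponding analysis
# stage end to end, and returns the estimates next to the generating truth.
# They are what the acceptance machinery runs, and double as worked
# examples of the full pipeline.

#' Fitness-assay recovery experiment
#'
#' Simulates the full-scale fitness assay (about 1500 females per
#' condition, defaults calibrated to the published reproducing-female means
#' and variances), fits the 2x2 factorial model on reproducing females and
#' summarizes per-condition fitness.
#'
#' @param seed integer seed.
#' @param n_per_condition assay females per condition.
#' @param n_boot bootstrap replicates for the factorial SEs.
#' @return list: `fit` ([factorial_fit()]), `summary`
#'   ([summarize_fitness()]), `samples`.
#' @export
fitness_assay_recovery <- function(seed = 1, n_per_condition = 1500,
                                   n_boot = 200) {
  cfg <- sim_config(n_fitness_only = n_per_condition, seed = seed)
  samples <- simulate_fitness_assay(cfg)
  list(fit = factorial_fit(samples, n_boot = n_boot, seed = seed + 1L),
       summary = summarize_fitness(samples),
       samples = samples)
}

#' Cross-environment selection-correlation recovery experiment
#'
#' Simulates expression and fitness for a large split-family cohort whose
#' true per-gene selection structure follows the latent-quality model with
#' the published cross-environment gradient correlations as generating
#' truth, estimates per-condition selection intensities with the standard
#' chain (TMM -> CPM -> within-condition z-scores over reproducing females
#' -> per-gene regression), and reports all pairwise correlations of the
#' estimates. The default cohort (500 families x 2 females per condition =
#' 1000 individuals per condition, 2000 genes) together with the gradient
#' scale (net SD 0.12, in line with the published per-condition medians of
#' |beta|) keeps estimation attenuation of the correlations below a few
#' percent.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param n_families number of families.
#' @param n_per_family_condition females per family and condition.
#' @return list: `selection` (per-condition `selection_result`s),
#'   `correlations` (data.frame of pairwise r), `truth` (generating
#'   correlation matrix).
#' @export
gradient_correlation_recovery <- function(seed = 1, n_genes = 2000,
                                          n_families = 500,
                                          n_per_family_condition = 2) {
  st <- selection_truth(quality_sd = 0.3, net_gradient_sd = 0.12,
                        fitness_channel = "latent")
  cfg <- sim_config(n_families = n_families,
                    n_per_family_condition = n_per_family_condition,
                    n_genes = n_genes, frac_responsive = 0,
                    selection_truth = st, seed = seed)
  ds <- simulate_dataset(cfg)
  norm <- cpm(ds$counts, tmm_factors(ds$counts))
  sel <- condition_gradients(norm, ds$samples)
  pairs <- utils::combn(names(sel), 2L)
  correlations <- data.frame(
    condition_a = pairs[1, ], condition_b = pairs[2, ],
    r = apply(pairs, 2L, function(pp) {
      cross_condition_correlation(sel[[pp[1]]], sel[[pp[2]]])$r
    }),
    true_r = apply(pairs, 2L, function(pp) {
      st$gradient_corr[pp[1], pp[2]]
    }),
    stringsAsFactors = FALSE)
  list(selection = sel, correlations = correlations,
       truth = st$gradient_corr, dataset = ds)
}

# selection gradients for every condition over reproducing females
condition_gradients <- function(norm, samples, subset_ids = NULL) {
  sel <- list()
  for (cc in conditions()) {
    keep <- samples$sample_id[as.character(samples$condition) == cc &
                                samples$offspring > 0]
    if (!is.null(subset_ids)) keep <- intersect(keep, subset_ids)
    if (length(keep) < 3L) next
    z <- zscore_by_gene(norm, samples, cc, subset = keep)
    w <- relative_fitness(
      samples$offspring[match(colnames(z$values), samples$sample_id)])
    sel[[cc]] <- selection_gradients(z, w, cc)
  }
  sel
}

#' Response-mode classification recovery experiment
#'
#' Simulates responsive genes from the published category mixture
#' (independent / combinatorial / cancelled / prioritized / similar =
#' 63 : 14 : 9.5 : 8 : 5) with 45 females per condition, calls DE for the
#' three treatment contrasts, classifies the DE union against the
#' 20-profile bank on log2 CPM, and compares against the generating
#' archetypes.
#'
#' @param seed integer seed.
#' @param n_genes number of (all responsive) genes.
#' @return list: `classification`, `accuracy` (overall),
#'   `category_accuracy` (per generating category),
#'   `independent_pct` (percentage assigned independent),
#'   `true_independent_pct`, `mixture`.
#' @export
mode_recovery <- function(seed = 1, n_genes = 2000) {
  cfg <- sim_config(n_families = 15, n_per_family_condition = 3,
                    n_genes = n_genes, frac_responsive = 1,
                    effect_size_logfc = 2, seed = seed)
  ds <- simulate_dataset(cfg)
  lnorm <- cpm(ds$counts, tmm_factors(ds$counts), log2 = TRUE)
  de <- lapply(c("Dry", "Hot", "Hot-Dry"), function(trt) {
    de_test(ds$counts, ds$samples, "Control", trt)
  })
  mc <- classify_responsive(lnorm, ds$samples, de)
  merged <- merge(mc$assignments, ds$truth$archetype, by = "gene")
  ok <- !is.na(merged$category.x)
  acc_by <- tapply(merged$category.x[ok] == merged$category.y[ok],
                   merged$category.y[ok], mean)
  list(classification = mc,
       accuracy = mean(merged$category.x[ok] == merged$category.y[ok]),
       category_accuracy = acc_by,
       independent_pct = 100 * mean(merged$category.x[ok] == "independent"),
       true_independent_pct = 100 * mean(ds$truth$archetype$category ==
                                           "independent"),
       mixture = cfg$archetype_mixture)
}

#' Plasticity-selection recovery experiment
#'
#' Simulates a split-family cohort in which gene plasticity loadings on a
#' family-level stress-tolerance factor are correlated (0.62 by default)
#' with the quality loadings that define selection on expression, and the
#' tolerance factor carries part of the assay-cohort family fitness.
#' Selection on expression is estimated from the sequenced females in the
#' linked treatment; selection on plasticity from the correlation of
#' family-mean plastic change (sequenced females, CPM scale) with mean
#' family fitness of held-out assay sisters; the experiment reports the
#' correlation between the two per-gene estimates.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param n_families number of families.
#' @param n_perm permutations for the significance test.
#' @return list: `r` (estimated correlation), `p`, `induced` (generating
#'   loading correlation), `selection`, `sel_plasticity`.
#' @export
plasticity_selection_recovery <- function(seed = 1, n_genes = 2000,
                                          n_families = 750, n_perm = 1000) {
  st <- selection_truth(plasticity_cor = 0.62, plasticity_sd = 0.2,
                        tolerance_fitness_sd = 6,
                        link_condition = "Hot-Dry",
                        fitness_channel = "latent")
  cfg <- sim_config(n_families = n_families, n_per_family_condition = 2,
                    n_assay_per_family_condition = 4, n_genes = n_genes,
                    frac_responsive = 0, nb_dispersion = 0.01,
                    baseline_log2_cpm_range = c(5, 10),
                    plasticity_family_sd = 0.1, fitness_family_sd = 0,
                    selection_truth = st, seed = seed)
  ds <- simulate_dataset(cfg)
  norm <- cpm(ds$counts, tmm_factors(ds$counts))
  trt <- st$link_condition
  seqs <- ds$samples[ds$samples$cohort == "rnaseq", ]
  sel <- condition_gradients(norm, ds$samples,
                             subset_ids = seqs$sample_id)[[trt]]
  fm <- family_means(norm, seqs)
  pl <- plasticity(fm, trt)
  assay <- ds$samples[ds$samples$cohort == "assay", ]
  ff <- family_fitness(assay, trt)
  sp <- selection_on_plasticity(pl, ff)
  res <- selection_level_vs_plasticity(sel, sp, n_perm = n_perm,
                                       seed = seed + 1L)
  list(r = res$r, p = res$p, induced = st$plasticity_cor,
       selection = sel, sel_plasticity = sp)
}
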