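#' Configuration for the synthetic split-family dataset
#'
#' Bundles every parameter of the generator that emulates the study design:
#' full-sib families split across the four conditions, negative-binomial
#' read counts with archetypal stress-response profiles and family structure,
#' and offspring counts tied to expression through known selection gradients.
#' Defaults reproduce the fitness calibration of the original assay
#' (reproducing-female cell means parameterized as a control mean of 49.09
#' offspring with heat, drought and interaction effects of -15.98, -5.12 and
#' -2.22, per-condition offspring SDs matching the published variances, and
#' per-condition reproduction probabilities 0.961, 0.976, 0.717, 0.891).
#'
#' @param n_families number of full-sib families, each split across all four
#'   conditions.
#' @param n_per_family_condition sequenced females per family within each
#'   condition.
#' @param n_assay_per_family_condition additional fitness-assay sisters per
#'   family and condition (cohort `"assay"`); they are simulated like any
#'   other female but stand in for the large expression-free fitness assay,
#'   and the tolerance-linked family fitness component
#'   (`tolerance_fitness_sd` in [selection_truth()]) is expressed in this
#'   cohort.
#' @param n_genes number of genes.
#' @param frac_responsive proportion of genes given a stress-response
#'   archetype; the rest are flat across conditions.
#' @param archetype_mixture named non-negative weights over the five response
#'   categories (`similar`, `independent`, `combinatorial`, `prioritized`,
#'   `cancelled`); normalized to proportions. Default: the observed category
#'   shares 63 / 14 / 9.5 / 8 / 5 (independent / combinatorial / cancelled /
#'   prioritized / similar), renormalized.
#' @param baseline_log2_cpm_range interval for per-gene baseline expression,
#'   log2-CPM units.
#' @param nb_dispersion negative-binomial dispersion phi (scalar or one per
#'   gene); `0` degrades to Poisson.
#' @param family_sd SD of the gene-specific family baseline effect, log2
#'   units.
#' @param plasticity_family_sd SD of the gene-specific family-by-condition
#'   (plasticity) effect, log2 units.
#' @param effect_size_logfc magnitude Delta (log2 units) mapped onto profile
#'   level +/-1.
#' @param lib_size nominal library size; realized sizes are log-normal
#'   around it with `lib_size_spread` as sdlog.
#' @param lib_size_spread sdlog of library-size variation.
#' @param control_mean,heat_effect,drought_effect,interaction_effect 2x2
#'   factorial parameterization (treatment coding, offspring units) of the
#'   per-condition mean offspring of reproducing females.
#' @param fitness_means optional named vector of per-condition means
#'   overriding the factorial parameterization.
#' @param fitness_total_sd per-condition SD of offspring number among
#'   reproducing females (family + residual combined).
#' @param fitness_family_sd SD of the family effect on offspring number.
#' @param repro_prob named per-condition probability that a female reproduces
#'   (independent Bernoulli; not linked to expression).
#' @param n_fitness_only females per condition in the expression-free fitness
#'   assay built by [simulate_fitness_assay()].
#' @param selection_truth `NULL` for no selection structure, or a list from
#'   [selection_truth()] describing latent-quality-mediated gradients.
#' @param seed integer seed; sub-stages use `seed`, `seed + 1`, `seed + 2`
#'   (design, counts, fitness) so every stage is reproducible standalone.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [selection_truth()]
#' @export
sim_config <- function(n_families = 12,
                       n_per_family_condition = 4,
                       n_assay_per_family_condition = 0,
                       n_genes = 4000,
                       frac_responsive = 0.3,
                       archetype_mixture = NULL,
                       baseline_log2_cpm_range = c(3, 10),
                       nb_dispersion = 0.05,
                       family_sd = 0.25,
                       plasticity_family_sd = 0.15,
                       effect_size_logfc = 2,
                       lib_size = 2e6,
                       lib_size_spread = 0.15,
                       control_mean = 49.09,
                       heat_effect = -15.98,
                       drought_effect = -5.12,
                       interaction_effect = -2.22,
                       fitness_means = NULL,
                       fitness_total_sd = c(Control = 15.74, Dry = 14.29,
                                            Hot = 17.58, `Hot-Dry` = 11.69),
                       fitness_family_sd = 3,
                       repro_prob = c(Control = 1514 / 1575, Dry = 1603 / 1642,
                                      Hot = 1005 / 1401, `Hot-Dry` = 1396 / 1567),
                       n_fitness_only = 1500,
                       selection_truth = NULL,
                       seed = NULL) {
  if (n_families < 2 || n_per_family_condition < 1) {
    stop_input("need n_families >= 2 and n_per_family_condition >= 1")
  }
  if (n_genes < 0) stop_input("n_genes must be non-negative")
  if (frac_responsive < 0 || frac_responsive > 1) {
    stop_input("frac_responsive must be in [0, 1]")
  }
  if (is.null(archetype_mixture)) {
    archetype_mixture <- c(independent = 63, combinatorial = 14,
                           cancelled = 9.5, prioritized = 8, similar = 5)
  }
  cats <- unique(profile_bank_definition()$category)
  bad <- setdiff(names(archetype_mixture), cats)
  if (length(bad) > 0L) {
    stop_input("unknown response category in archetype_mixture: ",
               paste(bad, collapse = ", "))
  }
  if (any(archetype_mixture < 0) || sum(archetype_mixture) <= 0) {
    stop_input("archetype_mixture weights must be non-negative, not all zero")
  }
  archetype_mixture <- archetype_mixture / sum(archetype_mixture)
  if (any(nb_dispersion < 0)) stop_input("nb_dispersion must be >= 0")
  if (!length(nb_dispersion) %in% c(1L, max(1L, n_genes))) {
    stop_input("nb_dispersion must be a scalar or one value per gene")
  }
  if (is.null(fitness_means)) {
    fitness_means <- c(
      Control    = control_mean,
      Dry        = control_mean + drought_effect,
      Hot        = control_mean + heat_effect,
      `Hot-Dry`  = control_mean + heat_effect + drought_effect +
                   interaction_effect)
  }
  for (nm in list(fitness_means, fitness_total_sd, repro_prob)) {
    if (!setequal(names(nm), conditions())) {
      stop_input("fitness_means, fitness_total_sd and repro_prob must be ",
                 "named for exactly the four conditions")
    }
  }
  if (any(repro_prob < 0 | repro_prob > 1)) {
    stop_input("repro_prob entries must be probabilities")
  }
  if (fitness_family_sd < 0 || any(fitness_total_sd < fitness_family_sd)) {
    stop_input("need 0 <= fitness_family_sd <= fitness_total_sd")
  }
  cfg <- list(
    n_families = as.integer(n_families),
    n_per_family_condition = as.integer(n_per_family_condition),
    n_assay_per_family_condition = as.integer(n_assay_per_family_condition),
    n_genes = as.integer(n_genes),
    frac_responsive = frac_responsive,
    archetype_mixture = archetype_mixture,
    baseline_log2_cpm_range = baseline_log2_cpm_range,
    nb_dispersion = nb_dispersion,
    family_sd = family_sd,
    plasticity_family_sd = plasticity_family_sd,
    effect_size_logfc = effect_size_logfc,
    lib_size = lib_size,
    lib_size_spread = lib_size_spread,
    fitness_means = fitness_means[conditions()],
    fitness_total_sd = fitness_total_sd[conditions()],
    fitness_family_sd = fitness_family_sd,
    repro_prob = repro_prob[conditions()],
    n_fitness_only = as.integer(n_fitness_only),
    selection_truth = selection_truth,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Latent-quality selection structure for the generator
#'
#' Describes how true selection gradients are built. Each individual carries
#' a latent physiological quality `q` (standard normal); gene `g` loads on it
#' with condition-specific loading `alpha_gc`, and its direct gradient is
#' proportional to the same loading. Because transcripts sharing the latent
#' factor are mutually correlated, the univariate (net) selection intensity
#' the pipeline estimates is `sigma_gc = beta*_gc (1 + sum_g' alpha_g'c^2 -
#' alpha_gc^2)`, and the across-gene spread of `sigma` is set by
#' `net_gradient_sd` rather than by the number of genes. Rows of `alpha` are
#' multivariate normal with correlation `gradient_corr` across conditions,
#' which therefore is also the cross-environment correlation of the net
#' gradients. Optionally a family-by-condition latent tolerance factor
#' `Q_fc` induces heritable plasticity: gene plasticity loadings `delta_g`
#' are drawn jointly with `alpha_g` in `link_condition` at correlation
#' `plasticity_cor`, and a share `quality_fitness_share` of the family
#' fitness variance is mediated by `Q`, so that selection on expression and
#' selection on plasticity are correlated by construction.
#'
#' @param gradient_corr 4x4 cross-condition correlation matrix of gradients
#'   (dimnames = conditions). Default: the published pairwise estimates
#'   (-0.24 Control-Dry, -0.095 Control-Hot, -0.215 Control-Hot-Dry,
#'   0.095 Dry-Hot, 0.015 Dry-Hot-Dry, 0.34 Hot-Hot-Dry).
#' @param quality_sd SD of the quality loadings alpha (clipped to +/-0.8).
#' @param net_gradient_sd target across-gene SD of the net selection
#'   intensity in each condition (relative-fitness units per expression SD).
#' @param plasticity_cor correlation between alpha in `link_condition` and
#'   the plasticity loading delta; 0 disables the plasticity link.
#' @param plasticity_sd SD of delta (log2 units).
#' @param tolerance_fitness_sd SD (offspring units) of the family fitness
#'   component carried by the latent tolerance factor Q; it is expressed in
#'   the assay cohort, on top of the ordinary family effect
#'   (`fitness_family_sd`), which is drawn independently per cohort.
#' @param link_condition condition whose quality loading is tied to delta.
#' @param fitness_channel how fitness is tied to expression: `"sum"` is the
#'   literal per-gene model `w' = 1 + sum_g beta*_g z_g` (direct gradients
#'   `beta* = kappa alpha` recorded in the truth); `"latent"` ties fitness
#'   to the quality factor itself, `w' = 1 + theta q`, the large-G limit of
#'   the sum, under which the net gradient of every gene is exactly
#'   `theta alpha_gc` and recovery estimands are free of cross-gene
#'   feedback.
#' @return list of class `selection_truth_config`.
#' @export
selection_truth <- function(gradient_corr = NULL,
                            quality_sd = 0.25,
                            net_gradient_sd = 0.08,
                            plasticity_cor = 0,
                            plasticity_sd = 0.2,
                            tolerance_fitness_sd = 0,
                            link_condition = "Hot-Dry",
                            fitness_channel = c("sum", "latent")) {
  fitness_channel <- match.arg(fitness_channel)
  if (is.null(gradient_corr)) gradient_corr <- default_gradient_corr()
  stopifnot(is.matrix(gradient_corr), dim(gradient_corr) == c(4L, 4L))
  if (is.null(dimnames(gradient_corr))) {
    dimnames(gradient_corr) <- list(conditions(), conditions())
  }
  gradient_corr <- gradient_corr[conditions(), conditions()]
  if (any(abs(gradient_corr - t(gradient_corr)) > 1e-10) ||
      any(abs(diag(gradient_corr) - 1) > 1e-10)) {
    stop_input("gradient_corr must be a symmetric correlation matrix")
  }
  if (min(eigen(gradient_corr, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop_input("gradient_corr must be positive definite")
  }
  if (abs(plasticity_cor) > 1) stop_input("plasticity_cor must be in [-1, 1]")
  if (tolerance_fitness_sd < 0) {
    stop_input("tolerance_fitness_sd must be >= 0")
  }
  link_condition <- match.arg(link_condition, conditions())
  structure(list(gradient_corr = gradient_corr,
                 quality_sd = quality_sd,
                 net_gradient_sd = net_gradient_sd,
                 plasticity_cor = plasticity_cor,
                 plasticity_sd = plasticity_sd,
                 tolerance_fitness_sd = tolerance_fitness_sd,
                 link_condition = link_condition,
                 fitness_channel = fitness_channel),
            class = "selection_truth_config")
}

# Published pairwise correlations of selection intensities across
# environments (text values where stated, CI midpoints otherwise).
default_gradient_corr <- function() {
  r <- diag(4)
  dimnames(r) <- list(conditions(), conditions())
  fill <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  fill("Control", "Dry", -0.24)
  fill("Control", "Hot", -0.095)
  fill("Control", "Hot-Dry", -0.215)
  fill("Dry", "Hot", 0.095)
  fill("Dry", "Hot-Dry", 0.015)
  fill("Hot", "Hot-Dry", 0.34)
  r
}

#' Simulate the split-family sampling design
#'
#' One row per simulated female. Every full-sib family (one dam x one sire)
#' appears in all four conditions; each female gets an independent
#' Bernoulli `reproduced` flag with the condition's reproduction
#' probability.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `sample_id`, `condition`, `family_f`,
#'   `family_m`, `offspring` (NA until [simulate_fitness()]), `reproduced`.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fam <- sprintf("F%03d", seq_len(config$n_families))
  sire <- sprintf("M%03d", seq_len(config$n_families))
  n_tot <- config$n_per_family_condition + config$n_assay_per_family_condition
  grid <- expand.grid(rep = seq_len(n_tot),
                      family = seq_len(config$n_families),
                      condition = conditions(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  assay <- grid$rep > config$n_per_family_condition
  tag <- ifelse(assay, paste0("A", grid$rep - config$n_per_family_condition),
                as.character(grid$rep))
  design <- data.frame(
    sample_id = sprintf("%s_%s_%s", fam[grid$family],
                        gsub("-", "", grid$condition), tag),
    condition = factor(grid$condition, levels = conditions()),
    family_f = fam[grid$family],
    family_m = sire[grid$family],
    cohort = ifelse(assay, "assay", "rnaseq"),
    offspring = NA_integer_,
    stringsAsFactors = FALSE)
  design$reproduced <- with_seed(
    if (is.null(config$seed)) NULL else config$seed,
    stats::rbinom(nrow(design), 1L,
                  config$repro_prob[as.character(design$condition)]) == 1L)
  design
}

#' Simulate negative-binomial read counts for a design
#'
#' Gene `g`, individual `i` of family `f` in condition `c` gets
#' `count ~ NB(mean = L_i 2^x / 1e6, dispersion = phi_g)` with
#' `x = m_g + P_g(c) Delta + a_fg + b_fcg + lambda_gc q_i` on the log2-CPM
#' scale: a uniform baseline `m_g`, the archetype profile level `P_g(c)` in
#' {-1, 0, 1} scaled by `Delta`, gene-specific family and family-by-condition
#' normal effects, and (when a [selection_truth()] is configured) the latent
#' quality factor `q_i` with gene loading `lambda_gc` calibrated so the
#' realized expression-quality correlation approximates `alpha_gc`.
#'
#' @param design output of [simulate_design()].
#' @param config a [sim_config()].
#' @return list with `counts` (integer gene x sample matrix) and `truth`
#'   (class `sim_truth`: archetypes, condition log2 fold changes, direct and
#'   net gradients, latent loadings, family effects, fitness coefficients).
#' @export
simulate_counts <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  n <- nrow(design)
  fam_levels <- sort(unique(design$family_f))
  nf <- length(fam_levels)
  cond <- as.character(design$condition)
  fam_idx <- match(design$family_f, fam_levels)
  cond_idx <- match(cond, conditions())
  phi <- rep_len(config$nb_dispersion, max(1L, g))
  bank <- build_profile_bank()

  seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  out <- with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(g))
    n_resp <- round(config$frac_responsive * g)
    responsive <- rep(FALSE, g)
    responsive[sample.int(g, n_resp)] <- TRUE
    category <- rep("none", g)
    profile <- rep(NA_character_, g)
    levels_mat <- matrix(0, g, 4L, dimnames = list(gene_id, conditions()))
    if (n_resp > 0L) {
      cat_draw <- sample(names(config$archetype_mixture), n_resp,
                         replace = TRUE, prob = config$archetype_mixture)
      resp_idx <- which(responsive)
      for (j in seq_along(resp_idx)) {
        i <- resp_idx[j]
        rows <- which(bank$category == cat_draw[j])
        pick <- rows[sample.int(length(rows), 1L)]
        category[i] <- cat_draw[j]
        profile[i] <- bank$label[pick]
        levels_mat[i, ] <- as.numeric(bank[pick, conditions()])
      }
    }
    condition_logfc <- levels_mat * config$effect_size_logfc

    m <- stats::runif(g, config$baseline_log2_cpm_range[1],
                      config$baseline_log2_cpm_range[2])
    a_fg <- matrix(stats::rnorm(g * nf, 0, config$family_sd), g, nf,
                   dimnames = list(gene_id, fam_levels))
    b_fcg <- array(stats::rnorm(g * nf * 4L, 0, config$plasticity_family_sd),
                   dim = c(g, nf, 4L),
                   dimnames = list(gene_id, fam_levels, conditions()))

    st <- config$selection_truth
    alpha <- gradients <- net_gradients <- NULL
    delta <- NULL
    q_i <- rep(0, n)
    Q_fc <- matrix(0, nf, 4L, dimnames = list(fam_levels, conditions()))
    if (!is.null(st) && g > 0L) {
      ch <- chol(st$gradient_corr)
      alpha <- (matrix(stats::rnorm(g * 4L), g, 4L) %*% ch) * st$quality_sd
      alpha <- pmin(pmax(alpha, -0.8), 0.8)
      dimnames(alpha) <- list(gene_id, conditions())
      if (st$plasticity_cor != 0) {
        a_link <- alpha[, st$link_condition] / st$quality_sd
        delta <- st$plasticity_sd *
          (st$plasticity_cor * a_link +
           sqrt(1 - st$plasticity_cor^2) * stats::rnorm(g))
      } else {
        delta <- rep(0, g)
      }
      Q_fc[] <- stats::rnorm(nf * 4L)
      b_fcg <- b_fcg + outer(delta, Q_fc)  # g x f x c
      if (st$fitness_channel == "latent") {
        gradients <- NULL
        net_gradients <- (st$net_gradient_sd / st$quality_sd) * alpha
      } else {
        kappa <- st$net_gradient_sd /
          (st$quality_sd * (1 + g * st$quality_sd^2))
        gradients <- kappa * alpha
        ssq <- colSums(alpha^2)
        net_gradients <- gradients *
          (1 + rep(ssq, each = g) - alpha^2)
      }
      q_i <- stats::rnorm(n)
    }

    lib <- stats::rlnorm(n, log(config$lib_size) - config$lib_size_spread^2 / 2,
                         config$lib_size_spread)

    counts <- matrix(0L, g, n, dimnames = list(gene_id, design$sample_id))
    if (g > 0L) {
      x <- matrix(m, g, n) + condition_logfc[, cond_idx, drop = FALSE] +
        a_fg[, fam_idx, drop = FALSE] +
        matrix(b_fcg[cbind(rep(seq_len(g), n),
                           rep(fam_idx, each = g),
                           rep(cond_idx, each = g))], g, n)
      if (!is.null(alpha)) {
        mu0 <- 2^m * config$lib_size / 1e6
        tau <- sqrt(config$family_sd^2 + config$plasticity_family_sd^2 +
                    delta^2 + (log2(exp(1)))^2 * (phi + 1 / mu0))
        lambda <- (tau * alpha / sqrt(1 - alpha^2))  # recycles tau over cols
        x <- x + lambda[, cond_idx, drop = FALSE] *
          matrix(q_i, g, n, byrow = TRUE)
      }
      mu <- 2^x * matrix(lib, g, n, byrow = TRUE) / 1e6
      pois <- phi == 0
      if (any(pois)) {
        counts[pois, ] <- stats::rpois(sum(pois) * n, mu[pois, , drop = FALSE])
      }
      if (any(!pois)) {
        counts[!pois, ] <- stats::rnbinom(sum(!pois) * n,
                                          size = 1 / phi[!pois],
                                          mu = mu[!pois, , drop = FALSE])
      }
    }
    storage.mode(counts) <- "integer"

    truth <- structure(list(
      archetype = data.frame(gene = gene_id, responsive = responsive,
                             category = category, profile = profile,
                             stringsAsFactors = FALSE),
      condition_logfc = condition_logfc,
      gradients = gradients,
      net_gradients = net_gradients,
      quality_loadings = alpha,
      plasticity_loadings = delta,
      quality = q_i,
      fitness_channel = if (is.null(st)) NULL else st$fitness_channel,
      quality_strength = if (is.null(st)) NULL else
        st$net_gradient_sd / st$quality_sd,
      family_quality = Q_fc,
      family_effects = a_fg,
      family_condition_effects = b_fcg,
      fitness_coefficients = list(
        means = config$fitness_means,
        total_sd = config$fitness_total_sd,
        family_sd = config$fitness_family_sd,
        repro_prob = config$repro_prob)),
      class = "sim_truth")
    list(counts = counts, truth = truth)
  })
  out
}

#' Simulate offspring counts from expression and known gradients
#'
#' For a reproducing female `i` of family `f` in condition `c`, offspring
#' number is a rounded gamma draw with mean
#' `mu_c (1 + sum_g beta*_gc z_gi) + u_fc` and the condition's residual
#' variance, where `u_fc` is a family effect (in the assay cohort partly
#' mediated by the latent family tolerance `Q_fc` from the counts stage).
#' The gamma (rather than normal) residual keeps the calibrated mean and
#' variance while placing essentially no mass at zero, so reproducing-only
#' summaries are unbiased. Non-reproducing females get 0 offspring.
#' `beta*` is taken from `truth$gradients`; with no selection structure the
#' expression term vanishes and per-condition means equal `mu_c` up to
#' rounding and zero-truncation.
#'
#' @param design output of [simulate_design()].
#' @param zscores gene x sample matrix of within-condition z-scores (columns
#'   must match `design$sample_id`), or `NULL` when no genes are simulated.
#' @param config a [sim_config()].
#' @param truth optional `sim_truth` from [simulate_counts()]; required for
#'   gradient-linked fitness and the family tolerance share.
#' @return `design` with the `offspring` column filled.
#' @export
simulate_fitness <- function(design, zscores, config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(zscores) && nrow(zscores) > 0L) {
    if (is.null(colnames(zscores)) ||
        !identical(colnames(zscores), design$sample_id)) {
      stop_input("zscores columns must match design$sample_id")
    }
  }
  n <- nrow(design)
  cond <- as.character(design$condition)
  mu <- config$fitness_means[cond]
  resid_sd <- sqrt(config$fitness_total_sd^2 - config$fitness_family_sd^2)[cond]
  fam_levels <- sort(unique(design$family_f))
  nf <- length(fam_levels)
  tol_sd <- 0
  Q <- matrix(0, nf, 4L, dimnames = list(fam_levels, conditions()))
  s_term <- rep(0, n)
  if (!is.null(truth)) {
    st <- config$selection_truth
    if (!is.null(st)) tol_sd <- st$tolerance_fitness_sd %||% 0
    if (!is.null(truth$family_quality) &&
        all(fam_levels %in% rownames(truth$family_quality))) {
      Q <- truth$family_quality[fam_levels, , drop = FALSE]
    }
    if (identical(truth$fitness_channel, "latent") &&
        !is.null(truth$quality)) {
      if (length(truth$quality) != n) {
        stop_input("truth$quality does not match the design")
      }
      s_term <- truth$quality_strength * truth$quality
    } else if (!is.null(truth$gradients) && !is.null(zscores) &&
               nrow(zscores) > 0L) {
      genes <- intersect(rownames(zscores), rownames(truth$gradients))
      z <- zscores[genes, , drop = FALSE]
      z[is.na(z)] <- 0
      b <- truth$gradients[genes, , drop = FALSE]
      for (cc in conditions()) {
        j <- which(cond == cc)
        if (length(j)) s_term[j] <- colSums(z[, j, drop = FALSE] * b[, cc])
      }
    }
  }
  seed <- if (is.null(config$seed)) NULL else config$seed + 2L
  cohort <- if (is.null(design$cohort)) rep("rnaseq", n) else design$cohort
  design$offspring <- with_seed(seed, {
    u_raw <- matrix(stats::rnorm(nf * 4L), nf, 4L,
                    dimnames = list(fam_levels, conditions()))
    u_raw2 <- matrix(stats::rnorm(nf * 4L), nf, 4L)
    # the tolerance-linked fitness component is expressed in the assay
    # cohort; each cohort carries an independent ordinary family effect
    u_rna <- config$fitness_family_sd * u_raw
    u_assay <- config$fitness_family_sd * u_raw2 + tol_sd * Q
    idx <- cbind(match(design$family_f, fam_levels),
                 match(cond, conditions()))
    u_i <- ifelse(cohort == "assay", u_assay[idx], u_rna[idx])
    # right-skewed count noise: gamma with the condition's residual variance.
    # A normal residual would put non-negligible mass at zero under the Hot
    # calibration, and conditioning reproducing-only summaries on
    # offspring > 0 would then bias cell means upward by sigma*lambda.
    mu_i <- pmax(mu * (1 + s_term) + u_i, 0.01)
    shape <- pmin((mu / resid_sd)^2, 1e10)  # cap: sd -> 0 degrades smoothly
    w <- stats::rgamma(n, shape = shape, scale = mu_i / shape)
    as.integer(ifelse(design$reproduced, pmax(0, round(w)), 0L))
  })
  design
}

#' Simulate a complete dataset: design, counts, normalization, fitness
#'
#' Runs [simulate_design()], [simulate_counts()], TMM/CPM normalization and
#' within-condition z-scoring, then [simulate_fitness()], wiring the latent
#' truth through. With `config$seed` set the whole object is bit-reproducible.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`: `counts`, `samples`, `truth`.
#' @export
simulate_dataset <- function(config) {
  design <- simulate_design(config)
  cnt <- simulate_counts(design, config)
  z <- NULL
  if (config$n_genes > 0L) {
    norm <- cpm(cnt$counts, tmm_factors(cnt$counts))
    z <- matrix(NA_real_, config$n_genes, nrow(design),
                dimnames = dimnames(cnt$counts))
    for (cc in conditions()) {
      zc <- zscore_by_gene(norm, design, cc)
      z[rownames(zc$values), colnames(zc$values)] <- zc$values
    }
  }
  samples <- simulate_fitness(design, z, config, truth = cnt$truth)
  structure(list(counts = cnt$counts, samples = samples, truth = cnt$truth,
                 config = config),
            class = "sim_dataset")
}

#' Simulate the expression-free fitness assay
#'
#' Builds a large split-family design (about `n_fitness_only` females per
#' condition, four per family and condition) and simulates offspring with no
#' expression linkage, mirroring the scale of the original assay.
#'
#' @param config a [sim_config()]; only the fitness and family parameters
#'   are used.
#' @return sample table with filled `offspring`.
#' @export
simulate_fitness_assay <- function(config) {
  per_fam <- 4L
  assay_cfg <- config
  assay_cfg$n_families <- as.integer(ceiling(config$n_fitness_only / per_fam))
  assay_cfg$n_per_family_condition <- per_fam
  assay_cfg$n_genes <- 0L
  assay_cfg$selection_truth <- NULL
  design <- simulate_design(assay_cfg)
  simulate_fitness(design, NULL, assay_cfg)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated split-family dataset\n")
  cat(sprintf("  %d genes x %d females (%d families, %d per family/condition)\n",
              nrow(x$counts), nrow(x$samples),
              length(unique(x$samples$family_f)),
              x$config$n_per_family_condition))
  cat(sprintf("  responsive genes: %d; selection structure: %s\n",
              sum(x$truth$archetype$responsive),
              if (is.null(x$truth$gradients)) "none" else "latent-quality"))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d families x %d per condition, %d genes (%.0f%% responsive)\n",
              x$n_families, x$n_per_family_condition, x$n_genes,
              100 * x$frac_responsive))
  cat(sprintf("  effect size %.2g log2, dispersion %.3g, seed %s\n",
              x$effect_size_logfc, x$nb_dispersion[1],
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
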