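#' Differential expression between two conditions
#'
#' Stand-in DE callers operating on the count matrix directly (the original
#' study used edgeR; reproducing its GLM/dispersion-shrinkage machinery is
#' deliberately not attempted here, and no result in this package depends on
#' matching its gene counts).
#'
#' * `welch_logcpm` (default): unequal-variance two-sample t-test on
#'   `log2(CPM + 0.5)`, vectorized over genes.
#' * `nb_exact`: conditional exact test for equal negative-binomial means
#'   given a method-of-moments common dispersion, applied to counts
#'   quantile-adjusted to the mean effective library size. With dispersion 0
#'   and equal library sizes this reduces to the exact conditional binomial
#'   test on the group sums.
#'
#' In both cases `log2fc` is the difference of group means of
#' `log2(CPM + 0.5)` (condition b minus a), p-values are Benjamini-Hochberg
#' adjusted across tested genes, and `direction` is `up`/`down` for genes
#' with `q <= alpha`, `ns` otherwise. Genes failing the low-expression
#' filter (CPM >= `min_cpm` in >= `min_frac` of the two groups' samples) are
#' not tested.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample table (`sample_id`, `condition`).
#' @param cond_a reference condition (e.g. `"Control"`).
#' @param cond_b comparison condition; positive `log2fc` means higher in
#'   `cond_b`.
#' @param method `"welch_logcpm"` or `"nb_exact"`.
#' @param alpha FDR threshold for the direction call.
#' @param min_cpm,min_frac low-expression filter; `min_cpm = 0` disables it.
#' @return `de_result`: data.frame (gene, log2fc, statistic, p, q,
#'   direction) with attributes `contrast`, `method`, `alpha`.
#' @export
de_test <- function(counts, samples, cond_a, cond_b,
                    method = c("welch_logcpm", "nb_exact"),
                    alpha = 0.05, min_cpm = 1, min_frac = 0.25) {
  method <- match.arg(method)
  ids_a <- samples$sample_id[as.character(samples$condition) == cond_a]
  ids_b <- samples$sample_id[as.character(samples$condition) == cond_b]
  if (length(ids_a) < 3L || length(ids_b) < 3L) {
    stop_input("need at least 3 samples per group")
  }
  sub <- counts[, c(ids_a, ids_b), drop = FALSE]
  keep <- if (min_cpm > 0) filter_genes(sub, min_cpm, min_frac) else
    rep(TRUE, nrow(sub))
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop_input("no genes pass the expression filter")
  f <- tmm_factors(sub)
  lc <- cpm(sub, f, log2 = TRUE)$values
  ia <- seq_along(ids_a)
  ib <- length(ids_a) + seq_along(ids_b)
  lfc <- rowMeans(lc[, ib, drop = FALSE]) - rowMeans(lc[, ia, drop = FALSE])
  if (method == "welch_logcpm") {
    ws <- welch_rows(lc[, ia, drop = FALSE], lc[, ib, drop = FALSE])
    stat <- ws$t
    p <- ws$p
  } else {
    lib_eff <- colSums(sub) * f
    phi <- common_dispersion_mom(sub, lib_eff)
    adj <- quantile_adjust(sub, lib_eff, phi)
    p <- nb_exact_rows(adj, ia, ib, phi)
    stat <- stats::qnorm(pmax(p / 2, 1e-300), lower.tail = FALSE) * sign(lfc)
  }
  q <- bh_adjust(p)
  direction <- ifelse(q <= alpha, ifelse(lfc > 0, "up", "down"), "ns")
  res <- data.frame(gene = rownames(sub), log2fc = lfc, statistic = stat,
                    p = p, q = q, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            contrast = paste(cond_b, "vs", cond_a), method = method,
            alpha = alpha, n_a = length(ids_a), n_b = length(ids_b))
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("DE result %s (%s): %d genes tested, %d up / %d down at FDR %.2g\n",
              attr(x, "contrast"), attr(x, "method"), nrow(x),
              sum(x$direction == "up"), sum(x$direction == "down"),
              attr(x, "alpha")))
  invisible(x)
}

# Vectorized Welch t-test across matrix rows.
welch_rows <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {          # constant rows: no evidence either way
    p[zero] <- ifelse(abs(mb - ma)[zero] < 1e-12, 1, 0)
    t[zero] <- ifelse(abs(mb - ma)[zero] < 1e-12, 0, Inf * sign(mb - ma)[zero])
  }
  list(t = t, p = p, df = df)
}

# Method-of-moments common NB dispersion from ratio-scaled counts.
common_dispersion_mom <- function(counts, lib_eff) {
  y <- sweep(counts, 2L, mean(lib_eff) / lib_eff, "*")
  m <- rowMeans(y)
  v <- apply(y, 1L, stats::var)
  phi <- (v - m) / m^2
  phi <- phi[is.finite(phi)]
  if (length(phi) == 0L) return(0)
  max(0, stats::median(phi))
}

# Moment-matched adjustment of counts to the mean effective library size.
quantile_adjust <- function(counts, lib_eff, phi) {
  lbar <- mean(lib_eff)
  p_g <- rowSums(counts) / sum(lib_eff)
  out <- counts
  for (s in seq_along(lib_eff)) {
    mu <- p_g * lib_eff[s]
    mus <- p_g * lbar
    v <- mu + phi * mu^2
    vs <- mus + phi * mus^2
    r <- sqrt(ifelse(v > 0, vs / v, 1))
    out[, s] <- pmax(0, round(mus + (counts[, s] - mu) * r))
  }
  out
}

# Conditional exact NB test per row given the two group sums. Under equal
# per-sample means and common dispersion the conditional law of the first
# group's sum given the total does not depend on the mean; phi = 0 gives
# the exact conditional binomial split.
nb_exact_rows <- function(adj, ia, ib, phi) {
  na <- length(ia)
  nb <- length(ib)
  s1 <- rowSums(adj[, ia, drop = FALSE])
  s2 <- rowSums(adj[, ib, drop = FALSE])
  tt <- s1 + s2
  vapply(seq_len(nrow(adj)), function(i) {
    t_i <- tt[i]
    if (t_i == 0) return(1)
    if (phi == 0) {
      pr <- stats::dbinom(0:t_i, t_i, na / (na + nb))
      obs <- pr[s1[i] + 1]
      return(min(1, sum(pr[pr <= obs * (1 + 1e-7)])))
    }
    mu0 <- t_i / (na + nb)
    # support window around the conditional mode (mass outside negligible)
    sd0 <- sqrt(t_i * (na * nb) / (na + nb)^2 * (1 + phi * mu0))
    lo <- max(0, floor(t_i * na / (na + nb) - 40 * sd0 - 5))
    hi <- min(t_i, ceiling(t_i * na / (na + nb) + 40 * sd0 + 5))
    k <- lo:hi
    lp <- stats::dnbinom(k, size = na / phi, mu = na * mu0, log = TRUE) +
      stats::dnbinom(t_i - k, size = nb / phi, mu = nb * mu0, log = TRUE)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    if (s1[i] < lo || s1[i] > hi) return(2.2e-16)
    obs <- pr[s1[i] - lo + 1]
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values; order-preserving in p.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation test for a difference in DE-gene counts between contrasts
#'
#' Tests whether two treatments differ in how many genes respond relative
#' to the shared control. The observed statistic is |N_DE(treat_1 vs
#' control) - N_DE(treat_2 vs control)|. For each permutation, entire
#' samples of the two treatment groups are reshuffled between the two
#' treatments (the control group is untouched), both DE analyses rerun with
#' the in-package caller, and the statistic recomputed; p is the add-one
#' proportion of permuted statistics at least as large.
#'
#' Normalization (TMM on the three groups jointly) is computed once;
#' permutations only reassign group labels.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample table.
#' @param treat_1,treat_2 the two treatment conditions.
#' @param control shared reference condition.
#' @param n_perm number of permutations.
#' @param seed optional permutation seed.
#' @param alpha FDR threshold defining a DE gene.
#' @param min_cpm,min_frac expression filter.
#' @return list: `n_de_1`, `n_de_2`, `observed` (|difference|), `p`.
#' @export
de_count_permutation <- function(counts, samples, treat_1, treat_2,
                                 control = "Control", n_perm = 1000,
                                 seed = NULL, alpha = 0.05,
                                 min_cpm = 1, min_frac = 0.25) {
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  ids_c <- samples$sample_id[as.character(samples$condition) == control]
  ids_1 <- samples$sample_id[as.character(samples$condition) == treat_1]
  ids_2 <- samples$sample_id[as.character(samples$condition) == treat_2]
  if (min(lengths(list(ids_c, ids_1, ids_2))) < 3L) {
    stop_input("need at least 3 samples per group")
  }
  sub <- counts[, c(ids_c, ids_1, ids_2), drop = FALSE]
  keep <- if (min_cpm > 0) filter_genes(sub, min_cpm, min_frac) else
    rep(TRUE, nrow(sub))
  sub <- sub[keep, , drop = FALSE]
  lc <- cpm(sub, tmm_factors(sub), log2 = TRUE)$values
  ic <- seq_along(ids_c)
  pool <- length(ids_c) + seq_len(length(ids_1) + length(ids_2))
  n1 <- length(ids_1)
  n_de <- function(idx_t) {
    p <- welch_rows(lc[, ic, drop = FALSE], lc[, idx_t, drop = FALSE])$p
    sum(bh_adjust(p) <= alpha)
  }
  nd1 <- n_de(pool[seq_len(n1)])
  nd2 <- n_de(pool[-seq_len(n1)])
  obs <- abs(nd1 - nd2)
  b <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      sh <- sample(pool)
      d <- abs(n_de(sh[seq_len(n1)]) - n_de(sh[-seq_len(n1)]))
      if (d >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(n_de_1 = nd1, n_de_2 = nd2, observed = obs,
       p = (b + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Permutation test on mean absolute log2 fold change
#'
#' Compares the mean |log2FC| between two response vectors by randomly
#' reassigning the pooled values to the two groups.
#'
#' @param lfc_1,lfc_2 vectors of absolute log2 fold changes (absolute value
#'   is taken defensively).
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @param alternative `"two.sided"` (default) on |difference of means|, or
#'   one-sided variants on mean(lfc_2) - mean(lfc_1).
#' @param exact enumerate all assignments (small instances).
#' @return list with `observed` (mean_2 - mean_1) and `p`.
#' @export
magnitude_permutation <- function(lfc_1, lfc_2, n_perm = 10000, seed = NULL,
                                  alternative = "two.sided", exact = FALSE) {
  if (length(lfc_1) == 0L || length(lfc_2) == 0L) {
    stop_input("both fold-change vectors must be non-empty")
  }
  res <- perm_test(c(abs(lfc_2), abs(lfc_1)), length(lfc_2),
                   function(b, a) mean(b) - mean(a),
                   n_perm = n_perm, seed = seed,
                   alternative = alternative, exact = exact)
  list(observed = res$observed, p = res$p, n_perm = res$n_perm)
}

#' Association between two DE gene sets
#'
#' 2x2 chi-square (1 df, Pearson, no continuity correction) of joint DE
#' membership over a gene universe, plus the overlap split into same- and
#' opposite-direction responses when directions are supplied.
#'
#' @param de_set_1,de_set_2 character vectors of DE gene ids.
#' @param universe_size number of genes in the universe.
#' @param dir_1,dir_2 optional named direction vectors (`"up"`/`"down"`,
#'   names = gene ids) for the direction split.
#' @return list: `chisq`, `df`, `p`, `table`, `overlap`, `same_direction`,
#'   `opposite_direction`, `expected_warning` (TRUE if any expected cell
#'   < 1).
#' @export
overlap_test <- function(de_set_1, de_set_2, universe_size,
                         dir_1 = NULL, dir_2 = NULL) {
  de_set_1 <- unique(de_set_1)
  de_set_2 <- unique(de_set_2)
  u <- length(union(de_set_1, de_set_2))
  if (universe_size < u) stop_input("universe_size smaller than the union")
  n11 <- length(intersect(de_set_1, de_set_2))
  tab <- matrix(c(n11, length(de_set_1) - n11,
                  length(de_set_2) - n11,
                  universe_size - u), 2L, 2L,
                dimnames = list(set1 = c("in", "out"),
                                set2 = c("in", "out")))
  cs <- pearson_chisq(tab)
  same <- opp <- NA_integer_
  if (!is.null(dir_1) && !is.null(dir_2)) {
    both <- intersect(de_set_1, de_set_2)
    same <- sum(dir_1[both] == dir_2[both])
    opp <- sum(dir_1[both] != dir_2[both])
  }
  list(chisq = cs$statistic, df = cs$df, p = cs$p, table = tab,
       overlap = n11, same_direction = same, opposite_direction = opp,
       expected_warning = any(cs$expected < 1))
}
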