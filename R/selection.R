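#' Relative fitness
#'
#' `w'_i = w_i / mean(w)`, so the returned vector has mean exactly 1.
#'
#' @param offspring vector of offspring counts.
#' @return numeric vector of relative fitness.
#' @export
relative_fitness <- function(offspring) {
  if (length(offspring) == 0L || mean(offspring) <= 0) {
    stop_input("offspring counts must have a positive mean")
  }
  offspring / mean(offspring)
}

#' Per-gene selection intensities within one condition
#'
#' For every gene, the slope of the simple linear regression of relative
#' fitness on the within-condition z-scored expression level. Because the
#' predictor has unit SD, the slope is the selection intensity of classical
#' phenotypic selection analysis and equals the covariance of relative
#' fitness with the z-score. Two-sided p-values come from the usual OLS t
#' statistic (n - 2 df); q-values are Benjamini-Hochberg across genes
#' within the condition.
#'
#' @param z `norm_matrix` of z-scores for the individuals used (z-scoring
#'   must have been done over exactly these individuals), or a plain gene x
#'   individual matrix.
#' @param w_prime relative fitness for the same individuals (mean 1),
#'   aligned with the columns of `z`.
#' @param condition label stored on the result.
#' @return `selection_result`: data.frame (gene, beta, se, p, q) with
#'   attributes `condition` and `n`.
#' @export
selection_gradients <- function(z, w_prime, condition = NA_character_) {
  zv <- if (inherits(z, "norm_matrix")) z$values else as.matrix(z)
  n <- ncol(zv)
  if (n < 3L) stop_input("need at least 3 individuals")
  if (length(w_prime) != n) stop_input("w_prime must match the columns of z")
  if (abs(mean(w_prime) - 1) > 1e-6) {
    stop_input("w_prime must be relative fitness with mean 1")
  }
  wc <- w_prime - mean(w_prime)
  zc <- zv - rowMeans(zv)
  sxx <- rowSums(zc^2)
  beta <- as.numeric(zc %*% wc) / sxx
  rss <- sum(wc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  t <- beta / se
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  res <- data.frame(gene = rownames(zv), beta = beta, se = se,
                    p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("selection_result", "data.frame"),
            condition = condition, n = n)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection intensities in %s: %d genes, n = %d individuals\n",
              attr(x, "condition"), nrow(x), attr(x, "n")))
  cat(sprintf("  median |beta| = %.3f; %d genes at q <= 0.05\n",
              stats::median(abs(x$beta)), sum(x$q <= 0.05)))
  invisible(x)
}

#' Summaries of a selection-intensity distribution
#'
#' Median and SD of |beta|, proportions of positive/negative gradients,
#' counts of significant genes, and (when several results are supplied) a
#' Kruskal-Wallis test on |beta| across conditions.
#'
#' @param result a `selection_result` or a list of them.
#' @param alpha FDR threshold for the significance counts.
#' @return data.frame of per-condition summaries; with a list input, the
#'   Kruskal-Wallis statistic is attached as attribute `kruskal`.
#' @export
selection_summary <- function(result, alpha = 0.05) {
  one <- function(r) {
    data.frame(condition = attr(r, "condition"), n_genes = nrow(r),
               n_individuals = attr(r, "n"),
               median_abs_beta = stats::median(abs(r$beta)),
               sd_abs_beta = stats::sd(abs(r$beta)),
               prop_positive = mean(r$beta > 0),
               prop_negative = mean(r$beta < 0),
               n_sig = sum(r$q <= alpha),
               n_sig_positive = sum(r$q <= alpha & r$beta > 0),
               n_sig_negative = sum(r$q <= alpha & r$beta < 0),
               stringsAsFactors = FALSE)
  }
  if (inherits(result, "selection_result")) return(one(result))
  out <- do.call(rbind, lapply(result, one))
  if (length(result) > 1L) {
    vals <- unlist(lapply(result, function(r) abs(r$beta)))
    grp <- factor(rep(vapply(result, attr, "", "condition"),
                      vapply(result, nrow, 0L)))
    attr(out, "kruskal") <- stats::kruskal.test(vals, grp)
  }
  out
}

#' Correlation of selection intensities between two conditions
#'
#' Pearson correlation of the beta vectors over the genes present in both
#' results, with a 95% Fisher-z confidence interval.
#'
#' @param result_a,result_b `selection_result` objects.
#' @param conf confidence level.
#' @return list: `r`, `ci` (length 2), `n_genes`, `conditions`.
#' @export
cross_condition_correlation <- function(result_a, result_b, conf = 0.95) {
  shared <- intersect(result_a$gene, result_b$gene)
  if (length(shared) < 3L) stop_input("fewer than 3 shared genes")
  a <- result_a$beta[match(shared, result_a$gene)]
  b <- result_b$beta[match(shared, result_b$gene)]
  r <- stats::cor(a, b)
  zr <- atanh(r)
  se <- 1 / sqrt(length(shared) - 3)
  ci <- tanh(zr + stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2)) * se)
  list(r = r, ci = ci, n_genes = length(shared),
       conditions = c(attr(result_a, "condition"), attr(result_b, "condition")))
}

#' Sign switches of selection between Control and a treatment
#'
#' Counts genes whose gradient changes sign between the two results and
#' reports the magnitude of change among switchers and the share switching
#' from negative (in control) to positive (in treatment).
#'
#' @param result_control,result_treatment `selection_result` objects.
#' @return list: `n_switching`, `median_abs_delta` (among switchers),
#'   `prop_neg_to_pos`, `n_shared`.
#' @export
sign_switch_analysis <- function(result_control, result_treatment) {
  shared <- intersect(result_control$gene, result_treatment$gene)
  a <- result_control$beta[match(shared, result_control$gene)]
  b <- result_treatment$beta[match(shared, result_treatment$gene)]
  sw <- sign(a) != sign(b) & a != 0 & b != 0
  list(n_switching = sum(sw),
       median_abs_delta = if (any(sw)) stats::median(abs(b - a)[sw]) else NA_real_,
       prop_neg_to_pos = if (any(sw)) mean(a[sw] < 0 & b[sw] > 0) else NA_real_,
       n_shared = length(shared))
}

#' Shift in selection intensity of DE genes (adaptive-plasticity test)
#'
#' Asks whether genes up- (or down-) regulated in a treatment are under
#' more positive (more negative) selection than non-responding genes: the
#' observed statistic is the difference in mean selection intensity between
#' the chosen DE-direction group and the non-DE group. For each permutation
#' the group labels are reassigned at random over the pooled intensities.
#' The default alternative follows the adaptive hypothesis (one-sided:
#' `up` expects a positive shift, `down` a negative one); `two.sided` is
#' available.
#'
#' @param result `selection_result` for the treatment.
#' @param de `de_result` for the same treatment vs Control.
#' @param direction `"up"` or `"down"`.
#' @param n_perm permutations.
#' @param seed optional seed.
#' @param alternative `"adaptive"` (default) or `"two.sided"`.
#' @param exact enumerate all assignments (tiny instances only).
#' @return list: `delta_mean` (DE group minus non-DE), `p`, group sizes.
#' @export
de_selection_shift_test <- function(result, de, direction = c("up", "down"),
                                    n_perm = 10000, seed = NULL,
                                    alternative = c("adaptive", "two.sided"),
                                    exact = FALSE) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  shared <- intersect(result$gene, de$gene)
  dir_map <- de$direction[match(shared, de$gene)]
  beta <- result$beta[match(shared, result$gene)]
  in_grp <- dir_map == direction
  non_de <- dir_map == "ns"
  if (!any(in_grp)) stop_input("no genes in the ", direction, " group")
  if (!any(non_de)) stop_input("no non-DE genes")
  vals <- c(beta[in_grp], beta[non_de])
  alt <- if (alternative == "two.sided") "two.sided" else
    if (direction == "up") "greater" else "less"
  res <- perm_test(vals, sum(in_grp),
                   function(g, ns) mean(g) - mean(ns),
                   n_perm = n_perm, seed = seed, alternative = alt,
                   exact = exact)
  list(delta_mean = res$observed, p = res$p,
       n_de = sum(in_grp), n_non_de = sum(non_de), n_perm = res$n_perm)
}
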