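#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample normalization for count
#' libraries. A reference sample is chosen as the one whose
#' 75th-percentile count fraction is closest to the mean across samples;
#' for every other sample, per-gene log-ratios (M) and average log
#' abundances (A) against the reference are computed over genes expressed
#' in both, doubly trimmed (30% on M, 5% on A by default), and averaged
#' with inverse-asymptotic-variance weights. Factors are rescaled to
#' geometric mean 1, so they are pure composition corrections on top of
#' library size.
#'
#' @param counts integer gene x sample matrix.
#' @param trim_m two-sided trim proportion on M-values.
#' @param trim_a two-sided trim proportion on A-values.
#' @return named numeric vector of strictly positive per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_input("TMM needs at least two samples")
  if (any(counts < 0)) stop_input("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop_input("sample(s) with all-zero counts: ",
               paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f75 <- apply(counts, 2L, function(y) stats::quantile(y, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    tmm_pair(counts[, s], lib[s], counts[, ref], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference: double-trimmed weighted mean of M.
tmm_pair <- function(y, ly, r, lr, trim_m, trim_a) {
  keep <- y > 0 & r > 0
  y <- y[keep]
  r <- r[keep]
  if (length(y) == 0L) return(1)
  m <- log2((y / ly) / (r / lr))
  a <- 0.5 * log2((y / ly) * (r / lr))
  w <- (ly - y) / (ly * y) + (lr - r) / (lr * r)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2) || all(w[keep2] == 0)) return(1)
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Counts per million
#'
#' `cpm = count / (library size x TMM factor) x 1e6`. With unit factors the
#' columns of the result sum to exactly one million.
#'
#' @param counts gene x sample count matrix.
#' @param factors per-sample scaling factors ([tmm_factors()] output or
#'   all ones).
#' @param log2 return `log2(cpm + 0.5)` instead of the raw scale.
#' @return object of class `norm_matrix`: list with `values`, `scale_tag`
#'   (`"cpm"` or `"log2cpm"`), `factors`, `lib_sizes`.
#' @export
cpm <- function(counts, factors = NULL, log2 = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_input("counts must be non-negative")
  lib <- colSums(counts)
  if (is.null(factors)) factors <- stats::setNames(rep(1, ncol(counts)),
                                                   colnames(counts))
  if (length(factors) != ncol(counts)) {
    stop_input("one factor per sample required")
  }
  v <- sweep(counts, 2L, lib * factors, "/") * 1e6
  if (log2) v <- base::log2(v + 0.5)
  structure(list(values = v,
                 scale_tag = if (log2) "log2cpm" else "cpm",
                 factors = factors, lib_sizes = lib),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("normalized matrix (%s): %d genes x %d samples\n",
              x$scale_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Within-condition z-scores per gene
#'
#' For the samples of one condition (optionally restricted further, e.g. to
#' reproducing females), each gene row is centred and scaled to unit SD
#' (denominator n - 1). Genes constant within the condition cannot be
#' standardized; they are dropped from the output and listed in `excluded`.
#'
#' @param norm a `norm_matrix` from [cpm()].
#' @param samples sample table with `sample_id` and `condition`.
#' @param condition which condition to standardize within.
#' @param subset optional character vector of sample ids (within the
#'   condition) to use.
#' @return `norm_matrix` with `scale_tag = "zscore"`, plus elements
#'   `condition` and `excluded` (gene ids dropped as constant).
#' @export
zscore_by_gene <- function(norm, samples, condition, subset = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  condition <- match.arg(condition, conditions())
  ids <- samples$sample_id[as.character(samples$condition) == condition]
  if (!is.null(subset)) ids <- intersect(ids, subset)
  if (length(ids) < 3L) {
    stop_input("need at least 3 samples in condition ", condition)
  }
  v <- norm$values[, ids, drop = FALSE]
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  ok <- is.finite(sd) & sd > 0
  z <- (v[ok, , drop = FALSE] - mu[ok]) / sd[ok]
  structure(list(values = z, scale_tag = "zscore",
                 factors = norm$factors[ids], lib_sizes = norm$lib_sizes[ids],
                 condition = condition,
                 excluded = rownames(v)[!ok]),
            class = "norm_matrix")
}

#' Permutation test on the median coefficient of variation
#'
#' Per-gene CV (= SD / mean of CPM, within condition) is computed in two
#' conditions; the statistic is the difference in median CV (b minus a).
#' Genes with zero mean in either condition are excluded. Significance is
#' assessed by pooling the two CV vectors and permuting condition labels;
#' the default is two-sided on |difference in medians|, with the add-one
#' p-value rule.
#'
#' @param norm a `norm_matrix` on the CPM scale.
#' @param samples sample table.
#' @param cond_a,cond_b the two conditions compared.
#' @param n_perm number of permutations.
#' @param seed optional seed for the permutation stream.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   for the signed difference median(b) - median(a).
#' @param exact enumerate all label assignments (tiny instances only).
#' @return list: `delta_median` (observed), `p`, per-condition CV vectors.
#' @export
cv_median_test <- function(norm, samples, cond_a, cond_b, n_perm = 10000,
                           seed = NULL, alternative = "two.sided",
                           exact = FALSE) {
  stopifnot(inherits(norm, "norm_matrix"))
  cv_of <- function(cond) {
    ids <- samples$sample_id[as.character(samples$condition) == cond]
    if (length(ids) < 2L) stop_input("condition ", cond, " has < 2 samples")
    v <- norm$values[, ids, drop = FALSE]
    mu <- rowMeans(v)
    cv <- apply(v, 1L, stats::sd) / mu
    cv[is.finite(cv) & mu > 0]
  }
  cv_a <- cv_of(cond_a)
  cv_b <- cv_of(cond_b)
  if (length(cv_a) == 0L || length(cv_b) == 0L) {
    stop_input("all genes excluded (zero means)")
  }
  res <- perm_test(c(cv_b, cv_a), length(cv_b),
                   function(b, a) stats::median(b) - stats::median(a),
                   n_perm = n_perm, seed = seed, alternative = alternative,
                   exact = exact)
  list(delta_median = res$observed, p = res$p,
       cv_a = cv_a, cv_b = cv_b, n_perm = res$n_perm)
}

# Keep genes reasonably expressed: CPM >= min_cpm in >= min_frac of samples.
# The standard low-expression filter applied before DE and selection.

#' Low-expression gene filter
#'
#' @param counts gene x sample count matrix.
#' @param min_cpm CPM threshold.
#' @param min_frac minimum fraction of samples at or above the threshold.
#' @return logical vector (TRUE = keep), named by gene.
#' @export
filter_genes <- function(counts, min_cpm = 1, min_frac = 0.25) {
  v <- cpm(counts)$values
  keep <- rowMeans(v >= min_cpm) >= min_frac
  stats::setNames(keep, rownames(counts))
}
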