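#' Family-mean expression per condition
#'
#' Mean normalized expression of each gene per (maternal) family per
#' condition. Cells with no individuals are NA, never zero-filled. Family
#' identity is the female (dam) family: the split-brood design places
#' full sisters of each family in every condition.
#'
#' @param norm `norm_matrix` (CPM by convention; pass log2 CPM for
#'   log-scale plasticity).
#' @param samples sample table with `family_f`.
#' @return `family_means`: list with `means` (gene x family x condition
#'   array) and `sizes` (family x condition counts).
#' @export
family_means <- function(norm, samples) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.null(samples$family_f)) stop_input("samples must carry family_f")
  fam <- sort(unique(samples$family_f))
  g <- nrow(norm$values)
  means <- array(NA_real_, c(g, length(fam), 4L),
                 dimnames = list(rownames(norm$values), fam, conditions()))
  sizes <- matrix(0L, length(fam), 4L, dimnames = list(fam, conditions()))
  for (cc in conditions()) {
    for (fm in fam) {
      ids <- samples$sample_id[samples$family_f == fm &
                               as.character(samples$condition) == cc]
      sizes[fm, cc] <- length(ids)
      if (length(ids) > 0L) {
        means[, fm, cc] <- rowMeans(norm$values[, ids, drop = FALSE])
      }
    }
  }
  structure(list(means = means, sizes = sizes), class = "family_means")
}

#' Per-family plasticity of each gene
#'
#' `p_gf = mean(treatment, f, g) - mean(Control, f, g)`: the difference in
#' family means between a treatment and Control, the split-family estimate
#' of a gene's plastic response. Families missing either cell are NA for
#' that gene.
#'
#' @param fm `family_means` object.
#' @param treatment treatment condition.
#' @return gene x family matrix of plasticity estimates.
#' @export
plasticity <- function(fm, treatment) {
  stopifnot(inherits(fm, "family_means"))
  treatment <- match.arg(treatment, conditions())
  p <- fm_slice(fm, treatment) - fm_slice(fm, "Control")
  if (all(!is.finite(p))) stop_input("no family has both cells")
  p
}

# one condition slice of the family-mean array, always a gene x family matrix
fm_slice <- function(fm, cc) {
  m <- fm$means[, , cc, drop = FALSE]
  dim(m) <- dim(fm$means)[1:2]
  dimnames(m) <- dimnames(fm$means)[1:2]
  m
}

#' Association between treatment expression level and plasticity
#'
#' Per gene, the Pearson correlation across families between the family's
#' mean expression in the treatment and its plastic change from Control;
#' summarized as the mean and median correlation over genes. Significance
#' of the mean correlation is assessed by permuting the family labels of
#' the plasticity matrix (one shared family permutation per iteration, so
#' the across-gene dependence structure is preserved), with the add-one
#' rule; the default alternative is one-sided in the sign of the observed
#' mean.
#'
#' @param fm `family_means` object.
#' @param treatment treatment condition.
#' @param n_perm permutations.
#' @param seed optional seed.
#' @return list: `per_gene_r`, `mean_r`, `median_r`, `p`, `n_families`.
#' @export
expression_plasticity_correlation <- function(fm, treatment, n_perm = 10000,
                                              seed = NULL) {
  pl <- plasticity(fm, treatment)
  ex <- fm_slice(fm, treatment)
  ok_fam <- colSums(is.finite(pl)) > 0
  pl <- pl[, ok_fam, drop = FALSE]
  ex <- ex[, ok_fam, drop = FALSE]
  if (ncol(pl) < 3L) stop_input("need at least 3 families")
  row_cor <- function(a, b) {
    ac <- a - rowMeans(a)
    bc <- b - rowMeans(b)
    rowSums(ac * bc) / sqrt(rowSums(ac^2) * rowSums(bc^2))
  }
  r <- row_cor(ex, pl)
  obs <- mean(r, na.rm = TRUE)
  b <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      sh <- sample.int(ncol(pl))
      rp <- mean(row_cor(ex, pl[, sh, drop = FALSE]), na.rm = TRUE)
      extreme <- if (obs >= 0) rp >= obs - 1e-12 else rp <= obs + 1e-12
      if (extreme) hits <- hits + 1L
    }
    hits
  })
  list(per_gene_r = r, mean_r = obs, median_r = stats::median(r, na.rm = TRUE),
       p = (b + 1) / (n_perm + 1), n_families = ncol(pl), n_perm = n_perm)
}

#' Mean family fitness within a condition
#'
#' @param samples sample table with filled `offspring`.
#' @param condition condition to summarize.
#' @param reproducing_only average over reproducing females only (default,
#'   consistent with the selection universe).
#' @return named vector of mean offspring per family.
#' @export
family_fitness <- function(samples, condition, reproducing_only = TRUE) {
  sel <- as.character(samples$condition) == condition
  if (reproducing_only) sel <- sel & samples$offspring > 0
  s <- samples[sel, ]
  if (nrow(s) == 0L) stop_input("no individuals in ", condition)
  tapply(s$offspring, s$family_f, mean)
}

#' Indirect selection on plasticity
#'
#' Per gene, the Pearson correlation across families between plasticity
#' (difference in family means, treatment minus Control) and mean family
#' fitness in the treatment. A family with high fitness and a strong
#' expression increase marks positive selection on that gene's plasticity.
#'
#' @param plast gene x family plasticity matrix from [plasticity()].
#' @param fitness named vector of family-mean fitness ([family_fitness()]).
#' @return numeric vector of per-gene correlations (NA where undefined).
#' @export
selection_on_plasticity <- function(plast, fitness) {
  fam <- intersect(colnames(plast), names(fitness))
  if (length(fam) < 3L) stop_input("need at least 3 families")
  if (stats::sd(fitness[fam]) == 0) {
    stop_input("family fitness is constant; correlation undefined")
  }
  p <- plast[, fam, drop = FALSE]
  f <- fitness[fam]
  pc <- p - rowMeans(p)
  fc <- f - mean(f)
  r <- as.numeric(pc %*% fc) / sqrt(rowSums(pc^2) * sum(fc^2))
  stats::setNames(r, rownames(plast))
}

#' Correlation of selection on expression with selection on plasticity
#'
#' Pearson correlation over genes between per-gene selection intensities on
#' expression levels and per-gene selection-on-plasticity estimates, with a
#' permutation p-value obtained by shuffling the gene assignment of one
#' vector (one-sided: permuted correlations at or above the observed one,
#' per the add-one rule; `two.sided` available).
#'
#' @param sel_expr `selection_result` (or named beta vector) for the
#'   treatment.
#' @param sel_plast named per-gene vector from [selection_on_plasticity()].
#' @param n_perm permutations.
#' @param seed optional seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exact enumerate all gene permutations (tiny instances only).
#' @return list: `r`, `p`, `n_genes`.
#' @export
selection_level_vs_plasticity <- function(sel_expr, sel_plast, n_perm = 10000,
                                          seed = NULL,
                                          alternative = c("greater", "two.sided"),
                                          exact = FALSE) {
  alternative <- match.arg(alternative)
  if (inherits(sel_expr, "selection_result")) {
    sel_expr <- stats::setNames(sel_expr$beta, sel_expr$gene)
  }
  shared <- intersect(names(sel_expr), names(sel_plast))
  shared <- shared[is.finite(sel_expr[shared]) & is.finite(sel_plast[shared])]
  if (length(shared) < 3L) stop_input("fewer than 3 shared genes")
  a <- sel_expr[shared]
  b <- sel_plast[shared]
  obs <- stats::cor(a, b)
  n <- length(shared)
  score <- function(r) {
    if (alternative == "greater") r >= obs - 1e-12 else abs(r) >= abs(obs) - 1e-12
  }
  if (exact) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, function(i) stats::cor(a, b[i]))
    return(list(r = obs, p = mean(score(rs)), n_genes = n, exact = TRUE))
  }
  hits <- with_seed(seed, {
    h <- 0L
    for (k in seq_len(n_perm)) {
      if (score(stats::cor(a, b[sample.int(n)]))) h <- h + 1L
    }
    h
  })
  list(r = obs, p = (hits + 1) / (n_perm + 1), n_genes = n, exact = FALSE)
}

# All permutations of seq_len(n), rows = permutations (n! grows fast; only
# used for exhaustive checks on tiny instances).
all_permutations <- function(n) {
  if (n > 8L) stop_input("exhaustive permutation only for n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
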