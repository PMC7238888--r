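# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 101, ...) {
  args <- list(n_families = 5, n_per_family_condition = 2, n_genes = 120,
               frac_responsive = 0.4, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_dataset <- function(seed = 101, ...) {
  simulate_dataset(tiny_config(seed = seed, ...))
}

# deterministic toy count matrix with gene/sample names
toy_counts <- function(values, n_genes = NULL, n_samples = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  m
}

# sample table for hand-built matrices
toy_samples <- function(condition, family = NULL, offspring = NULL,
                        ids = NULL) {
  n <- length(condition)
  data.frame(
    sample_id = ids %||% sprintf("s%02d", seq_len(n)),
    condition = factor(condition, levels = conditions()),
    family_f = family %||% sprintf("F%03d", seq_len(n)),
    family_m = sub("^F", "M", family %||% sprintf("F%03d", seq_len(n))),
    offspring = offspring %||% rep(NA_integer_, n),
    reproduced = if (is.null(offspring)) rep(TRUE, n) else offspring > 0,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive two-group permutation p-value oracle (independent of perm_test)
exhaustive_perm_p <- function(x, y, stat, two_sided = TRUE) {
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  obs <- stat(x, y)
  vals <- apply(idx, 2L, function(i) stat(pooled[i], pooled[-i]))
  if (two_sided) mean(abs(vals) >= abs(obs) - 1e-12)
  else mean(vals >= obs - 1e-12)
}

# independent enumerator of all permutations of 1..n (for exhaustive oracles)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      q <- p + (p >= k)
      out[[length(out) + 1L]] <- c(k, q)
    }
  }
  out
}
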