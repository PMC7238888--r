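#' Canonical condition labels
#'
#' The four rearing environments of the split-family design, in canonical
#' order: benign control (33C / 70% r.h.), drought (33C / 30%), heat
#' (37C / 70%) and combined heat-drought (37C / 30%).
#'
#' @return Character vector of length four.
#' @export
conditions <- function() c("Control", "Dry", "Hot", "Hot-Dry")

# Abort with a classed condition so callers/tests can distinguish user error.
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("stressel_error", "error")))
}

check_conditions <- function(x, where = "samples") {
  bad <- setdiff(unique(as.character(x)), conditions())
  if (length(bad) > 0L) {
    stop_input("unknown condition label(s) in ", where, ": ",
               paste(bad, collapse = ", "))
  }
  factor(as.character(x), levels = conditions())
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG stream.
# A NULL seed leaves the global stream untouched (draws still consume it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Permutation p-value for a two-group statistic
#'
#' Shared engine for the label-shuffling tests in the package. Values are
#' pooled, group labels are reassigned at random (or exhaustively), the
#' statistic recomputed, and the p-value formed with the add-one rule
#' (b + 1) / (B + 1), which never reports exactly zero. In exhaustive mode
#' every assignment of `n_a` pooled values to the first group is enumerated
#' and the p-value is the exact proportion of assignments at least as
#' extreme as the observed one (the observed labelling is one of them).
#'
#' @param values numeric vector of pooled values.
#' @param n_a size of the first group (the first `n_a` entries of `values`
#'   are the observed first group).
#' @param stat function taking (a, b) and returning a scalar statistic.
#' @param n_perm number of random permutations.
#' @param seed optional integer seed for the permutation stream.
#' @param alternative `"two.sided"` compares |stat|, `"greater"`/`"less"`
#'   compare signed values.
#' @param exact enumerate all label assignments instead of sampling;
#'   requires `choose(n, n_a)` to be modest.
#' @return list with `observed`, `p`, `n_perm` (or number of assignments).
#' @keywords internal
perm_test <- function(values, n_a, stat, n_perm = 10000, seed = NULL,
                      alternative = c("two.sided", "greater", "less"),
                      exact = FALSE) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n_a < 1L || n_a >= n) stop_input("invalid group size for permutation test")
  if (!exact && n_perm < 1L) stop_input("n_perm must be >= 1")
  obs <- stat(values[seq_len(n_a)], values[-seq_len(n_a)])
  score <- switch(alternative,
    two.sided = function(s) abs(s) >= abs(obs) - 1e-12,
    greater   = function(s) s >= obs - 1e-12,
    less      = function(s) s <= obs + 1e-12)
  if (exact) {
    idx <- utils::combn(n, n_a)
    stats <- apply(idx, 2L, function(i) stat(values[i], values[-i]))
    return(list(observed = obs, p = mean(score(stats)), n_perm = ncol(idx),
                exact = TRUE))
  }
  b <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      i <- sample.int(n, n_a)
      if (score(stat(values[i], values[-i]))) hits <- hits + 1L
    }
    hits
  })
  list(observed = obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
       exact = FALSE)
}

# Pearson chi-square on a contingency table, no continuity correction.
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = e)
}
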