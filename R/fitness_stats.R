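#' Per-condition fitness summaries
#'
#' Counts, reproducing counts, and mean / SE / variance of offspring number
#' among reproducing females, per condition.
#'
#' @param samples sample table with filled `offspring`.
#' @return data.frame with one row per condition (`n`, `n_reproducing`,
#'   `mean_offspring`, `se`, `variance`); conditions with no reproducing
#'   females carry NA summaries.
#' @export
summarize_fitness <- function(samples) {
  if (is.null(samples$offspring) || all(is.na(samples$offspring))) {
    stop_input("offspring counts missing")
  }
  cond <- check_conditions(samples$condition)
  out <- lapply(conditions(), function(cc) {
    w <- samples$offspring[cond == cc]
    rep_w <- w[w > 0]
    data.frame(condition = cc, n = length(w), n_reproducing = length(rep_w),
               mean_offspring = if (length(rep_w)) mean(rep_w) else NA_real_,
               se = if (length(rep_w) > 1)
                 stats::sd(rep_w) / sqrt(length(rep_w)) else NA_real_,
               variance = if (length(rep_w) > 1) stats::var(rep_w) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Factorial temperature x humidity model of offspring number
#'
#' Saturated OLS on the 2x2 factorial with treatment coding (Control as
#' reference): intercept = Control cell mean, `heat` = Hot - Control,
#' `drought` = Dry - Control, `interaction` = Hot-Dry - Hot - Dry + Control.
#' Fitted cell means reproduce observed cell means exactly. Standard errors
#' come from a nonparametric bootstrap resampling whole female families,
#' honoring the within-family correlation that the original mixed model
#' absorbed with random family effects.
#'
#' @param samples sample table.
#' @param reproducing_only restrict to females with offspring (default).
#' @param n_boot bootstrap replicates for the SEs.
#' @param seed optional seed for the bootstrap.
#' @return `factorial_fit`: list with `coefficients` (intercept, heat,
#'   drought, interaction), `se` (bootstrap), `se_ols`, `cell_means`, `n`.
#' @export
factorial_fit <- function(samples, reproducing_only = TRUE, n_boot = 200,
                          seed = NULL) {
  cond <- check_conditions(samples$condition)
  d <- data.frame(offspring = samples$offspring,
                  family = samples$family_f,
                  heat = as.integer(cond %in% c("Hot", "Hot-Dry")),
                  dry = as.integer(cond %in% c("Dry", "Hot-Dry")),
                  condition = cond)
  if (reproducing_only) d <- d[d$offspring > 0, ]
  if (length(unique(d$condition)) < 4L) {
    stop_input("all four conditions must contain (reproducing) females")
  }
  fit_once <- function(dd) {
    fit <- stats::lm(offspring ~ heat * dry, data = dd)
    stats::setNames(stats::coef(fit),
                    c("intercept", "heat", "drought", "interaction"))
  }
  co <- fit_once(d)
  se_ols <- sqrt(diag(stats::vcov(stats::lm(offspring ~ heat * dry, data = d))))
  names(se_ols) <- names(co)
  fams <- unique(d$family)
  rows_by_fam <- split(seq_len(nrow(d)), d$family)
  boot <- with_seed(seed, {
    reps <- matrix(NA_real_, n_boot, 4L)
    for (b in seq_len(n_boot)) {
      take <- sample(fams, length(fams), replace = TRUE)
      dd <- d[unlist(rows_by_fam[take], use.names = FALSE), ]
      if (length(unique(dd$condition)) == 4L) reps[b, ] <- fit_once(dd)
    }
    reps
  })
  se <- apply(boot, 2L, stats::sd, na.rm = TRUE)
  names(se) <- names(co)
  cells <- tapply(d$offspring, d$condition, mean)
  structure(list(coefficients = co, se = se, se_ols = se_ols,
                 cell_means = cells, n = nrow(d), n_boot = n_boot,
                 reproducing_only = reproducing_only),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("Factorial fitness model (n = %d%s; family bootstrap, B = %d)\n",
              x$n, if (x$reproducing_only) " reproducing females" else "",
              x$n_boot))
  tab <- cbind(estimate = x$coefficients, boot_se = x$se)
  print(round(tab, 3))
  invisible(x)
}

#' @export
coef.factorial_fit <- function(object, ...) object$coefficients

#' Chi-square test on the proportion of reproducing females
#'
#' Pearson chi-square (df = 3) on the 2 x 4 reproduced-by-condition table.
#' (The original analysis used a binomial GLMM with family random effects;
#' this contingency test addresses the same question with a simpler
#' estimator and is not expected to reproduce the GLMM statistic.)
#'
#' @param samples sample table with `reproduced` (or filled `offspring`,
#'   from which reproduction is inferred as offspring > 0).
#' @return list: `chisq`, `df`, `p`, `proportions`, `table`.
#' @export
reproduction_proportion_test <- function(samples) {
  cond <- check_conditions(samples$condition)
  rep_flag <- if (!is.null(samples$reproduced)) samples$reproduced else
    samples$offspring > 0
  tab <- table(factor(rep_flag, levels = c(TRUE, FALSE)), cond)
  cs <- pearson_chisq(tab)
  list(chisq = cs$statistic, df = cs$df, p = cs$p,
       proportions = tab[1, ] / colSums(tab), table = tab)
}
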