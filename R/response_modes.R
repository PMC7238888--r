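# The 20 predefined combined-stress response profiles over
# (Control, Dry, Hot, Hot-Dry), control fixed at level 0. Reconstructed from
# the five category definitions so that the category counts total 20:
#   similar       same response to both single stressors and the combination
#   independent   response to exactly one single stressor, kept in combination
#   combinatorial similar single-stress levels, different combined response
#   cancelled     single-stress response(s) return to control when combined
#   prioritized   opposing single-stress responses, one wins in combination
profile_bank_definition <- function() {
  p <- rbind(
    c("similar",        0,  1,  1,  1),
    c("similar",        0, -1, -1, -1),
    c("independent",    0,  1,  0,  1),
    c("independent",    0, -1,  0, -1),
    c("independent",    0,  0,  1,  1),
    c("independent",    0,  0, -1, -1),
    c("combinatorial",  0,  0,  0,  1),
    c("combinatorial",  0,  0,  0, -1),
    c("combinatorial",  0,  1,  1, -1),
    c("combinatorial",  0, -1, -1,  1),
    c("cancelled",      0,  1,  0,  0),
    c("cancelled",      0, -1,  0,  0),
    c("cancelled",      0,  0,  1,  0),
    c("cancelled",      0,  0, -1,  0),
    c("cancelled",      0,  1,  1,  0),
    c("cancelled",      0, -1, -1,  0),
    c("prioritized",    0,  1, -1,  1),
    c("prioritized",    0,  1, -1, -1),
    c("prioritized",    0, -1,  1,  1),
    c("prioritized",    0, -1,  1, -1))
  out <- data.frame(category = p[, 1],
                    Control = as.numeric(p[, 2]),
                    Dry = as.numeric(p[, 3]),
                    Hot = as.numeric(p[, 4]),
                    `Hot-Dry` = as.numeric(p[, 5]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$label <- sprintf("%s_CT0_D%+d_H%+d_HD%+d", out$category,
                       out$Dry, out$Hot, out$`Hot-Dry`)
  out[, c("label", "category", conditions())]
}

#' The bank of 20 predefined response profiles
#'
#' Each profile assigns an idealized expression level in {-1, 0, +1} to the
#' four conditions (Control fixed at 0) and carries one of five response-mode
#' categories: `similar`, `independent`, `combinatorial`, `prioritized`,
#' `cancelled`. Genes are classified by Pearson correlation against these
#' profiles. The bank is plain data and can be written/read as TSV
#' ([write_profile_bank()], [read_profile_bank()]) so an alternative
#' enumeration can be swapped in without code change.
#'
#' @return `profile_bank`: data.frame with columns `label`, `category`,
#'   `Control`, `Dry`, `Hot`, `Hot-Dry` (20 rows).
#' @export
build_profile_bank <- function() {
  structure(profile_bank_definition(),
            class = c("profile_bank", "data.frame"))
}

validate_profile_bank <- function(bank) {
  need <- c("label", "category", conditions())
  if (!all(need %in% names(bank))) {
    stop_input("profile bank must have columns ", paste(need, collapse = ", "))
  }
  if (any(bank$Control != 0)) stop_input("Control level must be 0")
  if (anyDuplicated(bank$label)) stop_input("duplicate profile labels")
  lv <- as.matrix(bank[, conditions()])
  if (anyDuplicated(lv)) stop_input("duplicate profiles")
  structure(as.data.frame(bank), class = c("profile_bank", "data.frame"))
}

#' Classify one gene's response mode
#'
#' Expands each profile into a per-sample vector through the sample's
#' condition (so conditions are weighted by their sample counts, matching a
#' correlation of per-sample normalized counts against the profile) and
#' assigns the gene to the profile with the highest Pearson correlation.
#' The classification is invariant to affine rescaling of the gene vector.
#' Correlation ties (measure-zero for noisy data) are broken by the larger
#' margin over the category's mean correlation, then by profile label;
#' whether a tie occurred is recorded.
#'
#' @param gene_values per-sample normalized expression (CPM scale by
#'   convention) for one gene.
#' @param samples sample table aligned with `gene_values` (or with names of
#'   `gene_values` matching `sample_id`).
#' @param bank a [build_profile_bank()] object.
#' @return one-row data.frame: `profile`, `category`, `r`, `runner_up_r`,
#'   `margin`, `tied`; or NULL-like NA row for a constant gene.
#' @export
assign_mode <- function(gene_values, samples, bank = build_profile_bank()) {
  bank <- validate_profile_bank(bank)
  cond <- as.character(samples$condition)
  if (!all(conditions() %in% cond)) {
    stop_input("all four conditions must be present")
  }
  if (stats::sd(gene_values) == 0 || any(!is.finite(gene_values))) {
    return(data.frame(profile = NA_character_, category = NA_character_,
                      r = NA_real_, runner_up_r = NA_real_,
                      margin = NA_real_, tied = NA,
                      stringsAsFactors = FALSE))
  }
  lv <- as.matrix(bank[, conditions()])
  expanded <- lv[, match(cond, conditions()), drop = FALSE]  # profile x sample
  r <- as.numeric(stats::cor(gene_values, t(expanded)))
  best <- which(r >= max(r) - 1e-12)
  tied <- length(best) > 1L
  if (tied) {
    cat_mean <- tapply(r, bank$category, mean)
    marg <- r[best] - cat_mean[bank$category[best]]
    best <- best[order(-marg, bank$label[best])]
  }
  b <- best[1L]
  runner <- max(r[-b])
  data.frame(profile = bank$label[b], category = bank$category[b],
             r = r[b], runner_up_r = runner, margin = r[b] - runner,
             tied = tied, stringsAsFactors = FALSE)
}

#' Classify all responsive genes and summarize category proportions
#'
#' Restricts to the union of DE genes over the three treatment-vs-Control
#' contrasts, classifies each against the profile bank, and tabulates
#' category and profile (subcategory) proportions.
#'
#' Correlation against the symmetric profiles is scale dependent: on the
#' raw CPM scale a k-fold down-regulation spans a much smaller interval
#' than a k-fold up-regulation, which systematically misassigns mixed-sign
#' (prioritized/combinatorial) profiles. Pass log2 CPM
#' (`cpm(..., log2 = TRUE)`), as the pipeline does, for a symmetric scale.
#'
#' @param norm `norm_matrix` of normalized expression (CPM scale).
#' @param samples sample table.
#' @param de_results list of `de_result` objects for the Dry, Hot and
#'   Hot-Dry contrasts against Control (any order); the union of their
#'   `q <= alpha` genes defines the responsive set. Alternatively a
#'   character vector of gene ids.
#' @param bank profile bank.
#' @param alpha FDR cutoff defining DE within each contrast.
#' @return `mode_classification`: list with `assignments` (per-gene table),
#'   `category_freq` and `profile_freq` (proportion tables), `n_unclassified`.
#' @export
classify_responsive <- function(norm, samples, de_results,
                                bank = build_profile_bank(), alpha = 0.05) {
  bank <- validate_profile_bank(bank)
  if (is.character(de_results)) {
    responsive <- unique(de_results)
  } else {
    if (inherits(de_results, "de_result")) de_results <- list(de_results)
    responsive <- unique(unlist(lapply(de_results, function(d) {
      d$gene[d$q <= alpha]
    })))
  }
  responsive <- intersect(responsive, rownames(norm$values))
  if (length(responsive) == 0L) {
    warning("empty responsive set; nothing to classify")
    return(structure(list(assignments = data.frame(),
                          category_freq = table(character()),
                          profile_freq = table(character()),
                          n_unclassified = 0L),
                     class = "mode_classification"))
  }
  rows <- lapply(responsive, function(gid) {
    assign_mode(norm$values[gid, ], samples, bank)
  })
  assignments <- cbind(data.frame(gene = responsive, stringsAsFactors = FALSE),
                       do.call(rbind, rows))
  ok <- !is.na(assignments$category)
  cat_freq <- table(factor(assignments$category[ok],
                           levels = unique(bank$category))) / sum(ok)
  prof_freq <- table(factor(assignments$profile[ok],
                            levels = bank$label)) / sum(ok)
  structure(list(assignments = assignments,
                 category_freq = cat_freq,
                 profile_freq = prof_freq,
                 n_unclassified = sum(!ok)),
            class = "mode_classification")
}

#' @export
print.mode_classification <- function(x, ...) {
  cat(sprintf("Response-mode classification of %d genes (%d unclassifiable)\n",
              nrow(x$assignments), x$n_unclassified))
  if (length(x$category_freq)) {
    pct <- sort(100 * x$category_freq, decreasing = TRUE)
    for (k in names(pct)) cat(sprintf("  %-13s %5.1f%%\n", k, pct[[k]]))
  }
  invisible(x)
}

#' Write / read a profile bank as TSV
#'
#' @param bank profile bank.
#' @param path file path.
#' @return `read_profile_bank` returns a validated `profile_bank`.
#' @export
write_profile_bank <- function(bank, path) {
  utils::write.table(as.data.frame(bank), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_bank
#' @export
read_profile_bank <- function(path) {
  validate_profile_bank(utils::read.delim(path, check.names = FALSE,
                                          stringsAsFactors = FALSE))
}
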