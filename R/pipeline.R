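#' Read / write a gene x sample count matrix as TSV
#'
#' The TSV carries gene ids in the first column and one integer column per
#' sample. Duplicate gene ids, negative or non-integer entries are rejected
#' with the offender named.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("count table needs gene ids plus >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_input("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop_input("counts must be finite numbers")
  }
  if (any(m < 0) || any(m != round(m))) {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    stop_input("non-integer or negative count at gene ", ids[bad[1]],
               ", sample ", colnames(m)[bad[2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_counts
#' @param counts matrix to write.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Columns: `sample_id`, `condition`, `family_f`, `family_m`, `offspring`,
#' `reproduced`.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "family_f", "family_m",
            "offspring", "reproduced")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_input("sample table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop_input("duplicate sample_id")
  df$condition <- check_conditions(df$condition)
  df$reproduced <- as.logical(df$reproduced)
  df
}

#' @rdname read_samples
#' @param samples table to write.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates normalize -> DE -> response modes -> selection ->
#' plasticity -> fitness on a counts + samples pair (either given as files
#' or freshly simulated), writing one TSV per stage plus a JSON summary of
#' the headline statistics and a log of seeds and versions. Reruns with the
#' same configuration and seed are bit-identical.
#'
#' @param config a list or the path of a YAML file. Recognized keys:
#'   `counts` / `samples` (paths), or `simulate` (argument list for
#'   [sim_config()]; a nested `selection_truth` list is passed to
#'   [selection_truth()]); `out_dir`; `alpha` (FDR, default 0.05);
#'   `min_cpm` / `min_frac` (expression filter); `de_method`; `n_perm`
#'   (default 1000); `seed`; `profile_bank` (TSV path, optional);
#'   `selection_include_zero` (include zero-offspring females in the
#'   selection universe; default FALSE, reproducing only); `stages`
#'   (subset of normalize, de, modes, selection, plasticity, fitness).
#' @param out_dir output directory (overrides the config key).
#' @return (invisibly) the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop_input("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  min_cpm <- config$min_cpm %||% 1
  min_frac <- config$min_frac %||% 0.25
  n_perm <- config$n_perm %||% 1000
  de_method <- config$de_method %||% "welch_logcpm"
  seed <- config$seed
  stages <- config$stages %||%
    c("normalize", "de", "modes", "selection", "plasticity", "fitness")
  bank <- if (!is.null(config$profile_bank)) {
    read_profile_bank(config$profile_bank)
  } else build_profile_bank()
  log_lines <- c(sprintf("stressel %s",
                         as.character(utils::packageVersion("stressel"))),
                 sprintf("R %s", R.version.string),
                 sprintf("seed %s", if (is.null(seed)) "unset" else seed),
                 sprintf("run at steps: %s", paste(stages, collapse = ", ")))
  summary <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(sim_args$selection_truth) &&
        !inherits(sim_args$selection_truth, "selection_truth_config")) {
      sim_args$selection_truth <- do.call(selection_truth,
                                          sim_args$selection_truth)
    }
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    ds <- simulate_dataset(do.call(sim_config, sim_args))
    counts <- ds$counts
    samples <- ds$samples
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write_samples(samples, file.path(out_dir, "samples.tsv"))
    log_lines <- c(log_lines, sprintf("simulated %d genes x %d samples",
                                      nrow(counts), nrow(samples)))
  } else {
    counts <- read_counts(config$counts %||% stop_input("counts path required"))
    samples <- read_samples(config$samples %||%
                              stop_input("samples path required"))
    if (!identical(colnames(counts), samples$sample_id)) {
      stop_input("count columns and sample table rows must match")
    }
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  norm <- NULL
  if ("normalize" %in% stages) {
    norm <- run_stage("normalize", {
      f <- tmm_factors(counts)
      utils::write.table(
        data.frame(sample_id = names(f), tmm_factor = f,
                   lib_size = colSums(counts)),
        file.path(out_dir, "tmm_factors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      cpm(counts, f)
    })
  }

  de <- list()
  if ("de" %in% stages) {
    de <- run_stage("de", {
      out <- list()
      for (trt in c("Dry", "Hot", "Hot-Dry")) {
        d <- de_test(counts, samples, "Control", trt, method = de_method,
                     alpha = alpha, min_cpm = min_cpm, min_frac = min_frac)
        utils::write.table(d, file.path(out_dir, paste0(
          "de_", gsub("-", "", trt), "_vs_Control.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        out[[trt]] <- d
      }
      summary$n_de <- lapply(out, function(d) sum(d$direction != "ns"))
      out
    })
  }

  modes <- NULL
  if ("modes" %in% stages && length(de) == 3L) {
    modes <- run_stage("modes", {
      lnorm <- cpm(counts, norm$factors, log2 = TRUE)
      mc <- classify_responsive(lnorm, samples, de, bank, alpha = alpha)
      if (nrow(mc$assignments)) {
        utils::write.table(mc$assignments,
                           file.path(out_dir, "response_modes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(category = names(mc$category_freq),
                     proportion = as.numeric(mc$category_freq)),
          file.path(out_dir, "response_mode_summary.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summary$mode_proportions <- as.list(mc$category_freq)
      mc
    })
  }

  sel <- list()
  if ("selection" %in% stages) {
    include_zero <- isTRUE(config$selection_include_zero)
    sel <- run_stage("selection", {
      out <- list()
      for (cc in conditions()) {
        keep <- samples$sample_id[as.character(samples$condition) == cc &
                                    (include_zero | samples$offspring > 0)]
        if (length(keep) < 3L) next
        z <- zscore_by_gene(norm, samples, cc, subset = keep)
        w <- relative_fitness(
          samples$offspring[match(colnames(z$values), samples$sample_id)])
        r <- selection_gradients(z, w, cc)
        utils::write.table(r, file.path(out_dir, paste0(
          "selection_", gsub("-", "", cc), ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        out[[cc]] <- r
      }
      if (length(out)) {
        ss <- selection_summary(out)
        utils::write.table(ss, file.path(out_dir, "selection_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$median_abs_beta <- stats::setNames(
          as.list(ss$median_abs_beta), ss$condition)
      }
      if (length(out) >= 2L) {
        pairs <- utils::combn(names(out), 2L)
        cors <- apply(pairs, 2L, function(pp) {
          cross_condition_correlation(out[[pp[1]]], out[[pp[2]]])$r
        })
        cor_tab <- data.frame(condition_a = pairs[1, ],
                              condition_b = pairs[2, ], r = cors)
        utils::write.table(cor_tab,
                           file.path(out_dir, "selection_correlations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$selection_correlations <- stats::setNames(
          as.list(cor_tab$r), paste(cor_tab$condition_a, cor_tab$condition_b,
                                    sep = "_"))
      }
      if ("Control" %in% names(out) && length(de) == 3L) {
        shift <- list()
        for (trt in intersect(names(de), names(out))) {
          for (dir in c("up", "down")) {
            st <- tryCatch(de_selection_shift_test(
              out[[trt]], de[[trt]], dir, n_perm = n_perm,
              seed = if (is.null(seed)) NULL else seed + 11L),
              stressel_error = function(e) NULL)
            if (!is.null(st)) {
              shift[[paste(trt, dir, sep = "_")]] <-
                list(delta_mean = st$delta_mean, p = st$p)
            }
          }
        }
        summary$shift_tests <- shift
      }
      out
    })
  }

  if ("plasticity" %in% stages && length(sel) > 0L) {
    run_stage("plasticity", {
      fm <- family_means(norm, samples)
      pl_sum <- list()
      for (trt in c("Dry", "Hot", "Hot-Dry")) {
        ok <- tryCatch({
          epc <- expression_plasticity_correlation(
            fm, trt, n_perm = n_perm,
            seed = if (is.null(seed)) NULL else seed + 23L)
          ff <- family_fitness(samples, trt)
          sp <- selection_on_plasticity(plasticity(fm, trt), ff)
          res <- if (trt %in% names(sel)) {
            selection_level_vs_plasticity(
              sel[[trt]], sp, n_perm = n_perm,
              seed = if (is.null(seed)) NULL else seed + 29L)
          } else NULL
          pl_sum[[trt]] <- list(
            mean_expr_plasticity_r = epc$mean_r,
            median_expr_plasticity_r = epc$median_r,
            expr_plasticity_p = epc$p,
            sel_vs_plasticity_r = if (is.null(res)) NULL else res$r,
            sel_vs_plasticity_p = if (is.null(res)) NULL else res$p)
          TRUE
        }, stressel_error = function(e) FALSE)
        if (!ok) next
      }
      summary$plasticity <- pl_sum
    })
  }

  if ("fitness" %in% stages) {
    run_stage("fitness", {
      fs <- summarize_fitness(samples)
      utils::write.table(fs, file.path(out_dir, "fitness_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$mean_offspring <- stats::setNames(as.list(fs$mean_offspring),
                                                 fs$condition)
      rp <- reproduction_proportion_test(samples)
      summary$reproduction_chisq <- rp$chisq
      ff <- tryCatch(factorial_fit(samples,
                                   seed = if (is.null(seed)) NULL else
                                     seed + 31L),
                     stressel_error = function(e) NULL)
      if (!is.null(ff)) {
        utils::write.table(
          data.frame(term = names(ff$coefficients),
                     estimate = ff$coefficients, boot_se = ff$se),
          file.path(out_dir, "factorial_fit.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        summary$factorial <- as.list(ff$coefficients)
      }
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
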