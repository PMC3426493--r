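# End-to-end orchestration: configuration validation and the pipeline from
# trio alignments (plus optional domain and expression tables) to the full
# set of TSV reports.

#' Build and validate a pipeline configuration
#'
#' @param trios Named list of [codon_trio()] objects.
#' @param architectures Optional named list (by pair id) of architectures,
#'   as in [test_asymmetry()].
#' @param expression Optional named list (by pair id) of
#'   `list(copy1 = , copy2 = )` [expression_profile()] pairs.
#' @param levels Asymmetry levels to run.
#' @param engine `"counting"` (default), `"likelihood"`, or `"both"` (adds
#'   the whole-protein likelihood-ratio test next to the Fisher test).
#' @param fdr,alpha,cluster_alpha,ds_lo,ds_hi Thresholds.
#' @param cda_background As in [test_asymmetry()].
#' @param seed Mandatory seed for the stochastic steps.
#' @param out_dir Output directory for the TSV reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(trios, architectures = NULL, expression = NULL,
                            levels = c("WPA", "CDA", "DSA", "LINKER"),
                            engine = c("counting", "likelihood", "both"),
                            fdr = 0.10, alpha = 0.05, cluster_alpha = 0.05,
                            ds_lo = 0.2, ds_hi = 2.0,
                            cda_background = "protein",
                            seed, out_dir = tempfile("dupasym_run_")) {
  engine <- match.arg(engine)
  levels <- match.arg(levels, several.ok = TRUE)
  for (thr in c(fdr, alpha, cluster_alpha)) {
    if (!is.finite(thr) || thr < 0 || thr > 1) {
      stop_typed("config_error", "thresholds must lie in [0, 1]")
    }
  }
  if (!is.finite(ds_lo) || !is.finite(ds_hi) || ds_lo < 0 || ds_lo > ds_hi) {
    stop_typed("config_error", "require 0 <= ds_lo <= ds_hi")
  }
  if (missing(seed) || is.null(seed)) {
    stop_typed("config_error", "a seed is mandatory")
  }
  if (is.null(names(trios))) {
    names(trios) <- vapply(trios, function(x) x$pair_id, character(1))
  }
  structure(list(trios = trios, architectures = architectures,
                 expression = expression, levels = levels, engine = engine,
                 fdr = fdr, alpha = alpha, cluster_alpha = cluster_alpha,
                 ds_lo = ds_lo, ds_hi = ds_hi,
                 cda_background = cda_background, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full asymmetry pipeline
#'
#' Applies the admission filters, runs the Fisher-exact asymmetry tests at
#' the configured levels (and the whole-protein likelihood-ratio test when
#' the likelihood engine is enabled), then the downstream pattern analyses
#' (clustering of non-synonymous changes, domain assortment, faster-copy
#' concordance, family asymmetry frequency, interleaving runs test),
#' BLOSUM62 substitution scoring, and expression divergence when expression
#' profiles are supplied. Writes one TSV per analysis plus an exclusions
#' table and a JSON run manifest into `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory results (also written
#'   to disk): `asymmetry` (per level), `branch_counts`, `exclusions`,
#'   `clustering`, `assortment`, `concordance`, `family_frequency`,
#'   `interleaving`, `scores`, `score_comparison`, `expression`,
#'   `lrt` (when enabled) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  # per-pair branch counts
  bc_rows <- lapply(names(config$trios), function(pid) {
    bc <- suppressWarnings(branch_counts(config$trios[[pid]]))
    cbind(pair_id = pid, as.data.frame(bc))
  })
  results$branch_counts <- do.call(rbind, bc_rows)
  .write_tsv(results$branch_counts, config$out_dir, "branch_counts")

  # asymmetry tests per level
  results$asymmetry <- list()
  excl_all <- list()
  for (lv in config$levels) {
    if (lv != "WPA" && is.null(config$architectures)) next
    res <- test_asymmetry(config$trios, config$architectures, level = lv,
                          fdr = config$fdr, alpha = config$alpha,
                          ds_lo = config$ds_lo, ds_hi = config$ds_hi,
                          cda_background = config$cda_background)
    results$asymmetry[[lv]] <- res
    .write_tsv(as.data.frame(res), config$out_dir,
               paste0("asymmetry_", tolower(lv)))
    ex <- attr(res, "exclusions")
    if (nrow(ex)) excl_all[[lv]] <- cbind(level = lv, ex)
  }
  results$exclusions <- if (length(excl_all)) do.call(rbind, excl_all) else
    data.frame(level = character(0), pair_id = character(0),
               reason = character(0))
  .write_tsv(results$exclusions, config$out_dir, "exclusions")

  # likelihood engine: whole-protein LRT next to the Fisher test
  if (config$engine %in% c("likelihood", "both")) {
    wpa <- results$asymmetry[["WPA"]]
    admitted <- if (!is.null(wpa)) wpa$pair_id else names(config$trios)
    lrt_rows <- lapply(admitted, function(pid) {
      lr <- lrt_test(config$trios[[pid]])
      ok <- !is.na(lr$p_value)
      data.frame(pair_id = pid,
                 lnL_free = if (ok) lr$free$lnL else NA_real_,
                 lnL_constrained = if (ok) lr$constrained$lnL else NA_real_,
                 statistic = lr$statistic, p_value = lr$p_value,
                 converged = ok)
    })
    results$lrt <- do.call(rbind, lrt_rows)
    results$lrt$q_value <- bh_fdr(results$lrt$p_value)
    .write_tsv(results$lrt, config$out_dir, "lrt_wpa")
  }

  dsa <- results$asymmetry[["DSA"]]
  have_arch <- function(pid) {
    !is.null(config$architectures) && !is.null(config$architectures[[pid]])
  }

  if (!is.null(dsa) && nrow(dsa)) {
    # clustering of non-synonymous changes (multi-domain proteins only)
    clus_rows <- list()
    for (pid in unique(dsa$pair_id)) {
      arch <- .resolve_architecture(config$architectures[[pid]])
      if (nrow(arch$intervals) < 2L) next
      for (cp in c("copy1", "copy2")) {
        clus_rows[[length(clus_rows) + 1]] <-
          clustering_test(config$trios[[pid]], arch, copy = cp,
                          alpha = config$cluster_alpha)
      }
    }
    if (length(clus_rows)) {
      results$clustering <- do.call(rbind, clus_rows)
      .write_tsv(results$clustering, config$out_dir, "clustering")
    }

    # assortment among multi-domain proteins
    flags <- list()
    for (pid in unique(dsa$pair_id)) {
      sub <- dsa[dsa$pair_id == pid, ]
      if (nrow(sub) >= 2L) flags[[pid]] <- sub$asymmetric
    }
    if (length(flags)) {
      results$assortment <- assortment_analysis(flags, seed = config$seed)
      .write_tsv(as.data.frame(results$assortment), config$out_dir,
                 "assortment")
    }

    results$concordance <- faster_copy_concordance(dsa)
    .write_tsv(as.data.frame(results$concordance), config$out_dir,
               "concordance")

    results$family_frequency <- family_asymmetry_frequency(dsa)
    .write_tsv(results$family_frequency, config$out_dir, "family_frequency")

    # BLOSUM62 substitution severity, asymmetric vs symmetric domains
    score_rows <- lapply(unique(dsa$pair_id), function(pid) {
      domain_scores(config$trios[[pid]], config$architectures[[pid]])
    })
    sc <- do.call(rbind, score_rows)
    key_sc <- paste(sc$pair_id, sc$domain_name)
    key_dsa <- paste(dsa$pair_id, dsa$domain_name)
    sc$asymmetric <- dsa$asymmetric[match(key_sc, key_dsa)]
    results$scores <- sc
    .write_tsv(sc, config$out_dir, "domain_scores")
    a_sc <- sc$mean_score[sc$asymmetric %in% TRUE & !is.na(sc$mean_score)]
    s_sc <- sc$mean_score[sc$asymmetric %in% FALSE & !is.na(sc$mean_score)]
    if (length(a_sc) && length(s_sc)) {
      results$score_comparison <- compare_score_distributions(a_sc, s_sc)
    }
  }

  # interleaving runs test over copy-specific substitution positions
  run_rows <- list()
  for (pid in names(config$trios)) {
    pos <- substitution_positions(config$trios[[pid]])
    if (length(unique(pos$copy)) != 2L) next
    rt <- interleaving_runs_test(pos$copy)
    run_rows[[length(run_rows) + 1]] <- data.frame(
      pair_id = pid, runs = rt$runs, n_copy1 = rt$n1, n_copy2 = rt$n2,
      p_value = rt$p_value)
  }
  if (length(run_rows)) {
    results$interleaving <- do.call(rbind, run_rows)
    ok <- results$interleaving$p_value > 0 & results$interleaving$p_value < 1
    if (any(ok)) {
      attr(results$interleaving, "combined_p") <-
        stouffer_combine(results$interleaving$p_value[ok])
    }
    .write_tsv(results$interleaving, config$out_dir, "interleaving")
  }

  # expression divergence (needs DSA calls and profiles)
  if (!is.null(config$expression) && !is.null(dsa) && nrow(dsa)) {
    asym_pairs <- unique(dsa$pair_id[dsa$asymmetric])
    ov_rows <- list()
    for (pid in names(config$expression)) {
      pr <- config$expression[[pid]]
      ov <- suppressWarnings(stage_overlap(pr$copy1, pr$copy2,
                                           pair_id = pid))
      if (nrow(ov)) {
        ov$asymmetric <- pid %in% asym_pairs
        ov_rows[[length(ov_rows) + 1]] <- ov
      }
    }
    if (length(ov_rows)) {
      ovs <- do.call(rbind, ov_rows)
      results$expression <- ovs
      .write_tsv(ovs, config$out_dir, "expression_overlap")
      a <- ovs[ovs$asymmetric, , drop = FALSE]
      b <- ovs[!ovs$asymmetric, , drop = FALSE]
      if (nrow(a) && nrow(b)) {
        results$expression_comparison <- divergence_compare(a, b)
      }
    }
  }

  results$manifest <- list(
    package = "dupasym",
    version = as.character(utils::packageVersion("dupasym")),
    n_pairs = length(config$trios),
    levels = config$levels, engine = config$engine,
    thresholds = list(fdr = config$fdr, alpha = config$alpha,
                      cluster_alpha = config$cluster_alpha,
                      ds_lo = config$ds_lo, ds_hi = config$ds_hi),
    seed = config$seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(results$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
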