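# Fisher-exact-test asymmetry analysis of duplicate pairs at four levels:
# whole protein (WPA), combined domains (CDA), single domain (DSA) and
# inter-domain linker regions, with Benjamini-Hochberg FDR, faster-copy
# calling, codon bootstrap support and the sampled-column WPA control.

#' Two-sided Fisher exact test on a 2x2 substitution table
#'
#' Rows are the two duplicate branches, columns the non-synonymous and
#' synonymous substitution counts. The two-sided p-value follows the
#' point-probability rule: with margins fixed, it is the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one.
#'
#' @param N1,S1 Non-synonymous and synonymous counts on the copy1 branch.
#' @param N2,S2 Counts on the copy2 branch.
#' @return The p-value. An all-zero table returns 1 with a warning.
#' @examples
#' fisher_exact_2x2(2, 0, 0, 2)  # 1/3
#' @export
fisher_exact_2x2 <- function(N1, S1, N2, S2) {
  cnt <- c(N1, S1, N2, S2)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_typed("fet_error", "counts must be non-negative integers")
  }
  if (sum(cnt) == 0) {
    warning("empty 2x2 table; p = 1")
    return(1)
  }
  r1 <- N1 + S1; r2 <- N2 + S2; k <- N1 + N2
  lo <- max(0, k - r2); hi <- min(k, r1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, k)
  p_obs <- stats::dhyper(N1, r1, r2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

# Round fractional substitution counts half-away-from-zero (counts >= 0).
round_half_up <- function(x) floor(x + 0.5)

#' Build the asymmetry contingency table for one test unit
#'
#' Non-synonymous counts come from the region under test (whole protein,
#' combined domains, one domain, or linker); synonymous counts come from the
#' whole protein for the domain-level tests (the region itself for WPA, or
#' when `background = "region"`). Fractional counts are rounded
#' half-away-from-zero.
#'
#' @param trio A [codon_trio()].
#' @param region_columns Codon columns of the region under test; `NULL`
#'   means the whole protein.
#' @param background `"protein"` (synonymous background from the whole
#'   protein) or `"region"`.
#' @return Named integer vector `c(N1=, S1=, N2=, S2=)` with attribute
#'   `fractional` holding the unrounded values.
#' @export
asymmetry_table <- function(trio, region_columns = NULL,
                            background = c("protein", "region")) {
  background <- match.arg(background)
  idx <- .trio_indices(trio)
  if (!is.null(region_columns) && length(region_columns) == 0L) {
    stop_typed("empty_region_error", "region contains no codon columns")
  }
  bc_region <- .branch_counts_core(idx, region_columns, rates = FALSE)
  N1 <- bc_region$N[bc_region$branch == "copy1"]
  N2 <- bc_region$N[bc_region$branch == "copy2"]
  if (is.null(region_columns) || background == "region") {
    bc_bg <- bc_region
  } else {
    bc_bg <- .branch_counts_core(idx, NULL, rates = FALSE)
  }
  S1 <- bc_bg$S[bc_bg$branch == "copy1"]
  S2 <- bc_bg$S[bc_bg$branch == "copy2"]
  frac <- c(N1 = N1, S1 = S1, N2 = N2, S2 = S2)
  out <- round_half_up(frac)
  storage.mode(out) <- "integer"
  attr(out, "fractional") <- frac
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone q-values).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

.faster_copy <- function(N1, S1, N2, S2) {
  o1 <- N1 / (S1 + 1); o2 <- N2 / (S2 + 1)
  if (o1 > o2) "copy1" else if (o2 > o1) "copy2" else "tie"
}

# Codon columns covered by the domains of an architecture (protein
# coordinates = codon columns).
domain_columns <- function(arch, n_columns) {
  iv <- arch$intervals
  if (nrow(iv) && max(iv$end_aa) > n_columns) {
    stop_typed("domain_coordinate_error",
               sprintf("architecture %s exceeds the %d-column alignment",
                       arch$protein_id, n_columns))
  }
  cols <- lapply(seq_len(nrow(iv)),
                 function(k) seq(iv$start_aa[k], iv$end_aa[k]))
  stats::setNames(cols, iv$domain_name)
}

# Resolve the per-pair architecture argument: a single architecture or a
# list of up to three (checked for identity). Returns the reference
# architecture or NULL on mismatch.
.resolve_architecture <- function(a) {
  if (inherits(a, "domain_architecture")) return(a)
  stopifnot(is.list(a), length(a) >= 1)
  if (length(a) >= 3 &&
      !architectures_identical(a[[1]], a[[2]], a[[3]])) return(NULL)
  if (length(a) == 2 &&
      !identical(a[[1]]$intervals$domain_name,
                 a[[2]]$intervals$domain_name)) return(NULL)
  a[[1]]
}

#' Fisher-exact asymmetry testing across a batch of duplicate pairs
#'
#' Runs the admission filters (architecture identity where architectures are
#' supplied, then the dS filter), builds the level-appropriate contingency
#' table per test unit (one per protein for WPA/CDA/LINKER, one per domain
#' for DSA), applies the two-sided Fisher exact test, and adjusts p-values
#' by Benjamini-Hochberg across all units of the level. A unit is called
#' asymmetric when `p <= alpha` and `q <= fdr`; the faster copy is the one
#' with the larger `N/(S+1)` odds.
#'
#' @param trios Named list of [codon_trio()] objects (names = pair ids; if
#'   unnamed, `pair_id` fields are used).
#' @param architectures Optional named list (by pair id); each element a
#'   [domain_architecture()] or a list of the three per-protein
#'   architectures (identity is then enforced). Required for CDA/DSA/LINKER.
#' @param level `"WPA"`, `"CDA"`, `"DSA"` or `"LINKER"`.
#' @param fdr FDR threshold for the asymmetric call (default 0.10).
#' @param alpha Per-test p-value threshold (default 0.05).
#' @param ds_lo,ds_hi Bounds for [ds_filter()].
#' @param cda_background `"protein"` (default) or `"region"`: source of the
#'   synonymous background for CDA.
#' @param apply_ds_filter Set `FALSE` to skip the dS admission filter (used
#'   by the calibration experiment, whose replicates are all admissible by
#'   construction).
#' @return Data frame of class `asymmetry_results` with one row per test
#'   unit: `pair_id`, `level`, `domain_name`, `N1`, `S1`, `N2`, `S2`,
#'   `p_value`, `q_value`, `faster_copy`, `asymmetric`. Excluded pairs are
#'   recorded in `attr(, "exclusions")` (`pair_id`, `reason`).
#' @export
test_asymmetry <- function(trios, architectures = NULL,
                           level = c("WPA", "CDA", "DSA", "LINKER"),
                           fdr = 0.10, alpha = 0.05,
                           ds_lo = 0.2, ds_hi = 2.0,
                           cda_background = c("protein", "region"),
                           apply_ds_filter = TRUE) {
  level <- match.arg(level)
  cda_background <- match.arg(cda_background)
  if (is.null(names(trios))) {
    names(trios) <- vapply(trios, function(x) x$pair_id, character(1))
  }
  if (level != "WPA" && is.null(architectures)) {
    stop_typed("config_error",
               sprintf("level %s requires domain architectures", level))
  }
  rows <- list(); excl <- list()
  note_excl <- function(pid, reason) {
    excl[[length(excl) + 1]] <<- data.frame(pair_id = pid, reason = reason)
  }
  for (pid in names(trios)) {
    trio <- trios[[pid]]
    arch <- NULL
    if (!is.null(architectures)) {
      if (is.null(architectures[[pid]])) {
        if (level != "WPA") { note_excl(pid, "missing_architecture"); next }
      } else {
        arch <- .resolve_architecture(architectures[[pid]])
        if (is.null(arch)) { note_excl(pid, "architecture_mismatch"); next }
      }
    }
    bc <- suppressWarnings(branch_counts(trio))
    if (apply_ds_filter && !suppressWarnings(ds_filter(bc, ds_lo, ds_hi))) {
      note_excl(pid, "ds_filter"); next
    }
    units <- tryCatch(
      .level_units(trio, arch, level, cda_background),
      empty_region_error = function(e) NULL)
    if (is.null(units)) { note_excl(pid, "empty_region"); next }
    for (u in units) {
      tab <- u$table
      p <- fisher_exact_2x2(tab[["N1"]], tab[["S1"]], tab[["N2"]],
                            tab[["S2"]])
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = pid, level = level, domain_name = u$domain_name,
        N1 = tab[["N1"]], S1 = tab[["S1"]], N2 = tab[["N2"]],
        S2 = tab[["S2"]], p_value = p,
        faster_copy = .faster_copy(tab[["N1"]], tab[["S1"]], tab[["N2"]],
                                   tab[["S2"]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), level = character(0),
               domain_name = character(0), N1 = integer(0), S1 = integer(0),
               N2 = integer(0), S2 = integer(0), p_value = numeric(0),
               faster_copy = character(0))
  res$q_value <- bh_fdr(res$p_value)
  res$asymmetric <- res$p_value <= alpha & res$q_value <= fdr
  res <- res[, c("pair_id", "level", "domain_name", "N1", "S1", "N2", "S2",
                 "p_value", "q_value", "faster_copy", "asymmetric")]
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(pair_id = character(0), reason = character(0))
  class(res) <- c("asymmetry_results", "data.frame")
  res
}

# Test units (region columns + background) for one pair at one level.
.level_units <- function(trio, arch, level, cda_background) {
  if (level == "WPA") {
    return(list(list(domain_name = NA_character_,
                     table = asymmetry_table(trio, NULL))))
  }
  cols <- domain_columns(arch, trio$n_columns)
  if (level == "CDA") {
    region <- sort(unique(unlist(cols)))
    return(list(list(domain_name = NA_character_,
                     table = asymmetry_table(trio, region,
                                             background = cda_background))))
  }
  if (level == "DSA") {
    return(lapply(seq_along(cols), function(k) {
      list(domain_name = names(cols)[k],
           table = asymmetry_table(trio, cols[[k]],
                                   background = "protein"))
    }))
  }
  # LINKER
  region <- setdiff(seq_len(trio$n_columns), unlist(cols))
  list(list(domain_name = NA_character_,
            table = asymmetry_table(trio, region, background = "protein")))
}

#' Bootstrap support for an asymmetry call
#'
#' Resamples codon columns of the alignment with replacement (preserving the
#' original length), repeats the level-appropriate Fisher exact test on each
#' replicate and reports the fraction of replicates with `p <=
#' p_threshold`.
#'
#' @param trio A [codon_trio()].
#' @param architecture Architecture for domain-level tests (see
#'   [test_asymmetry()]); `NULL` for WPA.
#' @param level Test level; for `"DSA"` supply `domain_name`.
#' @param domain_name Domain under test when `level = "DSA"`.
#' @param n_reps Number of bootstrap replicates.
#' @param p_threshold The p-value cutoff implied by the original run's FDR
#'   control (default 0.05).
#' @param seed Random seed (mandatory for reproducibility).
#' @param cda_background As in [test_asymmetry()].
#' @return The support fraction in `[0, 1]`.
#' @export
bootstrap_support <- function(trio, architecture = NULL, level = "WPA",
                              domain_name = NULL, n_reps = 100,
                              p_threshold = 0.05, seed,
                              cda_background = "protein") {
  set.seed(seed)
  idx <- .trio_indices(trio)
  n <- trio$n_columns
  region <- .region_membership(trio, architecture, level, domain_name,
                               cda_background)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    take <- sample.int(n, n, replace = TRUE)
    p <- .table_p_from_columns(idx[take, , drop = FALSE],
                               region$member[take], region$background)
    if (p <= p_threshold) hits <- hits + 1L
  }
  hits / n_reps
}

# Region membership (logical over columns) and background mode for a level.
.region_membership <- function(trio, architecture, level, domain_name,
                               cda_background) {
  level <- match.arg(level, c("WPA", "CDA", "DSA", "LINKER"))
  n <- trio$n_columns
  if (level == "WPA") {
    return(list(member = rep(TRUE, n), background = "region"))
  }
  arch <- .resolve_architecture(architecture)
  cols <- domain_columns(arch, n)
  member <- rep(FALSE, n)
  if (level == "CDA") {
    member[unlist(cols)] <- TRUE
    return(list(member = member, background = cda_background))
  }
  if (level == "DSA") {
    stopifnot(!is.null(domain_name))
    member[unlist(cols[names(cols) == domain_name])] <- TRUE
    return(list(member = member, background = "protein"))
  }
  member[setdiff(seq_len(n), unlist(cols))] <- TRUE
  list(member = member, background = "protein")
}

# FET p for a resampled/subsetted index matrix given region membership.
.table_p_from_columns <- function(idx, member, background) {
  bc_region <- .branch_counts_core(idx, which(member), rates = FALSE)
  N1 <- bc_region$N[1]; N2 <- bc_region$N[2]
  bc_bg <- if (background == "region") bc_region else
    .branch_counts_core(idx, NULL, rates = FALSE)
  S1 <- bc_bg$S[1]; S2 <- bc_bg$S[2]
  tab <- round_half_up(c(N1, S1, N2, S2))
  suppressWarnings(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]))
}

#' Sampled-column whole-protein control
#'
#' Repeats the whole-protein Fisher exact test on random column subsets of a
#' given length (sampled without replacement), mimicking the reduced
#' alignment length of domain-level tests, and reports the fraction of
#' replicates flagged at `p <= alpha`.
#'
#' @param trio A [codon_trio()].
#' @param target_length Number of codon columns per subset.
#' @param n_reps Number of replicates.
#' @param seed Random seed.
#' @param alpha Flagging threshold.
#' @return The flagged fraction in `[0, 1]`.
#' @export
sampled_wpa_control <- function(trio, target_length, n_reps = 100, seed,
                                alpha = 0.05) {
  n <- trio$n_columns
  if (target_length <= 0) {
    stop_typed("config_error", "target_length must be positive")
  }
  if (target_length > n) {
    stop_typed("config_error", "target_length exceeds the alignment")
  }
  set.seed(seed)
  idx <- .trio_indices(trio)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    take <- sample.int(n, target_length, replace = FALSE)
    sub <- idx[take, , drop = FALSE]
    p <- .table_p_from_columns(sub, rep(TRUE, target_length), "region")
    if (p <= alpha) hits <- hits + 1L
  }
  hits / n_reps
}
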