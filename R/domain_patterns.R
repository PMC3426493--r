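# Downstream pattern statistics: clustering of non-synonymous changes
# within domains, assortment of asymmetric domains among multi-domain
# proteins, faster-copy concordance, per-family asymmetry frequency, and
# the interleaving (runs) test on copy-specific substitution positions.

#' Clustering of non-synonymous changes within domains
#'
#' For one gene copy of a multi-domain protein, tests each domain for an
#' enrichment of non-synonymous changes relative to the other domains, using
#' a one-sided Fisher exact test on the table
#' `[[N_domain, S_domain], [N_other, S_other]]` (synonymous counts as
#' background). Counts are NG86 branch counts for the chosen copy's branch,
#' restricted to domain columns.
#'
#' @param trio A [codon_trio()].
#' @param architecture A [domain_architecture()] (or list of three, checked
#'   for identity) with at least two domains.
#' @param copy `"copy1"` or `"copy2"`.
#' @param alpha Per-domain significance threshold for the `clustered` call.
#' @return Data frame with one row per domain: `pair_id`, `copy`,
#'   `domain_name`, `N_dom`, `S_dom`, `N_other`, `S_other`, `p_value`,
#'   `clustered`.
#' @export
clustering_test <- function(trio, architecture, copy = c("copy1", "copy2"),
                            alpha = 0.05) {
  copy <- match.arg(copy)
  arch <- .resolve_architecture(architecture)
  cols <- domain_columns(arch, trio$n_columns)
  if (length(cols) < 2L) {
    stop_typed("single_domain_error",
               "clustering test needs a protein with >= 2 domains")
  }
  idx <- .trio_indices(trio)
  per_dom <- lapply(cols, function(cc) {
    bc <- .branch_counts_core(idx, cc, rates = FALSE)
    r <- bc[bc$branch == copy, ]
    c(N = r$N, S = r$S)
  })
  Nv <- round_half_up(vapply(per_dom, `[[`, numeric(1), "N"))
  Sv <- round_half_up(vapply(per_dom, `[[`, numeric(1), "S"))
  rows <- lapply(seq_along(cols), function(k) {
    N_dom <- Nv[k]; S_dom <- Sv[k]
    N_oth <- sum(Nv[-k]); S_oth <- sum(Sv[-k])
    # one-sided upper tail: enrichment of N in this domain
    p <- stats::phyper(N_dom - 1, N_dom + N_oth, S_dom + S_oth,
                       N_dom + S_dom, lower.tail = FALSE)
    odds_excess <- N_dom * S_oth > N_oth * S_dom
    data.frame(pair_id = trio$pair_id, copy = copy,
               domain_name = names(cols)[k],
               N_dom = N_dom, S_dom = S_dom, N_other = N_oth,
               S_other = S_oth, p_value = p,
               clustered = p <= alpha && odds_excess,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assortment of asymmetric domains among multi-domain proteins
#'
#' Compares the observed number of multi-domain proteins carrying exactly
#' one asymmetrically evolving domain against the expectation under random
#' assortment: asymmetric labels are permuted uniformly over all domain
#' slots, preserving each protein's domain count and the total number of
#' asymmetric domains.
#'
#' @param domain_flags Named list, one element per multi-domain protein, of
#'   logical vectors (`TRUE` = domain called asymmetric).
#' @param n_perms Number of label permutations.
#' @param seed Random seed.
#' @return List with `observed_exactly_one`, `expected_exactly_one`,
#'   `ratio` (`NA` when no domain is asymmetric) and `p_value` (one-sided,
#'   observed or more proteins with exactly one asymmetric domain).
#' @export
assortment_analysis <- function(domain_flags, n_perms = 2000, seed) {
  stopifnot(length(domain_flags) >= 1)
  sizes <- lengths(domain_flags)
  if (any(sizes < 2L)) {
    stop_typed("config_error", "all proteins must have >= 2 domains")
  }
  flags <- unlist(domain_flags, use.names = FALSE)
  total_asym <- sum(flags)
  grp <- rep(seq_along(sizes), sizes)
  exactly_one <- function(f) sum(tapply(f, grp, sum) == 1L)
  obs <- exactly_one(flags)
  if (total_asym == 0L) {
    return(list(observed_exactly_one = obs, expected_exactly_one = 0,
                ratio = NA_real_, p_value = NA_real_))
  }
  set.seed(seed)
  perm_counts <- vapply(seq_len(n_perms), function(i) {
    f <- logical(length(flags))
    f[sample.int(length(flags), total_asym)] <- TRUE
    exactly_one(f)
  }, numeric(1))
  expected <- mean(perm_counts)
  list(observed_exactly_one = obs,
       expected_exactly_one = expected,
       ratio = if (expected > 0) obs / expected else NA_real_,
       p_value = (sum(perm_counts >= obs) + 1) / (n_perms + 1))
}

#' Concordance of faster-evolving copies across domains
#'
#' Among duplicate pairs with at least two asymmetrically evolving domains,
#' the fraction in which all faster-evolving domain copies belong to the
#' same gene copy.
#'
#' @param dsa_results An `asymmetry_results` data frame from
#'   [test_asymmetry()] at level `"DSA"`.
#' @return List with `n_pairs` (pairs with >= 2 asymmetric domains),
#'   `n_concordant` and `fraction` (`NA` when no such pair exists).
#' @export
faster_copy_concordance <- function(dsa_results) {
  asym <- dsa_results[dsa_results$asymmetric, , drop = FALSE]
  by_pair <- split(asym$faster_copy, asym$pair_id)
  multi <- by_pair[lengths(by_pair) >= 2L]
  if (length(multi) == 0L) {
    return(list(n_pairs = 0L, n_concordant = 0L, fraction = NA_real_))
  }
  conc <- vapply(multi, function(fc) length(unique(fc)) == 1L, logical(1))
  list(n_pairs = length(multi), n_concordant = sum(conc),
       fraction = mean(conc))
}

#' Per-family frequency of asymmetric evolution
#'
#' For each domain family, compares its count of asymmetric calls against
#' the pooled asymmetric fraction over all tested domains, by hypergeometric
#' over- and under-representation tails.
#'
#' @param dsa_results An `asymmetry_results` data frame at level `"DSA"`.
#' @return Data frame with one row per domain family: `domain_name`,
#'   `n_tested`, `n_asymmetric`, `fraction`, `p_over`, `p_under`.
#' @export
family_asymmetry_frequency <- function(dsa_results) {
  stopifnot(nrow(dsa_results) >= 1)
  M <- nrow(dsa_results)
  K <- sum(dsa_results$asymmetric)
  fams <- split(dsa_results$asymmetric, dsa_results$domain_name)
  rows <- lapply(names(fams), function(fam) {
    n <- length(fams[[fam]]); k <- sum(fams[[fam]])
    data.frame(domain_name = fam, n_tested = n, n_asymmetric = k,
               fraction = k / n,
               p_over = stats::phyper(k - 1, K, M - K, n,
                                      lower.tail = FALSE),
               p_under = stats::phyper(k, K, M - K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$domain_name), , drop = FALSE]
}

# Exact lower-tail P(runs <= r) of the two-sample runs distribution,
# conditional on label counts n1, n2.
.runs_cdf_exact <- function(r_obs, n1, n2) {
  total <- choose(n1 + n2, n1)
  count_r <- function(r) {
    if (r < 2) return(0)
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (r - 1) / 2
      choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)
    }
  }
  sum(vapply(2:max(2, r_obs), count_r, numeric(1))) / total
}

#' Interleaving (runs) test on copy-specific substitution positions
#'
#' Orders the protein positions uniquely mutated in one or the other gene
#' copy and tests whether the copy labels form fewer runs than expected
#' under random interleaving (Wald-Wolfowitz runs test, one-sided for too
#' few runs). The distribution is exact for up to 20 labelled positions and
#' a continuity-corrected normal approximation beyond.
#'
#' @param labels Character (or factor) vector of copy labels ordered by
#'   position, with exactly two distinct values.
#' @return List with `runs`, `p_value`, `n1`, `n2`.
#' @export
interleaving_runs_test <- function(labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) {
    stop_typed("runs_error",
               "need positions labelled for exactly two copies")
  }
  n1 <- sum(labels == lv[1]); n2 <- sum(labels == lv[2])
  runs <- 1L + sum(labels[-1] != labels[-length(labels)])
  n <- n1 + n2
  if (n <= 20) {
    p <- .runs_cdf_exact(runs, n1, n2)
  } else {
    mu <- 1 + 2 * n1 * n2 / n
    sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    p <- stats::pnorm((runs - mu + 0.5) / sqrt(sigma2))
  }
  list(runs = runs, p_value = min(p, 1), n1 = n1, n2 = n2)
}

#' Combine one-sided p-values by Stouffer's method
#'
#' @param p_values Numeric vector of one-sided p-values.
#' @return The combined p-value `pnorm(sum(qnorm(p)) / sqrt(k))`.
#' @export
stouffer_combine <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values > 0 & p_values < 1))
  z <- stats::qnorm(p_values)
  stats::pnorm(sum(z) / sqrt(length(z)))
}

#' Copy-specific non-synonymous substitution positions
#'
#' Protein positions (codon columns) where the inferred ancestral amino
#' acid differs from exactly one of the two copies, labelled by the mutated
#' copy and ordered by position. Input to [interleaving_runs_test()].
#'
#' @param trio A [codon_trio()].
#' @return Data frame with columns `column` and `copy`.
#' @export
substitution_positions <- function(trio) {
  cd <- codon_data()
  idx <- .trio_indices(trio)
  anc <- .ancestor_indices(idx)$index
  keep <- which(!is.na(anc))
  aa_anc <- cd$aa[anc[keep]]
  d1 <- cd$aa[idx[keep, "copy1"]] != aa_anc
  d2 <- cd$aa[idx[keep, "copy2"]] != aa_anc
  uniq <- xor(d1, d2)
  data.frame(column = keep[uniq],
             copy = ifelse(d1[uniq], "copy1", "copy2"),
             stringsAsFactors = FALSE)
}
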