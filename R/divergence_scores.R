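# BLOSUM62-based severity scoring of the amino-acid substitutions between
# the two duplicate copies within a domain, and the asymmetric-vs-symmetric
# comparison with a percentile-matched control.

.blosum_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#'
#' Canonical 20x20 integer BLOSUM62 matrix shipped as a plain-text data
#' file; the loader verifies symmetry, the value range `[-4, 11]` and a
#' checksum on first use.
#'
#' @return A symmetric 20 x 20 integer matrix with amino-acid dimnames.
#' @export
blosum62_matrix <- function() {
  if (!is.null(.blosum_cache$m)) return(.blosum_cache$m)
  path <- system.file("extdata", "blosum62.tsv", package = "dupasym")
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (!identical(rownames(m), colnames(m)) || !isTRUE(all(m == t(m))) ||
      min(m) != -4L || max(m) != 11L || sum(m) != -426L) {
    stop_typed("blosum_error", "bundled BLOSUM62 matrix failed validation")
  }
  .blosum_cache$m <- m
  m
}

#' Mean substitution score over differing positions of a domain
#'
#' Averages the BLOSUM62 score over the amino-acid positions where the two
#' aligned copies differ; positions with a gap (`-`) or a residue outside
#' the 20 standard amino acids in either copy are excluded. A lower mean
#' marks rarer, more radical substitutions.
#'
#' @param seg1,seg2 Equal-length aligned amino-acid strings (one domain of
#'   copy1 and copy2).
#' @return List with `n_substituted_positions` and `mean_score`
#'   (`NA` and flagged via `n_substituted_positions = 0` when the segments
#'   do not differ at any scorable position).
#' @examples
#' mean_substitution_score("LW", "IC")  # mean of 2 and -2 = 0
#' @export
mean_substitution_score <- function(seg1, seg2) {
  a <- strsplit(toupper(seg1), "")[[1]]
  b <- strsplit(toupper(seg2), "")[[1]]
  if (length(a) != length(b)) {
    stop_typed("score_error", "segments must have equal length")
  }
  m <- blosum62_matrix()
  ok <- a %in% rownames(m) & b %in% rownames(m)
  diffp <- ok & a != b
  if (!any(diffp)) {
    return(list(n_substituted_positions = 0L, mean_score = NA_real_))
  }
  sc <- m[cbind(a[diffp], b[diffp])]
  list(n_substituted_positions = sum(diffp), mean_score = mean(sc))
}

# Amino-acid translation of one trio sequence over a set of codon columns;
# masked columns come back as "-".
.translate_columns <- function(trio, role, columns) {
  cd <- codon_data()
  idx <- .trio_indices(trio)[columns, role]
  aa <- rep("-", length(columns))
  aa[!is.na(idx)] <- cd$aa[idx[!is.na(idx)]]
  paste(aa, collapse = "")
}

#' Per-domain substitution-severity scores for a duplicate pair
#'
#' Translates both copies over each domain's codon columns and computes the
#' mean BLOSUM62 score over positions where the copies differ.
#'
#' @param trio A [codon_trio()].
#' @param architecture A [domain_architecture()] (or list of three).
#' @return Data frame with columns `pair_id`, `domain_name`,
#'   `n_substituted_positions`, `mean_score`.
#' @export
domain_scores <- function(trio, architecture) {
  arch <- .resolve_architecture(architecture)
  cols <- domain_columns(arch, trio$n_columns)
  rows <- lapply(seq_along(cols), function(k) {
    s1 <- .translate_columns(trio, "copy1", cols[[k]])
    s2 <- .translate_columns(trio, "copy2", cols[[k]])
    sc <- mean_substitution_score(s1, s2)
    data.frame(pair_id = trio$pair_id, domain_name = names(cols)[k],
               n_substituted_positions = sc$n_substituted_positions,
               mean_score = sc$mean_score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One-sided ("a lower") two-sample rank-sum p-value. Exact enumeration of
# all group assignments when the combined sample size is at most
# `exact_max` (average ranks, so ties are handled exactly); otherwise the
# normal approximation with tie correction.
.ranksum_less <- function(a, b, exact_max = 20) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, na)
    Ws <- colSums(matrix(r[combos], nrow = na))
    return(list(statistic = U, p_value = mean(Ws <= W + 1e-9)))
  }
  wt <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' One-sided rank-sum comparison of two score groups
#'
#' Wilcoxon rank-sum test of whether `group_a` scores are stochastically
#' lower than `group_b` scores; exact (enumeration over group assignments,
#' valid under ties) when the combined sample size is at most 20, otherwise
#' the normal approximation with tie correction.
#'
#' @param group_a,group_b Numeric vectors (e.g. mean domain scores of
#'   asymmetrically and symmetrically evolving domains).
#' @return List with `statistic` (Mann-Whitney U for `group_a`) and
#'   `p_value`.
#' @export
compare_score_distributions <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_typed("score_error", "both groups must be non-empty")
  }
  .ranksum_less(group_a, group_b)
}

#' Percentile-matched control sample of symmetric domains
#'
#' For each asymmetric-domain score, samples one symmetric-domain score
#' uniformly among the symmetric candidates whose percentile rank in the
#' pooled (asymmetric plus symmetric) score distribution lies within
#' `window` percentile points of the asymmetric score's rank. Asymmetric
#' scores with no candidate in the window are dropped with a warning.
#'
#' @param asym_scores,sym_scores Numeric score vectors.
#' @param window Matching window in percentile points (default 10).
#' @param seed Random seed.
#' @return List with `matched` (one sampled symmetric score per matched
#'   asymmetric score), `matched_asym` (the asymmetric scores that found a
#'   match) and `n_dropped`.
#' @export
percentile_matched_control <- function(asym_scores, sym_scores,
                                       window = 10, seed) {
  asym_scores <- asym_scores[!is.na(asym_scores)]
  sym_scores <- sym_scores[!is.na(sym_scores)]
  stopifnot(length(asym_scores) >= 1, length(sym_scores) >= 1)
  set.seed(seed)
  pooled <- c(asym_scores, sym_scores)
  pct <- function(x) 100 * (rank(c(x, pooled), ties.method = "average")[1] - 1) /
    length(pooled)
  pa <- vapply(asym_scores, pct, numeric(1))
  ps <- vapply(sym_scores, pct, numeric(1))
  matched <- numeric(0); matched_asym <- numeric(0); dropped <- 0L
  for (i in seq_along(asym_scores)) {
    cand <- which(abs(ps - pa[i]) <= window)
    if (length(cand) == 0L) { dropped <- dropped + 1L; next }
    pick <- cand[sample.int(length(cand), 1L)]
    matched <- c(matched, sym_scores[pick])
    matched_asym <- c(matched_asym, asym_scores[i])
  }
  if (dropped > 0L) {
    warning(sprintf("%d asymmetric domain(s) had no match within %g percentile",
                    dropped, window))
  }
  list(matched = matched, matched_asym = matched_asym, n_dropped = dropped)
}
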