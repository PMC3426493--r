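# Per-branch substitution counting on the duplicate trio: parsimony
# inference of the duplication-node ancestor, Nei-Gojobori (NG86) site and
# substitution counting, Jukes-Cantor corrected dN/dS per branch, and the
# dS admission filter.

#' Infer ancestral codons at the duplication node
#'
#' Fitch-style parsimony on the unrooted 3-leaf tree: per codon column the
#' ancestral codon at the duplicate pair's last common ancestor is the
#' majority codon among copy1, copy2 and outgroup; when all three differ the
#' outgroup codon is taken and the column is flagged ambiguous. Columns with
#' a gap or `N` in any sequence are masked (`NA` ancestor).
#'
#' @param trio A [codon_trio()].
#' @return A list of class `ancestral_assignment` with `ancestor` (character
#'   vector of codons, `NA` where masked), `ambiguous` (logical vector) and
#'   `masked` (logical vector), all of length `trio$n_columns`.
#' @export
infer_ancestral_codons <- function(trio) {
  cd <- codon_data()
  idx <- .trio_indices(trio)
  anc <- .ancestor_indices(idx)
  structure(list(
    ancestor = ifelse(is.na(anc$index), NA_character_, cd$sense[anc$index]),
    ambiguous = anc$ambiguous,
    masked = is.na(anc$index)
  ), class = "ancestral_assignment")
}

# Vectorized majority-rule ancestor with outgroup tie-break, on the codon
# index matrix produced by .trio_indices().
.ancestor_indices <- function(idx) {
  i1 <- idx[, "copy1"]; i2 <- idx[, "copy2"]; i3 <- idx[, "outgroup"]
  anc <- rep(NA_integer_, nrow(idx))
  amb <- rep(FALSE, nrow(idx))
  ok <- !is.na(i1)
  a <- i3[ok]                       # default: outgroup codon
  a[i1[ok] == i2[ok]] <- i1[ok][i1[ok] == i2[ok]]
  a[i1[ok] == i3[ok]] <- i1[ok][i1[ok] == i3[ok]]
  a[i2[ok] == i3[ok]] <- i2[ok][i2[ok] == i3[ok]]
  anc[ok] <- a
  amb[ok] <- i1[ok] != i2[ok] & i1[ok] != i3[ok] & i2[ok] != i3[ok]
  list(index = anc, ambiguous = amb)
}

#' NG86 synonymous and non-synonymous site counts for one codon
#'
#' Per codon position, the fraction of single-nucleotide changes not creating
#' a stop codon that are synonymous, rescaled so that synonymous plus
#' non-synonymous sites sum to 3.
#'
#' @param codon A sense codon string (standard genetic code).
#' @return Named numeric vector `c(S_sites=, N_sites=)`.
#' @examples
#' count_sites_ng86("TTT")  # c(S_sites = 1/3, N_sites = 8/3)
#' @export
count_sites_ng86 <- function(codon) {
  cd <- codon_data()
  codon <- toupper(codon)
  i <- cd$index[codon]
  if (is.na(i)) {
    stop_typed("codon_error",
               sprintf("'%s' is not a sense codon", codon))
  }
  c(S_sites = cd$sites[i, "S_sites"], N_sites = cd$sites[i, "N_sites"])
}

#' NG86 pathway-averaged substitution counts between two codons
#'
#' Classifies each mutational step on the shortest pathways between the
#' ancestral and descendant codon as synonymous or non-synonymous, averaging
#' uniformly over all orderings of the differing positions that avoid stop
#' codons. When no stop-free pathway exists the counts are averaged over all
#' orderings using only the stop-free steps, and the result carries
#' `attr(, "no_stop_free_path") = TRUE`.
#'
#' @param anc,des Sense codon strings.
#' @return Named numeric vector `c(S=, N=)`.
#' @examples
#' count_substitutions_ng86("TTT", "GTA")  # c(S = 0.5, N = 1.5)
#' @export
count_substitutions_ng86 <- function(anc, des) {
  cd <- codon_data()
  i <- cd$index[toupper(anc)]; j <- cd$index[toupper(des)]
  if (is.na(i) || is.na(j)) {
    stop_typed("codon_error", "both codons must be sense codons")
  }
  out <- c(S = cd$sub_S[i, j], N = cd$sub_N[i, j])
  if (cd$sub_flag[i, j]) attr(out, "no_stop_free_path") <- TRUE
  out
}

# Jukes-Cantor correction on a proportion of substitutions per site.
.jc_correct <- function(p, what, branch) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) {
    warning(structure(
      class = c("saturation_warning", "warning", "condition"),
      list(message = sprintf(
        "%s saturated on branch %s (p = %.3f >= 3/4); value set NA",
        what, branch, p), call = NULL)))
    return(NA_real_)
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Counting core on codon index matrices; `columns` restricts which codon
# columns contribute substitutions and sites; `rates = FALSE` skips the
# distance correction (raw counts only, no saturation warnings).
.branch_counts_core <- function(idx, columns = NULL, rates = TRUE) {
  cd <- codon_data()
  n_col <- nrow(idx)
  if (is.null(columns)) columns <- seq_len(n_col)
  idx <- idx[columns, , drop = FALSE]
  anc <- .ancestor_indices(idx)$index
  keep <- !is.na(anc)
  branches <- c("copy1", "copy2", "outgroup")
  out <- data.frame(branch = branches, N = 0, S = 0,
                    N_sites = 0, S_sites = 0,
                    dN = 0, dS = 0, omega = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(keep)) {
    out$dN <- NA_real_; out$dS <- NA_real_
    attr(out, "n_unmasked") <- 0L
    class(out) <- c("branch_counts", "data.frame")
    return(out)
  }
  a <- anc[keep]
  anc_S_sites <- sum(cd$sites[a, "S_sites"])
  anc_N_sites <- sum(cd$sites[a, "N_sites"])
  for (k in seq_along(branches)) {
    leaf <- idx[keep, branches[k]]
    out$N[k] <- sum(cd$sub_N[cbind(a, leaf)])
    out$S[k] <- sum(cd$sub_S[cbind(a, leaf)])
    out$S_sites[k] <- (anc_S_sites + sum(cd$sites[leaf, "S_sites"])) / 2
    out$N_sites[k] <- (anc_N_sites + sum(cd$sites[leaf, "N_sites"])) / 2
    if (rates) {
      out$dN[k] <- .jc_correct(out$N[k] / out$N_sites[k], "dN", branches[k])
      out$dS[k] <- .jc_correct(out$S[k] / out$S_sites[k], "dS", branches[k])
      out$omega[k] <- if (!is.na(out$dS[k]) && out$dS[k] > 0 &&
                          !is.na(out$dN[k])) out$dN[k] / out$dS[k] else
                            NA_real_
    } else {
      out$dN[k] <- NA_real_; out$dS[k] <- NA_real_
    }
  }
  attr(out, "n_unmasked") <- sum(keep)
  class(out) <- c("branch_counts", "data.frame")
  out
}

#' Per-branch substitution counts, sites and rates
#'
#' Sums NG86 pathway-averaged substitution counts from the inferred ancestor
#' to each leaf, per branch of the unrooted trio tree. Site counts are the
#' average of the ancestral and descendant sequence NG86 site counts.
#' `dN` and `dS` are Jukes-Cantor corrected proportions
#' (`d = -(3/4) log(1 - 4p/3)`); a branch/quantity with `p >= 3/4` is
#' reported `NA` with a `saturation_warning`.
#'
#' @param trio A [codon_trio()].
#' @param columns Optional integer vector of codon columns to restrict the
#'   counting to (e.g. the columns of one domain).
#' @return A `branch_counts` data frame with one row per branch (`copy1`,
#'   `copy2`, `outgroup`) and columns `N`, `S`, `N_sites`, `S_sites`, `dN`,
#'   `dS`, `omega`; attribute `n_unmasked` gives the contributing column
#'   count.
#' @export
branch_counts <- function(trio, columns = NULL) {
  if (!is.null(columns)) {
    columns <- as.integer(columns)
    if (any(columns < 1L) || any(columns > trio$n_columns)) {
      stop_typed("column_range_error", "columns outside the alignment")
    }
  }
  .branch_counts_core(.trio_indices(trio), columns)
}

#' Synonymous-rate admission filter
#'
#' A duplicate pair is admitted when the synonymous rate along each of the
#' two duplicate branches is reasonably large yet unsaturated:
#' `lo <= dS <= hi` for both copies (defaults 0.2 and 2).
#'
#' @param bc A [branch_counts()] result.
#' @param lo,hi Admission bounds on dS.
#' @return `TRUE` or `FALSE`; undefined dS gives `FALSE` with a warning.
#' @export
ds_filter <- function(bc, lo = 0.2, hi = 2.0) {
  ds <- bc$dS[match(c("copy1", "copy2"), bc$branch)]
  if (anyNA(ds)) {
    warning("dS undefined for a duplicate branch; pair rejected")
    return(FALSE)
  }
  all(ds >= lo & ds <= hi)
}

#' Import externally computed per-branch counts
#'
#' Reads a TSV with columns `pair_id`, `branch`, `N`, `S`, `dN`, `dS` so
#' that per-branch rate estimates produced by external tools can be
#' substituted for the built-in counting engine.
#'
#' @param path Path to the TSV file.
#' @return Named list (by `pair_id`) of `branch_counts`-like data frames.
#' @export
read_branch_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "branch", "N", "S", "dN", "dS")
  if (!all(need %in% names(df))) {
    stop_typed("branch_counts_table_error",
               sprintf("missing column(s): %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  }
  lapply(split(df, df$pair_id), function(d) {
    out <- d[, c("branch", "N", "S", "dN", "dS")]
    out$omega <- ifelse(out$dS > 0, out$dN / out$dS, NA_real_)
    rownames(out) <- NULL
    class(out) <- c("branch_counts", "data.frame")
    out
  })
}
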