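# Internal genetic-code machinery shared by the counting engine, the codon
# model and the simulator. Standard genetic code only. All tables are built
# once per session and memoized.

.codon_cache <- new.env(parent = emptyenv())

codon_bases <- function() c("T", "C", "A", "G")

.all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Genetic-code and substitution-pathway lookup tables
#'
#' Returns the memoized internal tables used throughout the package: the 61
#' sense codons of the standard genetic code, their amino-acid translations,
#' Nei-Gojobori synonymous/non-synonymous site fractions per codon, and
#' pathway-averaged synonymous/non-synonymous substitution counts for every
#' ordered pair of sense codons.
#'
#' @return A list with elements `codons64`, `aa64`, `sense` (character vector
#'   of 61 sense codons), `aa` (translations of `sense`), `index` (named
#'   integer map codon -> 1..61), `stops`, `sites` (61 x 2 matrix, columns
#'   `S_sites`, `N_sites`, rows named by codon), `sub_S`/`sub_N` (61 x 61
#'   pathway-averaged substitution-count matrices), `sub_flag` (61 x 61
#'   logical, `TRUE` where no stop-free shortest pathway exists), and
#'   `neighbors` (data frame of single-nucleotide codon pairs with
#'   transition/synonymous annotation, used to build rate matrices).
#' @keywords internal
codon_data <- function() {
  if (!is.null(.codon_cache$data)) return(.codon_cache$data)
  b <- codon_bases()
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  codons64 <- paste0(g$p1, g$p2, g$p3)
  gc_tab <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc_tab[codons64])
  stopifnot(!anyNA(aa64))
  sense <- codons64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  stops <- codons64[aa64 == "*"]
  index <- stats::setNames(seq_along(sense), sense)
  aa_of <- stats::setNames(aa64, codons64)

  split_mat <- do.call(rbind, strsplit(sense, ""))

  # NG86 site fractions: per codon, 3 * (synonymous single-nt changes) /
  # (single-nt changes not creating a stop); rescaled so S + N = 3.
  sites <- matrix(0, length(sense), 2,
                  dimnames = list(sense, c("S_sites", "N_sites")))
  for (i in seq_along(sense)) {
    cod <- split_mat[i, ]
    n_syn <- 0L; n_tot <- 0L
    for (pos in 1:3) {
      for (nb in setdiff(b, cod[pos])) {
        mut <- cod; mut[pos] <- nb
        mutc <- paste(mut, collapse = "")
        if (aa_of[[mutc]] == "*") next
        n_tot <- n_tot + 1L
        if (aa_of[[mutc]] == aa[i]) n_syn <- n_syn + 1L
      }
    }
    s <- 3 * n_syn / n_tot
    sites[i, ] <- c(s, 3 - s)
  }

  # Pathway-averaged substitution counts for every ordered sense-codon pair.
  # All orderings of the differing positions are enumerated; pathways passing
  # through a stop codon are discarded; each retained pathway contributes its
  # per-step synonymous/non-synonymous classification; counts are the uniform
  # average. If every ordering passes through a stop, counts are averaged
  # over all orderings using only the stop-free steps and the pair is flagged.
  n <- length(sense)
  sub_S <- matrix(0, n, n, dimnames = list(sense, sense))
  sub_N <- matrix(0, n, n, dimnames = list(sense, sense))
  sub_flag <- matrix(FALSE, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    ci <- split_mat[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- split_mat[j, ]
      dif <- which(ci != cj)
      perms <- .all_permutations(dif)
      path_s <- numeric(0); path_n <- numeric(0)
      fb_s <- numeric(0); fb_n <- numeric(0)
      for (perm in perms) {
        cur <- ci; s <- 0; nn <- 0; valid <- TRUE
        fs <- 0; fn <- 0
        for (pos in perm) {
          nxt <- cur; nxt[pos] <- cj[pos]
          curc <- paste(cur, collapse = ""); nxtc <- paste(nxt, collapse = "")
          if (aa_of[[nxtc]] == "*") {
            valid <- FALSE
          } else if (aa_of[[curc]] != "*") {
            if (aa_of[[nxtc]] == aa_of[[curc]]) { s <- s + 1; fs <- fs + 1 }
            else { nn <- nn + 1; fn <- fn + 1 }
          }
          cur <- nxt
        }
        if (valid) { path_s <- c(path_s, s); path_n <- c(path_n, nn) }
        fb_s <- c(fb_s, fs); fb_n <- c(fb_n, fn)
      }
      if (length(path_s)) {
        sub_S[i, j] <- mean(path_s); sub_N[i, j] <- mean(path_n)
      } else {
        sub_S[i, j] <- mean(fb_s); sub_N[i, j] <- mean(fb_n)
        sub_flag[i, j] <- TRUE
      }
    }
  }

  # Single-nucleotide neighbour pairs for the codon rate matrix.
  nb_i <- integer(0); nb_j <- integer(0); nb_ts <- logical(0); nb_syn <- logical(0)
  is_transition <- function(x, y) {
    (x %in% c("T", "C") && y %in% c("T", "C")) ||
      (x %in% c("A", "G") && y %in% c("A", "G"))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dif <- which(split_mat[i, ] != split_mat[j, ])
      if (length(dif) != 1L) next
      nb_i <- c(nb_i, i); nb_j <- c(nb_j, j)
      nb_ts <- c(nb_ts, is_transition(split_mat[i, dif], split_mat[j, dif]))
      nb_syn <- c(nb_syn, aa[i] == aa[j])
    }
  }
  neighbors <- data.frame(i = nb_i, j = nb_j, transition = nb_ts,
                          synonymous = nb_syn)

  .codon_cache$data <- list(
    codons64 = codons64, aa64 = aa64, sense = sense, aa = aa, index = index,
    stops = stops, sites = sites, sub_S = sub_S, sub_N = sub_N,
    sub_flag = sub_flag, neighbors = neighbors
  )
  .codon_cache$data
}

# Split an aligned nucleotide string into codon strings (no validation).
.codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Map codon strings to sense-codon indices; NA for gaps/N/stops.
.codon_index <- function(codons) {
  cd <- codon_data()
  idx <- cd$index[codons]
  unname(idx)
}
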