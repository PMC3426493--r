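# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

GC_TAB <- Biostrings::GENETIC_CODE
SENSE <- names(GC_TAB)[GC_TAB != "*"]
translate1 <- function(codon) unname(GC_TAB[codon])

# --- Fisher exact oracle: exhaustive enumeration with choose() -------------
oracle_fisher <- function(N1, S1, N2, S2) {
  r1 <- N1 + S1; r2 <- N2 + S2; k <- N1 + N2; n <- r1 + r2
  if (n == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, k - x) / choose(n, k)
  }, numeric(1))
  p_obs <- probs[xs == N1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- NG86 pathway oracle: recursive DFS over mutation orderings ------------
oracle_ng86_pair <- function(anc, des) {
  paths <- list()
  walk <- function(cur, s, n, hit_stop) {
    dif <- which(strsplit(cur, "")[[1]] != strsplit(des, "")[[1]])
    if (length(dif) == 0L) {
      paths[[length(paths) + 1L]] <<- c(s = s, n = n, stop = hit_stop)
      return(invisible())
    }
    for (pos in dif) {
      ch <- strsplit(cur, "")[[1]]
      ch[pos] <- strsplit(des, "")[[1]][pos]
      nxt <- paste(ch, collapse = "")
      if (translate1(nxt) == "*") {
        walk(nxt, s, n, TRUE)
      } else if (translate1(cur) == "*") {
        walk(nxt, s, n, hit_stop)
      } else if (translate1(nxt) == translate1(cur)) {
        walk(nxt, s + 1, n, hit_stop)
      } else {
        walk(nxt, s, n + 1, hit_stop)
      }
    }
  }
  if (anc == des) return(c(S = 0, N = 0))
  walk(anc, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "stop"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(S = mean(m[, "s"]), N = mean(m[, "n"]))
}

# --- NG86 site oracle ------------------------------------------------------
oracle_ng86_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0; tot <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("T", "C", "A", "G"), ch[pos])) {
      mut <- ch; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (translate1(mutc) == "*") next
      tot <- tot + 1
      if (translate1(mutc) == translate1(codon)) syn <- syn + 1
    }
  }
  s <- 3 * syn / tot
  c(S_sites = s, N_sites = 3 - s)
}

# --- Fitch parsimony oracle on the 3-leaf star -----------------------------
# Enumerates all candidate ancestral codons, minimizes the number of
# branches whose leaf differs from the candidate; outgroup codon breaks
# ties.
oracle_fitch <- function(c1, c2, c3) {
  cost <- vapply(SENSE, function(a) (a != c1) + (a != c2) + (a != c3),
                 numeric(1))
  best <- SENSE[cost == min(cost)]
  if (c3 %in% best) c3 else best[1]
}

# --- Brute-force pruning oracle -------------------------------------------
# Explicit per-column sum over the 61 ancestral states, transition matrices
# via Matrix::expm of the generator (independent of the package's spectral
# path).
oracle_loglik <- function(trio, params) {
  Qs <- lapply(c("copy1", "copy2", "outgroup"), function(b)
    rate_matrix(params, b))
  Ps <- lapply(1:3, function(k) {
    t_b <- params$t_by_branch[[k]]
    as.matrix(Matrix::expm(Qs[[k]] * t_b))
  })
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  cods <- lapply(c("copy1", "copy2", "outgroup"),
                 function(r) split3(trio[[r]]))
  ll <- 0
  for (col in seq_len(trio$n_columns)) {
    obs <- vapply(cods, `[[`, character(1), col)
    if (any(grepl("[-N]", obs)) || any(translate1(obs) == "*")) next
    lik <- 0
    for (a in seq_along(SENSE)) {
      term <- params$pi[a]
      for (k in 1:3) term <- term * Ps[[k]][a, match(obs[k], SENSE)]
      lik <- lik + term
    }
    ll <- ll + log(lik)
  }
  ll
}

# --- fixture builders ------------------------------------------------------
make_trio <- function(pair_id = "fix", c1 = "ATGTTT", c2 = "ATGTTC",
                      og = "ATGTTT") {
  codon_trio(pair_id, c1, c2, og)
}

# random gap-free sense-codon trio (possibly with divergence)
random_trio <- function(n_codons, seed, mut = 0.3) {
  set.seed(seed)
  draw <- function(base) {
    idx <- base
    flip <- runif(n_codons) < mut
    idx[flip] <- sample(length(SENSE), sum(flip), replace = TRUE)
    paste(SENSE[idx], collapse = "")
  }
  base <- sample(length(SENSE), n_codons, replace = TRUE)
  codon_trio("rand", draw(base), draw(base), draw(base))
}
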