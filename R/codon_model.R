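# Goldman-Yang (GY94) codon substitution model on the unrooted 3-leaf trio
# tree: rate matrices, pruning likelihood, free vs omega-constrained fits,
# and the likelihood-ratio test for rate asymmetry between the duplicate
# branches.

.BRANCHES <- c("copy1", "copy2", "outgroup")

#' Construct codon-model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param pi Frequency vector over the 61 sense codons (sums to 1); `NULL`
#'   for uniform.
#' @param omega_by_branch Named numeric vector of dN/dS per branch
#'   (`copy1`, `copy2`, `outgroup`), all >= 0.
#' @param t_by_branch Named numeric vector of branch lengths in expected
#'   substitutions per codon, all >= 0.
#' @return An object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa = 2,
                               pi = NULL,
                               omega_by_branch = c(copy1 = 1, copy2 = 1,
                                                   outgroup = 1),
                               t_by_branch = c(copy1 = 0.5, copy2 = 0.5,
                                               outgroup = 0.5)) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61, all(is.finite(pi)), all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-9) {
    stop_typed("model_param_error", "pi must sum to 1 (tolerance 1e-9)")
  }
  stopifnot(is.finite(kappa), kappa > 0)
  for (v in list(omega_by_branch, t_by_branch)) {
    stopifnot(all(.BRANCHES %in% names(v)), all(is.finite(v)), all(v >= 0))
  }
  structure(list(kappa = kappa, pi = as.numeric(pi),
                 omega_by_branch = omega_by_branch[.BRANCHES],
                 t_by_branch = t_by_branch[.BRANCHES]),
            class = "codon_model_params")
}

#' GY94 instantaneous rate matrix for one branch
#'
#' Entries for single-nucleotide codon changes are `pi_j` times `kappa` for
#' transitions and times `omega` of the branch for non-synonymous changes;
#' multi-nucleotide changes have rate zero; rows sum to zero. The matrix is
#' scaled so the mean substitution rate at stationarity is 1 (branch lengths
#' are expected substitutions per codon at that branch's omega).
#'
#' @param params A [codon_model_params()].
#' @param branch One of `"copy1"`, `"copy2"`, `"outgroup"`.
#' @return A 61 x 61 generator matrix with sense-codon dimnames.
#' @export
rate_matrix <- function(params, branch = "copy1") {
  branch <- match.arg(branch, .BRANCHES)
  .rate_matrix_raw(params$pi, params$kappa,
                   params$omega_by_branch[[branch]])
}

.rate_matrix_raw <- function(pi, kappa, omega) {
  cd <- codon_data()
  nb <- cd$neighbors
  Q <- matrix(0, 61, 61, dimnames = list(cd$sense, cd$sense))
  rate <- pi[nb$j] * ifelse(nb$transition, kappa, 1) *
    ifelse(nb$synonymous, 1, omega)
  Q[cbind(nb$i, nb$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop_typed("model_param_error", "degenerate rate matrix")
  Q / scale
}

# Spectral decomposition of the reversible generator, reusable across branch
# lengths: Q = D^{-1/2} S D^{1/2} with S symmetric.
.rate_eigen <- function(pi, kappa, omega) {
  Q <- .rate_matrix_raw(pi, kappa, omega)
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, sq = sq)
}

.transition_from_eigen <- function(ed, t) {
  if (t == 0) return(diag(61))
  P <- ed$vectors %*% (exp(t * ed$values) * t(ed$vectors))
  P <- ((1 / ed$sq) %o% ed$sq) * P
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix over a branch
#'
#' Matrix exponential of the scaled GY94 generator times the branch length,
#' computed by spectral decomposition of the reversible generator.
#'
#' @param params A [codon_model_params()].
#' @param branch Branch identifier.
#' @return A 61 x 61 stochastic matrix.
#' @export
transition_matrix <- function(params, branch = "copy1") {
  branch <- match.arg(branch, .BRANCHES)
  ed <- .rate_eigen(params$pi, params$kappa,
                    params$omega_by_branch[[branch]])
  P <- .transition_from_eigen(ed, params$t_by_branch[[branch]])
  dimnames(P) <- list(codon_data()$sense, codon_data()$sense)
  P
}

#' F3x4 empirical codon frequencies from a trio
#'
#' Position-specific nucleotide frequencies across all three sequences at
#' unmasked codon columns, multiplied per codon, zeroed at stops and
#' renormalized over the 61 sense codons. A small pseudocount keeps every
#' frequency positive.
#'
#' @param trio A [codon_trio()].
#' @param pseudocount Added to every position-specific base count.
#' @return Numeric vector of length 61, summing to 1.
#' @export
f3x4_frequencies <- function(trio, pseudocount = 0.5) {
  cd <- codon_data()
  idx <- .trio_indices(trio)
  obs <- cd$sense[idx[!is.na(idx[, 1]), , drop = FALSE]]
  if (length(obs) == 0L) stop_typed("trio_empty_error", "no unmasked columns")
  ch <- do.call(rbind, strsplit(obs, ""))
  b <- codon_bases()
  fr <- sapply(1:3, function(p) {
    cnt <- table(factor(ch[, p], levels = b)) + pseudocount
    as.numeric(cnt / sum(cnt))
  })  # 4 x 3
  rownames(fr) <- b
  sense_ch <- do.call(rbind, strsplit(cd$sense, ""))
  pi <- fr[cbind(match(sense_ch[, 1], b), 1)] *
    fr[cbind(match(sense_ch[, 2], b), 2)] *
    fr[cbind(match(sense_ch[, 3], b), 3)]
  pi / sum(pi)
}

# Site-pattern compression: unique (i1,i2,i3) rows with weights.
.trio_patterns <- function(trio) {
  idx <- .trio_indices(trio)
  idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
  if (nrow(idx) == 0L) stop_typed("trio_empty_error", "no unmasked columns")
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  first <- idx[match(names(tab), key), , drop = FALSE]
  list(idx = first, w = as.numeric(tab))
}

.loglik_patterns <- function(pat, pi, kappa, omega_by_branch, t_by_branch,
                             eigen_cache = NULL) {
  Ps <- lapply(.BRANCHES, function(b) {
    om <- omega_by_branch[[b]]
    ed <- NULL
    if (!is.null(eigen_cache)) {
      key <- sprintf("%.15g_%.15g", kappa, om)
      ed <- eigen_cache[[key]]
      if (is.null(ed)) {
        ed <- .rate_eigen(pi, kappa, om)
        eigen_cache[[key]] <- ed
      }
    } else ed <- .rate_eigen(pi, kappa, om)
    .transition_from_eigen(ed, t_by_branch[[b]])
  })
  M <- Ps[[1]][, pat$idx[, 1], drop = FALSE] *
    Ps[[2]][, pat$idx[, 2], drop = FALSE] *
    Ps[[3]][, pat$idx[, 3], drop = FALSE]
  site_lik <- colSums(pi * M)
  if (any(!is.finite(site_lik)) || any(site_lik <= 0)) {
    bad <- which(!is.finite(site_lik) | site_lik <= 0)[1]
    stop_typed("likelihood_error",
               sprintf("non-finite site likelihood at pattern %d", bad))
  }
  sum(pat$w * log(site_lik))
}

#' Log-likelihood of a trio under the GY94 branch model
#'
#' Felsenstein pruning over the unrooted 3-leaf tree (a single internal
#' node summed over the 61 sense codon states), taken as a product over
#' unmasked codon columns.
#'
#' @param trio A [codon_trio()].
#' @param params A [codon_model_params()].
#' @return The log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(trio, params) {
  pat <- .trio_patterns(trio)
  .loglik_patterns(pat, params$pi, params$kappa,
                   params$omega_by_branch, params$t_by_branch)
}

# Informed starting values from the counting engine.
.fit_init <- function(trio) {
  bc <- suppressWarnings(branch_counts(trio))
  n_cod <- attr(bc, "n_unmasked")
  t0 <- om <- stats::setNames(numeric(3), .BRANCHES)
  for (b in .BRANCHES) {
    r <- bc[bc$branch == b, ]
    dn <- if (is.na(r$dN)) 0.7 else r$dN
    ds <- if (is.na(r$dS)) 1.5 else r$dS
    t0[b] <- max((dn * r$N_sites + ds * r$S_sites) / max(n_cod, 1), 1e-3)
    om[b] <- min(max(if (ds > 0) dn / ds else 0.5, 0.02), 10)
  }
  list(t = t0, omega = om, kappa = 2)
}

#' Fit the GY94 branch model to a trio
#'
#' Maximizes the pruning log-likelihood over kappa, the three branch lengths
#' and branch-wise omega values. In the free model each branch carries its
#' own omega; in the constrained model the two duplicate branches share one
#' omega while the outgroup omega stays free. Codon frequencies are fixed at
#' their F3x4 empirical estimate. Optimization is bounded quasi-Newton
#' (`L-BFGS-B` on log-transformed parameters) from an informed start plus
#' `n_starts - 1` randomly jittered restarts.
#'
#' @param trio A [codon_trio()].
#' @param constrain_equal_omega If `TRUE`, fit with `omega_copy1 =
#'   omega_copy2`.
#' @param n_starts Number of optimizer starts (first is informed).
#' @param seed Optional seed for the restart jitter.
#' @param init Optional named list `list(t=, omega=, kappa=)` overriding the
#'   informed start (used for warm starts).
#' @param control Passed to [stats::optim()] (with defaults for `factr` and
#'   `maxit`).
#' @return An object of class `likelihood_fit`: list with `params`
#'   ([codon_model_params()] at the optimum), `lnL`, `model_tag`
#'   (`"free"` or `"constrained"`) and `converged`.
#' @export
fit_branch_model <- function(trio, constrain_equal_omega = FALSE,
                             n_starts = 3, seed = NULL, init = NULL,
                             control = list()) {
  control <- utils::modifyList(list(factr = 1e8, maxit = 300), control)
  pi <- f3x4_frequencies(trio)
  pat <- .trio_patterns(trio)
  cache <- new.env(parent = emptyenv())

  unpack <- function(theta) {
    th <- exp(theta)
    if (constrain_equal_omega) {
      list(t = stats::setNames(th[1:3], .BRANCHES), kappa = th[4],
           omega = stats::setNames(th[c(5, 5, 6)], .BRANCHES))
    } else {
      list(t = stats::setNames(th[1:3], .BRANCHES), kappa = th[4],
           omega = stats::setNames(th[5:7], .BRANCHES))
    }
  }
  nll <- function(theta) {
    p <- unpack(theta)
    -tryCatch(
      .loglik_patterns(pat, pi, p$kappa, as.list(p$omega), as.list(p$t),
                       eigen_cache = cache),
      dupasym_error = function(e) -Inf)
  }

  if (is.null(init)) init <- .fit_init(trio)
  base_theta <- if (constrain_equal_omega) {
    log(c(init$t, init$kappa,
          sqrt(init$omega[["copy1"]] * init$omega[["copy2"]]),
          init$omega[["outgroup"]]))
  } else {
    log(c(init$t, init$kappa, init$omega))
  }
  npar <- length(base_theta)
  lower <- rep(log(1e-4), npar); upper <- rep(log(60), npar)

  if (!is.null(seed)) set.seed(seed)
  starts <- list(base_theta)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- pmin(pmax(base_theta + stats::rnorm(npar, 0, 0.5),
                                   lower), upper)
    }
  }
  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = control),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, lnL = NA_real_,
                          model_tag = if (constrain_equal_omega)
                            "constrained" else "free",
                          converged = FALSE),
                     class = "likelihood_fit"))
  }
  p <- unpack(best$par)
  structure(list(
    params = codon_model_params(kappa = p$kappa, pi = pi,
                                omega_by_branch = p$omega,
                                t_by_branch = p$t),
    lnL = -best$value,
    model_tag = if (constrain_equal_omega) "constrained" else "free",
    converged = best$convergence == 0
  ), class = "likelihood_fit")
}

#' @export
print.likelihood_fit <- function(x, ...) {
  cat(sprintf("likelihood_fit (%s): lnL = %.4f, converged = %s\n",
              x$model_tag, x$lnL, x$converged))
  if (!is.null(x$params)) {
    cat(sprintf("  kappa = %.3f; omega = %s; t = %s\n", x$params$kappa,
                paste(sprintf("%s:%.3f", .BRANCHES,
                              x$params$omega_by_branch), collapse = " "),
                paste(sprintf("%s:%.3f", .BRANCHES,
                              x$params$t_by_branch), collapse = " ")))
  }
  invisible(x)
}

#' Likelihood-ratio test of duplicate-branch rate asymmetry
#'
#' Statistic `2 * |lnL_free - lnL_constrained|` compared to a chi-square
#' distribution with one degree of freedom (the constrained model ties the
#' two duplicate-branch omega values together).
#'
#' @param free,constrained [fit_branch_model()] results for the same trio.
#' @param tolerance Allowed optimizer slack when the constrained model
#'   apparently beats the free one.
#' @return Named list `list(statistic=, p_value=)`.
#' @export
lrt_asymmetry <- function(free, constrained, tolerance = 1e-3) {
  stopifnot(inherits(free, "likelihood_fit"),
            inherits(constrained, "likelihood_fit"))
  if (!isTRUE(free$converged) || !isTRUE(constrained$converged)) {
    stop_typed("lrt_error", "both fits must have converged")
  }
  if (free$model_tag != "free" || constrained$model_tag != "constrained") {
    stop_typed("lrt_error", "arguments must be a free and a constrained fit")
  }
  diff <- free$lnL - constrained$lnL
  if (diff < -max(tolerance, 0.5)) {
    stop_typed("lrt_error",
               sprintf("free lnL below constrained lnL by %.4f", -diff))
  }
  stat <- 2 * abs(diff)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fit both branch models and run the likelihood-ratio test
#'
#' Convenience wrapper: fits the free model from the counting-informed
#' start, warm-starts the constrained model from the free optimum, and
#' re-polishes the free model from the constrained optimum when that
#' improves it, so that the nested-model inequality holds up to optimizer
#' tolerance before [lrt_asymmetry()] is applied.
#'
#' @param trio A [codon_trio()].
#' @param n_starts,control Passed to [fit_branch_model()].
#' @return List with `free`, `constrained` (the two `likelihood_fit`
#'   objects), `statistic` and `p_value` (`NA` when either fit fails to
#'   converge).
#' @export
lrt_test <- function(trio, n_starts = 1,
                     control = list(factr = 1e7, maxit = 500)) {
  fr <- fit_branch_model(trio, constrain_equal_omega = FALSE,
                         n_starts = n_starts, control = control)
  if (!isTRUE(fr$converged)) {
    return(list(free = fr, constrained = NULL, statistic = NA_real_,
                p_value = NA_real_))
  }
  warm <- list(t = fr$params$t_by_branch, omega = fr$params$omega_by_branch,
               kappa = fr$params$kappa)
  con <- fit_branch_model(trio, constrain_equal_omega = TRUE,
                          n_starts = n_starts, init = warm,
                          control = control)
  if (isTRUE(con$converged) && con$lnL > fr$lnL) {
    warm2 <- list(t = con$params$t_by_branch,
                  omega = con$params$omega_by_branch,
                  kappa = con$params$kappa)
    fr2 <- fit_branch_model(trio, constrain_equal_omega = FALSE,
                            n_starts = 1, init = warm2, control = control)
    if (isTRUE(fr2$converged) && fr2$lnL > fr$lnL) fr <- fr2
  }
  if (!isTRUE(con$converged)) {
    return(list(free = fr, constrained = con, statistic = NA_real_,
                p_value = NA_real_))
  }
  lr <- tryCatch(lrt_asymmetry(fr, con), lrt_error = function(e) NULL)
  if (is.null(lr)) {
    return(list(free = fr, constrained = con, statistic = NA_real_,
                p_value = NA_real_))
  }
  list(free = fr, constrained = con, statistic = lr$statistic,
       p_value = lr$p_value)
}

#' Export one or more likelihood fits as a TSV table
#'
#' @param fits Named list (by pair id) of lists with elements `free` and/or
#'   `constrained` ([fit_branch_model()] results).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  rows <- list()
  for (pid in names(fits)) {
    for (f in fits[[pid]]) {
      if (is.null(f$params)) {
        rows[[length(rows) + 1]] <- data.frame(
          pair_id = pid, model = f$model_tag, lnL = NA_real_, kappa = NA,
          omega_copy1 = NA, omega_copy2 = NA, omega_outgroup = NA,
          t_copy1 = NA, t_copy2 = NA, t_outgroup = NA,
          converged = FALSE)
        next
      }
      p <- f$params
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = pid, model = f$model_tag, lnL = f$lnL, kappa = p$kappa,
        omega_copy1 = p$omega_by_branch[["copy1"]],
        omega_copy2 = p$omega_by_branch[["copy2"]],
        omega_outgroup = p$omega_by_branch[["outgroup"]],
        t_copy1 = p$t_by_branch[["copy1"]],
        t_copy2 = p$t_by_branch[["copy2"]],
        t_outgroup = p$t_by_branch[["outgroup"]],
        converged = f$converged)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
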