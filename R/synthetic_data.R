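# Codon-evolution simulator on the unrooted 3-leaf trio tree, with
# per-branch and per-domain omega, plus generators for domain layouts and
# paired expression profiles, and the neutral false-positive calibration
# experiment for the Fisher-exact asymmetry pipeline.

#' Define a simulation scenario
#'
#' Collects everything the trio simulator needs: branch lengths (expected
#' substitutions per codon), the transition/transversion ratio, root codon
#' frequencies, sequence length, per-branch omega with optional per-domain
#' overrides, replicate count and seed.
#'
#' The default branch lengths emulate the calibration conditions of the
#' asymmetry study: neutral evolution (omega = 1 on all branches), equal
#' duplicate branches with synonymous rate dS near 0.6 each, and an
#' outgroup branch placing the duplicate-to-outgroup synonymous distance
#' near 2.
#'
#' @param n_codons Number of codon columns to simulate.
#' @param t_by_branch Named branch lengths (`copy1`, `copy2`, `outgroup`).
#' @param kappa Transition/transversion ratio.
#' @param pi Root/stationary codon frequencies over the 61 sense codons;
#'   `NULL` for uniform.
#' @param omega_by_branch Named per-branch omega defaults.
#' @param domains Optional data frame `domain_name`, `start_aa`, `end_aa`
#'   describing the simulated domain layout.
#' @param domain_omega Optional data frame `domain_name`, `branch`, `omega`
#'   of per-(domain, branch) omega overrides.
#' @param n_replicates Replicate count carried by the scenario.
#' @param seed Mandatory base seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_codons = 10000,
                                t_by_branch = c(copy1 = 1.7, copy2 = 1.7,
                                                outgroup = 4.0),
                                kappa = 2,
                                pi = NULL,
                                omega_by_branch = c(copy1 = 1, copy2 = 1,
                                                    outgroup = 1),
                                domains = NULL,
                                domain_omega = NULL,
                                n_replicates = 1,
                                seed = 1) {
  stopifnot(n_codons >= 1, !is.null(seed))
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  params_check <- codon_model_params(kappa = kappa, pi = pi,
                                     omega_by_branch = omega_by_branch,
                                     t_by_branch = t_by_branch)
  if (!is.null(domains)) {
    stopifnot(all(c("domain_name", "start_aa", "end_aa") %in%
                    names(domains)))
    if (max(domains$end_aa) > n_codons) {
      stop_typed("layout_error", "domain layout exceeds the sequence")
    }
    # validates ordering/overlap
    domain_architecture("layout", domains$domain_name, domains$start_aa,
                        domains$end_aa)
  }
  if (!is.null(domain_omega)) {
    stopifnot(!is.null(domains),
              all(c("domain_name", "branch", "omega") %in%
                    names(domain_omega)),
              all(domain_omega$domain_name %in% domains$domain_name),
              all(domain_omega$branch %in% .BRANCHES),
              all(domain_omega$omega >= 0))
  }
  structure(list(n_codons = as.integer(n_codons),
                 t_by_branch = params_check$t_by_branch,
                 kappa = kappa, pi = params_check$pi,
                 omega_by_branch = params_check$omega_by_branch,
                 domains = domains, domain_omega = domain_omega,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "simulation_scenario")
}

# Column-wise omega per branch, combining the default with per-domain
# overrides.
.omega_profile <- function(scenario) {
  prof <- sapply(.BRANCHES, function(b)
    rep(scenario$omega_by_branch[[b]], scenario$n_codons))
  prof <- matrix(prof, nrow = scenario$n_codons,
                 dimnames = list(NULL, .BRANCHES))
  if (!is.null(scenario$domain_omega)) {
    for (k in seq_len(nrow(scenario$domain_omega))) {
      ov <- scenario$domain_omega[k, ]
      d <- scenario$domains[scenario$domains$domain_name == ov$domain_name, ]
      for (r in seq_len(nrow(d))) {
        prof[d$start_aa[r]:d$end_aa[r], ov$branch] <- ov$omega
      }
    }
  }
  prof
}

# Simulate codon index vectors for root and the three leaves.
.simulate_indices <- function(scenario) {
  n <- scenario$n_codons
  root <- sample.int(61, n, replace = TRUE, prob = scenario$pi)
  prof <- .omega_profile(scenario)
  leaves <- list()
  for (b in .BRANCHES) {
    t_b <- scenario$t_by_branch[[b]]
    des <- root
    for (om in unique(prof[, b])) {
      colsel <- which(prof[, b] == om)
      ed <- .rate_eigen(scenario$pi, scenario$kappa, om)
      P <- .transition_from_eigen(ed, t_b)
      for (a in unique(root[colsel])) {
        at <- colsel[root[colsel] == a]
        des[at] <- sample.int(61, length(at), replace = TRUE, prob = P[a, ])
      }
    }
    leaves[[b]] <- des
  }
  list(root = root, leaves = leaves)
}

.indices_to_seq <- function(idx) {
  paste(codon_data()$sense[idx], collapse = "")
}

#' Simulate a duplicate-trio codon alignment
#'
#' Draws an ancestral sequence from the scenario's codon frequencies at the
#' internal (duplication) node and evolves it independently along the three
#' branches using the GY94 transition matrices of [rate_matrix()], applying
#' any per-domain omega overrides segment-wise. Alignments are generated
#' gap-free.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Seed overriding the scenario's; `NULL` uses `scenario$seed`.
#' @param pair_id Identifier for the generated trio.
#' @return A [codon_trio()] whose `attr(, "truth")` records the ancestral
#'   codon sequence and the scenario.
#' @export
simulate_trio <- function(scenario, seed = NULL, pair_id = "sim") {
  if (is.null(seed)) seed <- scenario$seed
  set.seed(seed)
  sim <- .simulate_indices(scenario)
  trio <- codon_trio(pair_id,
                     copy1 = .indices_to_seq(sim$leaves$copy1),
                     copy2 = .indices_to_seq(sim$leaves$copy2),
                     outgroup = .indices_to_seq(sim$leaves$outgroup))
  attr(trio, "truth") <- list(ancestor = codon_data()$sense[sim$root],
                              scenario = scenario, seed = seed)
  trio
}

#' Neutral false-positive calibration of the Fisher-exact pipeline
#'
#' Simulates replicate duplicate trios under the neutral, rate-symmetric
#' scenario (omega = 1 on every branch, equal duplicate branch lengths),
#' runs the counting engine and the whole-protein two-sided Fisher exact
#' test on each replicate, adjusts across replicates by Benjamini-Hochberg,
#' and reports the fraction of replicates with `p <= alpha` that survive
#' the FDR threshold.
#'
#' @param n_reps Number of simulated replicates.
#' @param n_codons Codon columns per replicate.
#' @param alpha Per-replicate p-value threshold.
#' @param fdr FDR threshold across replicates.
#' @param seed Random seed.
#' @param scenario Optional [simulation_scenario()] overriding the default
#'   neutral scenario (its `n_codons` is replaced by `n_codons`).
#' @return The flagged fraction; `attr(, "p_values")` carries the
#'   per-replicate p-values.
#' @export
false_positive_experiment <- function(n_reps = 1000, n_codons = 10000,
                                      alpha = 0.05, fdr = 0.10, seed = 1,
                                      scenario = NULL) {
  if (is.null(scenario)) {
    scenario <- simulation_scenario(n_codons = n_codons, seed = seed)
  } else {
    scenario$n_codons <- as.integer(n_codons)
  }
  set.seed(seed)
  p <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- .simulate_indices(scenario)
    idx <- cbind(copy1 = sim$leaves$copy1, copy2 = sim$leaves$copy2,
                 outgroup = sim$leaves$outgroup)
    bc <- .branch_counts_core(idx, NULL, rates = FALSE)
    tab <- round_half_up(c(bc$N[1], bc$S[1], bc$N[2], bc$S[2]))
    p[r] <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
  }
  q <- bh_fdr(p)
  out <- mean(p <= alpha & q <= fdr)
  attr(out, "p_values") <- p
  out
}

#' Simulate a trio with one fast-evolving domain
#'
#' Builds a scenario in which a single domain on a single branch evolves at
#' `omega_fast` while everything else evolves at the scenario's background
#' omega, simulates the trio, and emits matching identical domain
#' architectures for the three proteins.
#'
#' @param layout Data frame `domain_name`, `start_aa`, `end_aa` of the
#'   simulated domain layout.
#' @param omega_fast Omega of the accelerated domain.
#' @param target_branch Branch carrying the accelerated domain (`"copy1"`
#'   or `"copy2"`).
#' @param target_domain Name of the accelerated domain (default: first of
#'   the layout).
#' @param scenario Base [simulation_scenario()] providing branch lengths,
#'   kappa, frequencies and the background omega.
#' @param seed Seed overriding the scenario's.
#' @param pair_id Identifier for the generated pair.
#' @return List with `trio` ([codon_trio()]) and `architectures` (list of
#'   three identical [domain_architecture()] objects).
#' @export
simulate_domain_scenario <- function(layout, omega_fast,
                                     target_branch = "copy1",
                                     target_domain = layout$domain_name[1],
                                     scenario, seed = NULL,
                                     pair_id = "sim") {
  target_branch <- match.arg(target_branch, c("copy1", "copy2"))
  stopifnot(target_domain %in% layout$domain_name)
  ov <- data.frame(domain_name = target_domain, branch = target_branch,
                   omega = omega_fast, stringsAsFactors = FALSE)
  sc <- simulation_scenario(
    n_codons = scenario$n_codons, t_by_branch = scenario$t_by_branch,
    kappa = scenario$kappa, pi = scenario$pi,
    omega_by_branch = scenario$omega_by_branch,
    domains = layout, domain_omega = ov,
    n_replicates = scenario$n_replicates, seed = scenario$seed)
  trio <- simulate_trio(sc, seed = seed, pair_id = pair_id)
  archs <- lapply(c("copy1", "copy2", "outgroup"), function(role) {
    domain_architecture(paste(pair_id, role, sep = "_"),
                        layout$domain_name, layout$start_aa, layout$end_aa)
  })
  list(trio = trio, architectures = archs)
}

#' Simulate paired expression profiles with a target overlap
#'
#' For each duplicate pair and stage, draws two anatomy-term sets of
#' `n_terms` terms whose expected Jaccard overlap equals `target_jaccard`:
#' the shared-term count is randomized between the two integers bracketing
#' the exact solution of `J = s / (2 n - s)` with the probability that makes
#' the expected Jaccard hit the target.
#'
#' @param n_pairs Number of duplicate pairs.
#' @param target_jaccard Desired expected per-stage Jaccard in `[0, 1]`.
#' @param n_terms Terms per gene per stage.
#' @param stages Character vector of stage labels.
#' @param seed Random seed.
#' @param universe_size Size of the anatomy-term universe (must allow
#'   disjoint sets).
#' @return Named list of `n_pairs` elements, each a list of two
#'   [expression_profile()] objects (`copy1`, `copy2`).
#' @export
simulate_expression <- function(n_pairs, target_jaccard, n_terms = 8,
                                stages = c("cleavage", "gastrula",
                                           "segmentation", "pharyngula",
                                           "larval"),
                                seed = 1,
                                universe_size = max(20 * n_terms, 50)) {
  stopifnot(target_jaccard >= 0, target_jaccard <= 1)
  if (n_terms < 1) {
    stop_typed("config_error",
               "n_terms too small for the requested overlap")
  }
  if (universe_size < 2 * n_terms) {
    stop_typed("config_error", "universe too small for disjoint sets")
  }
  set.seed(seed)
  universe <- sprintf("term%04d", seq_len(universe_size))
  s_exact <- 2 * n_terms * target_jaccard / (1 + target_jaccard)
  s_lo <- floor(s_exact); s_hi <- ceiling(s_exact)
  jac <- function(s) s / (2 * n_terms - s)
  p_hi <- if (s_hi == s_lo) 0 else
    (target_jaccard - jac(s_lo)) / (jac(s_hi) - jac(s_lo))
  out <- list()
  for (i in seq_len(n_pairs)) {
    st1 <- list(); st2 <- list()
    for (s in stages) {
      n_shared <- if (stats::runif(1) < p_hi) s_hi else s_lo
      terms <- sample(universe, 2 * n_terms - n_shared)
      shared <- terms[seq_len(n_shared)]
      rest <- if (n_shared > 0) terms[-seq_len(n_shared)] else terms
      u1 <- rest[seq_len(n_terms - n_shared)]
      u2 <- rest[n_terms - n_shared + seq_len(n_terms - n_shared)]
      st1[[s]] <- c(shared, u1)
      st2[[s]] <- c(shared, u2)
    }
    pid <- sprintf("pair%03d", i)
    out[[pid]] <- list(
      copy1 = expression_profile(paste0(pid, "_copy1"), st1),
      copy2 = expression_profile(paste0(pid, "_copy2"), st2))
  }
  out
}
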