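# Domain-pattern statistics: clustering, assortment, concordance, family
# frequency and the interleaving runs test.

test_that("clustering test matches the hypergeometric tail", {
  # direct table check via a constructed trio is cumbersome; check the
  # arithmetic through the one-sided enumeration oracle on the published
  # module example (10, 2, 3, 8)
  p_oracle <- 0
  N_dom <- 10; S_dom <- 2; N_oth <- 3; S_oth <- 8
  k <- N_dom + S_dom; K <- N_dom + N_oth; M <- K + S_dom + S_oth
  for (x in N_dom:min(k, K)) {
    p_oracle <- p_oracle + choose(K, x) * choose(M - K, k - x) / choose(M, k)
  }
  expect_equal(stats::phyper(N_dom - 1, K, M - K, k, lower.tail = FALSE),
               p_oracle, tolerance = 1e-12)
  expect_lte(p_oracle, 0.05)

  # protein with a 5x omega contrast in one domain clusters there in at
  # least 80% of seeded runs (equal branch lengths keep the ancestral
  # assignment clean)
  layout <- data.frame(domain_name = c("fast", "slow"),
                       start_aa = c(1, 201), end_aa = c(150, 400))
  arch <- domain_architecture("p", layout$domain_name, layout$start_aa,
                              layout$end_aa)
  hits <- 0L
  for (i in 1:20) {
    base <- simulation_scenario(
      n_codons = 400,
      t_by_branch = c(copy1 = 0.6, copy2 = 0.6, outgroup = 0.6),
      omega_by_branch = c(copy1 = 0.2, copy2 = 0.2, outgroup = 0.2),
      seed = 40 + i)
    sim <- simulate_domain_scenario(layout, omega_fast = 1.0,
                                    target_branch = "copy1",
                                    target_domain = "fast",
                                    scenario = base, seed = 40 + i)
    res <- clustering_test(sim$trio, arch, copy = "copy1")
    if (res$clustered[res$domain_name == "fast"]) hits <- hits + 1L
  }
  expect_gte(hits, 16L)

  # degenerate and error cases
  tr0 <- random_trio(20, seed = 3, mut = 0)
  res0 <- clustering_test(tr0, domain_architecture("p", c("A", "B"),
                                                   c(1, 11), c(10, 20)))
  expect_equal(res0$p_value, c(1, 1))
  expect_false(any(res0$clustered))
  expect_error(clustering_test(tr0, domain_architecture("p", "A", 1, 10)),
               class = "single_domain_error")
})

test_that("assortment expectation matches exhaustive enumeration", {
  # proteins with domain counts (2,2,2) and 3 asymmetric domains in total:
  # exhaustive average of 'exactly one per protein' over C(6,3) assignments
  slots <- 6; k <- 3
  combos <- combn(slots, k)
  grp <- rep(1:3, each = 2)
  exact <- mean(apply(combos, 2, function(ix) {
    f <- logical(slots); f[ix] <- TRUE
    sum(tapply(f, grp, sum) == 1L)
  }))
  expect_equal(exact, 1.8)

  flags <- list(p1 = c(TRUE, FALSE), p2 = c(TRUE, FALSE),
                p3 = c(TRUE, FALSE))
  res <- assortment_analysis(flags, n_perms = 4000, seed = 2)
  expect_equal(res$observed_exactly_one, 3L)
  expect_equal(res$expected_exactly_one, exact, tolerance = 0.02 * exact)
  expect_equal(res$ratio, 3 / res$expected_exactly_one)

  # zero asymmetric domains
  none <- assortment_analysis(list(p1 = c(FALSE, FALSE)), seed = 1)
  expect_equal(none$expected_exactly_one, 0)
  expect_true(is.na(none$ratio))

  # determinism
  r1 <- assortment_analysis(flags, n_perms = 500, seed = 9)
  r2 <- assortment_analysis(flags, n_perms = 500, seed = 9)
  expect_identical(r1, r2)
})

test_that("faster-copy concordance summarises multi-domain pairs", {
  mk <- function(pair, doms, faster, asym = TRUE) {
    data.frame(pair_id = pair, level = "DSA", domain_name = doms,
               N1 = 1, S1 = 1, N2 = 1, S2 = 1, p_value = 0.01,
               q_value = 0.05, faster_copy = faster, asymmetric = asym)
  }
  dsa <- rbind(mk("a", c("d1", "d2", "d3"), c("copy1", "copy1", "copy1")),
               mk("b", c("d1", "d2"), c("copy1", "copy2")),
               mk("c", "d1", "copy2"))
  res <- faster_copy_concordance(dsa)
  expect_equal(res$n_pairs, 2L)        # pair c has a single asym domain
  expect_equal(res$n_concordant, 1L)
  expect_equal(res$fraction, 0.5)

  empty <- faster_copy_concordance(mk("a", "d1", "copy1", asym = FALSE))
  expect_true(is.na(empty$fraction))
})

test_that("family asymmetry frequency uses hypergeometric tails", {
  mk_row <- function(fam, asym) {
    data.frame(pair_id = "x", level = "DSA", domain_name = fam,
               N1 = 1, S1 = 1, N2 = 1, S2 = 1, p_value = 0.5,
               q_value = 0.5, faster_copy = "tie", asymmetric = asym)
  }
  # family with 5/5 asymmetric against a ~10% pool
  dsa <- rbind(do.call(rbind, replicate(5, mk_row("kin", TRUE),
                                        simplify = FALSE)),
               do.call(rbind, replicate(50, mk_row("other", FALSE),
                                        simplify = FALSE)),
               do.call(rbind, replicate(1, mk_row("other", TRUE),
                                        simplify = FALSE)))
  res <- family_asymmetry_frequency(dsa)
  kin <- res[res$domain_name == "kin", ]
  expect_lt(kin$p_over, 0.001)
  expect_equal(kin$fraction, 1)

  # hand-computed hypergeometric for a 0-of-19 family in a 353/1113 pool
  M <- 1113; K <- 353; n <- 19
  p_under_oracle <- choose(M - K, n) / choose(M, n)
  expect_equal(stats::phyper(0, K, M - K, n), p_under_oracle,
               tolerance = 1e-12)

  # family matching the pool fraction carries no signal either way
  bal <- rbind(do.call(rbind, replicate(2, mk_row("f", TRUE),
                                        simplify = FALSE)),
               do.call(rbind, replicate(8, mk_row("f", FALSE),
                                        simplify = FALSE)),
               do.call(rbind, replicate(20, mk_row("g", TRUE),
                                        simplify = FALSE)),
               do.call(rbind, replicate(80, mk_row("g", FALSE),
                                        simplify = FALSE)))
  rb <- family_asymmetry_frequency(bal)
  expect_gt(rb$p_over[rb$domain_name == "f"], 0.3)
  expect_gt(rb$p_under[rb$domain_name == "f"], 0.3)
})

test_that("runs test: exact small-sample distribution and approximations", {
  r1 <- interleaving_runs_test(c("1", "1", "1", "2", "2", "2"))
  expect_equal(r1$runs, 2L)
  expect_equal(r1$p_value, 0.1)   # 2 of C(6,3)=20 orderings give 2 runs

  r2 <- interleaving_runs_test(c("1", "2", "1", "2", "1", "2"))
  expect_equal(r2$runs, 6L)
  expect_equal(r2$p_value, 1)     # maximal interleaving

  expect_error(interleaving_runs_test(rep("1", 5)), class = "runs_error")

  # normal approximation beyond n = 20: clustered labels give small p
  big <- c(rep("a", 15), rep("b", 15))
  pb <- interleaving_runs_test(big)
  expect_equal(pb$runs, 2L)
  expect_lt(pb$p_value, 1e-6)
  alt <- rep(c("a", "b"), 15)
  expect_gt(interleaving_runs_test(alt)$p_value, 0.99)
})

test_that("Stouffer combination reproduces the two-gene closed form", {
  p <- c(0.03, 0.2)
  z <- qnorm(p)
  expect_equal(stouffer_combine(p), pnorm((z[1] + z[2]) / sqrt(2)))
  expect_equal(stouffer_combine(0.5), 0.5)
})

test_that("substitution positions label uniquely mutated columns", {
  # ancestor TTT everywhere; copy1 mutated (nonsyn) at column 2,
  # copy2 at column 4; column 5 mutated in both (not unique)
  tr <- codon_trio("p",
                   paste0("TTT", "TGT", "TTT", "TTT", "TGT"),
                   paste0("TTT", "TTT", "TTT", "TCT", "TCT"),
                   paste0("TTT", "TTT", "TTT", "TTT", "TTT"))
  pos <- substitution_positions(tr)
  expect_equal(pos$column, c(2L, 4L))
  expect_equal(pos$copy, c("copy1", "copy2"))
})
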