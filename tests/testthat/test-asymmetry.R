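# Fisher-exact asymmetry machinery: the exact test, table construction,
# FDR adjustment, batch testing, bootstrap support and the sampled-column
# control.

test_that("two-sided FET matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(1, 0, 0, 1), 1)
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_2x2(10, 5, 10, 5), 1)
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 0, 0), "empty")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), class = "fet_error")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), class = "fet_error")

  set.seed(7)
  for (k in 1:30) {
    tab <- rpois(4, 8)
    p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
    # swapping copies leaves p unchanged
    expect_equal(p, fisher_exact_2x2(tab[3], tab[4], tab[1], tab[2]))
  }
})

test_that("fractional counts round half-away-from-zero", {
  expect_equal(dupasym:::round_half_up(c(12.4, 3.2, 10.1, 9.8)),
               c(12, 3, 10, 10))
  expect_equal(dupasym:::round_half_up(c(0.5, 1.5, 2.49)), c(1, 2, 2))
})

test_that("asymmetry tables use the prescribed backgrounds", {
  sc <- simulation_scenario(n_codons = 300,
                            t_by_branch = c(copy1 = 0.6, copy2 = 0.6,
                                            outgroup = 1.2), seed = 71)
  tr <- simulate_trio(sc, seed = 71)

  # a single domain spanning the whole protein: DSA table equals WPA table
  wpa <- asymmetry_table(tr, NULL)
  dsa_full <- asymmetry_table(tr, 1:300, background = "protein")
  expect_equal(unclass(wpa)[1:4], unclass(dsa_full)[1:4])

  # domain-restricted N with whole-protein S background
  dom <- asymmetry_table(tr, 1:60, background = "protein")
  reg <- asymmetry_table(tr, 1:60, background = "region")
  expect_equal(dom[["S1"]], wpa[["S1"]])   # background from whole protein
  expect_lte(reg[["S1"]], dom[["S1"]])     # region background is smaller
  expect_equal(dom[["N1"]], reg[["N1"]])

  expect_error(asymmetry_table(tr, integer(0)),
               class = "empty_region_error")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  p <- c(0.001, 0.2, 0.04, 0.9)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
})

test_that("batch testing flags a strong asymmetric pair among nulls", {
  hits <- 0L
  for (run in 1:10) {
    trios <- list()
    for (k in 1:10) {
      scn <- simulation_scenario(
        n_codons = 1000,
        t_by_branch = c(copy1 = 0.8, copy2 = 0.8, outgroup = 1.6),
        omega_by_branch = c(copy1 = 0.5, copy2 = 0.5, outgroup = 0.5),
        seed = run * 500 + k)
      pid <- sprintf("null%02d", k)
      trios[[pid]] <- simulate_trio(scn, seed = run * 500 + k,
                                    pair_id = pid)
    }
    sca <- simulation_scenario(
      n_codons = 1000,
      t_by_branch = c(copy1 = 0.8, copy2 = 0.8, outgroup = 1.6),
      omega_by_branch = c(copy1 = 1.5, copy2 = 0.2, outgroup = 0.5),
      seed = run * 500 + 99)
    trios[["asym"]] <- simulate_trio(sca, seed = run * 500 + 99,
                                     pair_id = "asym")
    res <- test_asymmetry(trios, level = "WPA")
    expect_s3_class(res, "asymmetry_results")
    expect_true(all(res$q_value >= res$p_value))
    row <- res[res$pair_id == "asym", ]
    if (row$asymmetric && row$faster_copy == "copy1") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("swapping the copies flips the faster-copy call", {
  sca <- simulation_scenario(
    n_codons = 1000,
    t_by_branch = c(copy1 = 0.8, copy2 = 0.8, outgroup = 1.6),
    omega_by_branch = c(copy1 = 1.5, copy2 = 0.2, outgroup = 0.5),
    seed = 81)
  tr <- simulate_trio(sca, seed = 81)
  sw <- codon_trio(tr$pair_id, tr$copy2, tr$copy1, tr$outgroup)
  r1 <- test_asymmetry(list(p = tr), level = "WPA")
  r2 <- test_asymmetry(list(p = sw), level = "WPA")
  expect_equal(r1$p_value, r2$p_value)
  expect_setequal(c(r1$faster_copy, r2$faster_copy), c("copy1", "copy2"))
})

test_that("admission filters populate the exclusions table", {
  sc_ok <- simulation_scenario(n_codons = 300, seed = 91)
  tr_ok <- simulate_trio(sc_ok, seed = 91, pair_id = "ok")
  # too little divergence -> fails dS >= 0.2
  sc_low <- simulation_scenario(n_codons = 300,
                                t_by_branch = c(copy1 = 0.05, copy2 = 0.05,
                                                outgroup = 0.1), seed = 92)
  tr_low <- simulate_trio(sc_low, seed = 92, pair_id = "low")
  arch_ab <- domain_architecture("a", c("A", "B"), c(1, 150), c(100, 250))
  arch_ba <- domain_architecture("b", c("B", "A"), c(1, 150), c(100, 250))

  res <- test_asymmetry(
    list(ok = tr_ok, low = tr_low),
    architectures = list(ok = list(arch_ab, arch_ab, arch_ba),
                         low = arch_ab),
    level = "DSA")
  ex <- attr(res, "exclusions")
  expect_setequal(ex$pair_id, c("ok", "low"))
  expect_equal(ex$reason[ex$pair_id == "ok"], "architecture_mismatch")
  expect_equal(ex$reason[ex$pair_id == "low"], "ds_filter")
  expect_equal(nrow(res), 0L)
})

test_that("bootstrap support is deterministic and zero for identical seqs", {
  tr0 <- random_trio(100, seed = 13, mut = 0)
  expect_equal(bootstrap_support(tr0, level = "WPA", n_reps = 20,
                                 seed = 1), 0)
  sc <- simulation_scenario(n_codons = 400, seed = 14)
  tr <- simulate_trio(sc, seed = 14)
  s1 <- bootstrap_support(tr, level = "WPA", n_reps = 30, seed = 99)
  s2 <- bootstrap_support(tr, level = "WPA", n_reps = 30, seed = 99)
  expect_identical(s1, s2)
})

test_that("sampled-column WPA control reduces to WPA at full length", {
  sc <- simulation_scenario(
    n_codons = 500,
    t_by_branch = c(copy1 = 0.8, copy2 = 0.8, outgroup = 1.6),
    omega_by_branch = c(copy1 = 1.5, copy2 = 0.2, outgroup = 0.5),
    seed = 15)
  tr <- simulate_trio(sc, seed = 15)
  tab <- asymmetry_table(tr, NULL)
  p_wpa <- fisher_exact_2x2(tab[["N1"]], tab[["S1"]], tab[["N2"]],
                            tab[["S2"]])
  frac_full <- sampled_wpa_control(tr, target_length = 500, n_reps = 10,
                                   seed = 3)
  expect_equal(frac_full, as.numeric(p_wpa <= 0.05))

  # power decays as the sampled length shrinks (in expectation)
  f_long <- sampled_wpa_control(tr, 400, n_reps = 60, seed = 4)
  f_short <- sampled_wpa_control(tr, 40, n_reps = 60, seed = 4)
  expect_lte(f_short, f_long)
  # determinism
  expect_identical(sampled_wpa_control(tr, 100, n_reps = 20, seed = 5),
                   sampled_wpa_control(tr, 100, n_reps = 20, seed = 5))
  expect_error(sampled_wpa_control(tr, 0, n_reps = 5, seed = 1),
               class = "config_error")
  expect_error(sampled_wpa_control(tr, 501, n_reps = 5, seed = 1),
               class = "config_error")
})
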