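# NG86 counting engine: site fractions, pathway-averaged substitution
# counts, ancestral inference, per-branch rates and the dS admission filter.

test_that("NG86 site counts match enumeration and normalize to 3", {
  expect_equal(count_sites_ng86("TTT"),
               c(S_sites = 1 / 3, N_sites = 8 / 3))
  expect_equal(count_sites_ng86("GGG"), c(S_sites = 1, N_sites = 2))
  expect_error(count_sites_ng86("TAA"), class = "codon_error")

  for (cod in SENSE) {
    s <- count_sites_ng86(cod)
    expect_equal(unname(sum(s)), 3)
    expect_equal(s, oracle_ng86_sites(cod), tolerance = 1e-12)
  }
})

test_that("pathway-averaged substitution counts match the DFS oracle", {
  expect_equal(count_substitutions_ng86("TTT", "TTA"), c(S = 0, N = 1))
  expect_equal(count_substitutions_ng86("TTT", "TTC"), c(S = 1, N = 0))
  expect_equal(count_substitutions_ng86("TTT", "GTA"), c(S = 0.5, N = 1.5))
  expect_equal(count_substitutions_ng86("AAA", "AAA"), c(S = 0, N = 0))
  expect_error(count_substitutions_ng86("TAA", "TTT"), class = "codon_error")

  # spot-check random pairs against the independent recursion
  set.seed(1)
  for (k in 1:40) {
    pair <- sample(SENSE, 2)
    got <- count_substitutions_ng86(pair[1], pair[2])
    expect_equal(unname(got), unname(oracle_ng86_pair(pair[1], pair[2])),
                 tolerance = 1e-12, label = paste(pair, collapse = "->"))
  }
})

test_that("ancestral inference is majority rule with outgroup tie-break", {
  tr <- codon_trio("p", "TTTTTATTA", "TTTTTTTTC", "TTTTTTTTG")
  asg <- infer_ancestral_codons(tr)
  expect_equal(asg$ancestor, c("TTT", "TTT", "TTG"))
  expect_equal(asg$ambiguous, c(FALSE, FALSE, TRUE))

  # column (TTA, TTT, TTT): single change attributed to copy1
  tr2 <- codon_trio("p", "TTA", "TTT", "TTT")
  bc <- branch_counts(tr2)
  expect_equal(bc$N[bc$branch == "copy1"], 1)
  expect_equal(sum(bc$N[bc$branch != "copy1"]), 0)

  # agreement with the enumerating Fitch oracle on random columns
  set.seed(42)
  for (k in 1:50) {
    cods <- sample(SENSE, 3, replace = TRUE)
    tr3 <- codon_trio("p", cods[1], cods[2], cods[3])
    expect_equal(infer_ancestral_codons(tr3)$ancestor,
                 oracle_fitch(cods[1], cods[2], cods[3]))
  }
})

test_that("branch counts: zeros on identical trios, additivity, site sums", {
  tr <- random_trio(30, seed = 9, mut = 0)
  bc <- branch_counts(tr)
  expect_equal(bc$N, rep(0, 3))
  expect_equal(bc$S, rep(0, 3))
  expect_equal(bc$dN, rep(0, 3))
  expect_equal(bc$dS, rep(0, 3))

  tr2 <- random_trio(40, seed = 10, mut = 0.3)
  whole <- branch_counts(tr2)
  part1 <- branch_counts(tr2, columns = 1:15)
  part2 <- branch_counts(tr2, columns = 16:40)
  expect_equal(part1$N + part2$N, whole$N)
  expect_equal(part1$S + part2$S, whole$S)
  # N_sites + S_sites = 3 x unmasked columns
  expect_equal(whole$N_sites + whole$S_sites,
               rep(3 * attr(whole, "n_unmasked"), 3))
  expect_error(branch_counts(tr2, columns = c(1, 99)),
               class = "column_range_error")
})

test_that("swapping copy1 and copy2 swaps their branch counts exactly", {
  tr <- random_trio(60, seed = 11, mut = 0.4)
  sw <- codon_trio(tr$pair_id, tr$copy2, tr$copy1, tr$outgroup)
  a <- branch_counts(tr); b <- branch_counts(sw)
  for (col in c("N", "S", "N_sites", "S_sites", "dN", "dS")) {
    expect_equal(a[a$branch == "copy1", col], b[b$branch == "copy2", col])
    expect_equal(a[a$branch == "copy2", col], b[b$branch == "copy1", col])
    expect_equal(a[a$branch == "outgroup", col],
                 b[b$branch == "outgroup", col])
  }
})

test_that("branch counts equal the explicit brute force on tiny trios", {
  # independent per-column recomputation: Fitch oracle ancestor + DFS
  # pathway oracle + site enumeration oracle
  for (seed in c(3, 4, 5)) {
    tr <- random_trio(10, seed = seed, mut = 0.5)
    got <- branch_counts(tr)
    split3 <- function(s) substring(s, seq(1, nchar(s), 3),
                                    seq(3, nchar(s), 3))
    cods <- sapply(c("copy1", "copy2", "outgroup"),
                   function(r) split3(tr[[r]]))
    exp_N <- exp_S <- exp_Ns <- exp_Ss <- c(copy1 = 0, copy2 = 0,
                                            outgroup = 0)
    for (col in 1:10) {
      anc <- oracle_fitch(cods[col, 1], cods[col, 2], cods[col, 3])
      anc_sites <- oracle_ng86_sites(anc)
      for (b in 1:3) {
        role <- c("copy1", "copy2", "outgroup")[b]
        cnt <- oracle_ng86_pair(anc, cods[col, b])
        exp_N[role] <- exp_N[role] + cnt[["N"]]
        exp_S[role] <- exp_S[role] + cnt[["S"]]
        leaf_sites <- oracle_ng86_sites(cods[col, b])
        exp_Ns[role] <- exp_Ns[role] +
          (anc_sites[["N_sites"]] + leaf_sites[["N_sites"]]) / 2
        exp_Ss[role] <- exp_Ss[role] +
          (anc_sites[["S_sites"]] + leaf_sites[["S_sites"]]) / 2
      }
    }
    expect_equal(got$N, unname(exp_N), tolerance = 1e-10)
    expect_equal(got$S, unname(exp_S), tolerance = 1e-10)
    expect_equal(got$N_sites, unname(exp_Ns), tolerance = 1e-10)
    expect_equal(got$S_sites, unname(exp_Ss), tolerance = 1e-10)
    # Jukes-Cantor correction of the proportions
    expect_equal(got$dN, -0.75 * log(1 - 4 * (got$N / got$N_sites) / 3))
  }
})

test_that("dS admission filter applies both bounds", {
  fake_bc <- function(ds1, ds2) {
    structure(data.frame(branch = c("copy1", "copy2", "outgroup"),
                         dS = c(ds1, ds2, 1)),
              class = c("branch_counts", "data.frame"))
  }
  expect_true(ds_filter(fake_bc(0.5, 0.7)))
  expect_false(ds_filter(fake_bc(0.1, 0.5)))   # below dS >= 0.2
  expect_false(ds_filter(fake_bc(0.5, 2.5)))   # above dS <= 2
  expect_true(ds_filter(fake_bc(0.2, 2.0)))    # bounds inclusive
  expect_warning(res <- ds_filter(fake_bc(NA, 0.5)), "undefined")
  expect_false(res)
})

test_that("saturated branches are reported NA with a typed warning", {
  # force near-total divergence between ancestor and copy1
  set.seed(2)
  anc <- sample(SENSE, 400, replace = TRUE)
  far <- sample(SENSE, 400, replace = TRUE)
  tr <- codon_trio("sat", paste(far, collapse = ""),
                   paste(anc, collapse = ""), paste(anc, collapse = ""))
  expect_warning(bc <- branch_counts(tr), class = "saturation_warning")
  expect_true(is.na(bc$dN[bc$branch == "copy1"]) ||
                is.na(bc$dS[bc$branch == "copy1"]))
})

test_that("external branch-count tables import per pair", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("pair_id\tbranch\tN\tS\tdN\tdS",
               "p1\tcopy1\t10\t5\t0.1\t0.2",
               "p1\tcopy2\t4\t6\t0.05\t0.25",
               "p1\toutgroup\t30\t20\t0.4\t0.9"), f)
  got <- read_branch_counts_tsv(f)
  expect_named(got, "p1")
  expect_equal(got$p1$omega[1], 0.5)
  expect_s3_class(got$p1, "branch_counts")
})
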