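---
title: "Detecting asymmetric evolution of gene duplicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting asymmetric evolution of gene duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupasym)
```

## The question and the data

After a whole-genome duplication, each retained duplicate pair consists of
two copies that have evolved for exactly the same amount of time. If one
copy diverges faster in protein sequence than the other — asymmetric
evolution — that is a classic signature of neofunctionalization. `dupasym`
asks this question on a *trio*: the two duplicate copies plus an outgroup
ortholog, related by a fixed unrooted 3-leaf tree whose internal node is
the duplication event. Evolutionary rates are obtained separately for each
branch.

The inputs are (a) in-frame codon alignments of trios (aligned FASTA, one
record per role, ids tagged `|copy1`, `|copy2`, `|outgroup`), (b) protein
domain-architecture tables (TSV: `protein_id`, `domain_name`, `start_aa`,
`end_aa`), and (c) optionally spatio-temporal expression tables (TSV:
`gene_id`, `stage`, `anatomy_term`). Only pairs whose three proteins share
an identical ordered domain architecture are analysed, and only pairs with
duplicate-branch synonymous divergence `0.2 <= dS <= 2` (large enough to
measure, not saturated) are admitted.

## Per-branch substitution counting

The counting engine is a self-contained desk-scale substitute for an ML
free-ratios fit:

1. **Ancestral inference.** Fitch parsimony on the 3-leaf star: per codon
   column the ancestor at the duplication node is the majority codon; when
   all three leaves disagree, the outgroup codon is used and the column is
   flagged ambiguous. Columns with a gap or `N` in any sequence are masked
   everywhere — a deliberately conservative convention, since the source
   data's treatment of alignment gaps in domain coordinates is not
   recoverable.
2. **NG86 counting.** Synonymous/non-synonymous *sites* per codon are the
   fraction of non-stop single-nucleotide changes that are synonymous,
   rescaled to sum to 3. *Substitutions* between ancestor and leaf are
   classified step-wise along all shortest mutational pathways avoiding
   stop codons, averaged uniformly (the classic NG86 convention). Sites per
   branch average the ancestral and descendant sequences.
3. **Distance correction.** `dN` and `dS` are Jukes–Cantor corrected
   proportions, `d = -(3/4) log(1 - 4p/3)`; a proportion at or above 3/4 is
   reported `NA` with a saturation warning, and such pairs fail the dS
   admission filter.

**Operating regime.** Parsimony-plus-NG86 is accurate at moderate
divergence. On trios simulated at duplicate-branch `t = 0.2`
substitutions/codon (dS about 0.2) with an outgroup twice as long, the
test suite verifies that the mean duplicate-branch omega is recovered
within ±20% for generating omega in {0.2, 0.5, 1.0}; that regime is where
the recovery experiment runs. At the deep study-scale tree (duplicate dS 0.6,
outgroup path dS 2) two biases dominate: uniform pathway averaging
overweights non-synonymous paths when selection is purifying, and ancestor
misassignment at the near-saturated outgroup reattributes shared-path
changes to both duplicate branches. The reattribution is symmetric between
the copies — which is why the asymmetry *tests* below stay valid (indeed
conservative) even where the absolute rates are biased.

## The Fisher-exact asymmetry test

For each admitted pair, substitutions on the two duplicate branches form a
2×2 table — non-synonymous counts as foreground, synonymous counts as
background:

|        | N   | S   |
|--------|-----|-----|
| copy 1 | N1  | S1  |
| copy 2 | N2  | S2  |

The two-sided exact p-value sums the hypergeometric probabilities of all
tables with the observed margins that are no more probable than the
observed table (point-probability rule — the standard "more extreme"
reading). Fractional counts (pathway averages) are rounded
half-away-from-zero first. The test runs at four levels:

* **WPA** — whole protein: N and S from all columns.
* **CDA** — combined domains: N from the union of domain columns, S from
  the whole protein (a `background = "region"` switch restricts S to the
  domains as well).
* **DSA** — one test per domain: N from that domain's columns, S from the
  whole protein.
* **LINKER** — the non-domain complement, S from the whole protein.

Within a level and run, p-values are Benjamini–Hochberg adjusted; a unit is
called asymmetric when `p <= 0.05` and `q <=` the working FDR of 10%. The
faster copy is the one with the larger `N/(S+1)` odds (add-one smoothing
settles zero-S tables; exact ties are reported as `tie`). Robustness of a
call can be quantified by `bootstrap_support()` (codon columns resampled
with replacement) and the power cost of shorter alignments by
`sampled_wpa_control()` (random column subsets of a target length).

## The likelihood-ratio test

The likelihood engine implements a Goldman–Yang codon model: single-
nucleotide codon changes have rate proportional to the target codon's
frequency, times `kappa` for transitions, times the branch's `omega` for
non-synonymous changes; the generator is scaled to one expected
substitution per codon per unit branch length. Codon frequencies are fixed
at their empirical F3x4 estimate; `kappa` is shared across branches. The
free model gives each of the three branches its own omega; the constrained
model ties the two duplicate branches (`omega1 = omega2`), leaving the
outgroup omega free in both (on a 3-branch unrooted tree this is the only
reading that keeps the comparison to a single degree of freedom). The
statistic `2|lnL_free - lnL_constrained|` is referred to chi-square with
1 df.

Fitting is bounded quasi-Newton (`L-BFGS-B`) on log-parameters from a
counting-informed start, with optional random restarts (default 3 in
`fit_branch_model()`; the convenience `lrt_test()` uses warm starts between
the two models so the nested inequality holds to optimizer tolerance).
Spectral decompositions of the reversible generator are cached per
`(kappa, omega)` so branch-length moves are cheap.

Two calibration caveats, observed with this package's own simulator:
the chi-square reference is asymptotic — at alignments of a few hundred
codons the null rejection rate at the 5% level runs visibly above
nominal, while at 2,000 codons it sits within 5% ± 3% (the calibration
test asserts that); and at the deep study-scale
tree the free-model optimizer is unreliable (flat likelihood in the
near-saturated outgroup direction), so likelihood results should be read
at moderate divergence. Relatedly, with *this* counting engine the FET is
the more conservative of the two tests: its parsimony counts place shared
outgroup-path changes on both duplicate rows, which correlates the rows
and shrinks apparent differences. A FET fed by ML branch counts does not
share that behaviour, so the relative sensitivity of FET and LRT here
should not be extrapolated to ML-count pipelines.

## Downstream pattern statistics

* **Clustering** (`clustering_test`): per copy and domain, one-sided FET of
  `[[N_dom, S_dom], [N_other, S_other]]` against the other domains —
  are the non-synonymous changes concentrated in this domain? Default
  per-domain threshold 0.05 (exposed as `cluster_alpha`).
* **Assortment** (`assortment_analysis`): is "exactly one asymmetric
  domain per multi-domain protein" more common than random assortment?
  The null permutes asymmetric labels over all domain slots, preserving
  per-protein domain counts and the total asymmetric count — the most
  literal reading of random assortment. Expectation and one-sided p come
  from the permutations; the suite checks the permutation expectation
  against exhaustive enumeration on small instances.
* **Faster-copy concordance** (`faster_copy_concordance`): among pairs
  with two or more asymmetric domains, the fraction where every faster
  copy is the same gene copy.
* **Family frequency** (`family_asymmetry_frequency`): per domain family,
  hypergeometric over-/under-representation of asymmetric calls against
  the pooled rate. This construction is ours; the source analysis did not
  specify its 2×2, so printed per-family p-values elsewhere are not
  comparable.
* **Interleaving** (`interleaving_runs_test`): positions uniquely mutated
  in exactly one copy, ordered along the protein, tested for too few
  label runs (Wald–Wolfowitz; exact conditional distribution up to 20
  labelled positions, continuity-corrected normal beyond; per-gene
  p-values combinable by Stouffer's method). This is a declared stand-in
  for a supplementary aggregation whose exact statistic is not visible.

## Substitution severity and expression divergence

Within each domain the two copies' translated sequences are compared at
positions where they differ; the mean BLOSUM62 score of those
substitutions (lower = rarer = more radical) is the domain's severity
score. Scores are per-domain means by default (a pooled-substitution
switch is trivial to apply downstream since counts are reported).
Asymmetric and symmetric domains are compared by a one-sided rank-sum
test — exact by enumeration over group assignments up to a combined n of
20 (valid under ties), normal approximation with tie correction beyond —
optionally after percentile matching: each asymmetric domain draws one
symmetric partner whose pooled-percentile rank lies within 10 points.

Expression divergence uses per-stage Jaccard overlap of anatomy-term sets
between the two copies; stages where either gene carries the configurable
ubiquitous sentinel term (default `"whole organism"`) are excluded, and
per-stage values enter the group comparison unaggregated by default (a
per-pair mean switch is provided). No ontology reasoning is attempted —
terms are opaque identifiers.

## The simulator

`simulate_trio()` draws a root sequence at the duplication node from the
scenario's codon frequencies and evolves it independently along the three
branches using the *same* transition matrices as the likelihood engine
(single source of truth), with per-(domain, branch) omega overrides
applied segment-wise. Alignments are gap-free and there is no among-site
rate variation — so passing tests say nothing about gap handling or rate
heterogeneity in real data; masking and coordinate conventions are
exercised by hand-built fixtures instead.

The default scenario encodes the calibration conditions of the study
design: neutral evolution (omega = 1 everywhere), `kappa = 2`, uniform
sense-codon frequencies, equal duplicate branches with generating dS near
0.6 each, and an outgroup branch placing the duplicate-to-outgroup dS near
2. Branch lengths `t = (1.7, 1.7, 4.0)` substitutions/codon were
calibrated once against the simulator's truth record to hit those dS
targets and then frozen. `false_positive_experiment()` runs the full
count→FET→BH pipeline on replicates of this scenario:

```{r fp, eval = FALSE}
fp <- false_positive_experiment(n_reps = 1000, n_codons = 10000, seed = 1)
100 * as.numeric(fp)   # percent of replicates flagged at p <= 0.05, FDR 10%
```

`simulate_expression()` draws paired per-stage term sets whose expected
Jaccard overlap equals a target, by randomizing the shared-term count
between the two integers bracketing the exact solution of
`J = s/(2n - s)`.

## Numerical choices and problem sizes

* FET ties in the point-probability rule use a `1e-7` relative tolerance.
* Optimizer: lnL tolerance ~1e-7 (`factr = 1e7`–`1e8`), parameters bounded
  in `[1e-4, 60]` on the natural scale.
* Zero-frequency protection: F3x4 uses a 0.5 pseudocount per base.
* The runs-test switches from exact to normal at 20 labelled positions;
  the rank-sum tests switch from enumeration to normal at a combined 20.
* Test-suite problem sizes: the false-positive experiment runs at 500
  replicates × 2,000 codons (the full-scale 1000 × 10,000 run lives in
  `scripts/acceptance.R`); LRT calibration at 200 × 2,000 codons; omega
  recovery at 50 trios × 10,000 codons per omega. These sizes were chosen
  so the whole suite completes in minutes on one core while keeping every
  binomial margin comfortable.

## Known limitations

* Parsimony ancestors bias *absolute* per-branch rates at deep divergence;
  asymmetry tests remain valid by symmetry, but per-branch omega values
  from `branch_counts()` should only be interpreted quantitatively at
  moderate divergence. An import hook (`read_branch_counts_tsv()`) accepts
  externally computed ML branch counts in place of the built-in engine.
* No gap simulation, no among-site rate variation, no codon-frequency-
  weighted site counting, no site or branch-site models.
* The family-frequency and interleaving constructions are this package's
  own explicit definitions of analyses whose original constructions were
  under-specified; their outputs are internally consistent but not
  comparable to any externally printed p-value.
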