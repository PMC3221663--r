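---
title: "Models and methods: site-level selection pressure in paralog subgroups"
author: "siteomega"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: site-level selection pressure in paralog subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`siteomega` analyses the evolutionary selection pressure acting on amino
acid positions of a multiple sequence alignment of a small paralog subgroup
— 3 to 10 closely related protein-coding genes, typically the concatenated
seven-transmembrane (7TM) fragments of a class A GPCR subgroup. This
vignette explains the models, the tunable parameters and their defaults, the
synthetic-data generator, and the numerical and design choices, in the
package's own terms.

## The codon substitution model

Evolution is modeled on the 61 sense codons of the standard genetic code.
The generator matrix assigns rate zero to codon pairs differing at more than
one nucleotide; a single-nucleotide change from codon *i* to *j* has rate
π_j multiplied by 1 (synonymous transversion), κ (synonymous transition),
ω (nonsynonymous transversion) or ωκ (nonsynonymous transition). The matrix
is scaled so that branch lengths are expected substitutions per codon.
Equilibrium codon frequencies π default to the F3x4 estimator
(position-specific nucleotide frequencies; options: equal, F1x4, F61) —
the conventional default where the choice is not dictated by the data.

ω heterogeneity across sites uses the standard site-class mixtures M0, M1a,
M2a, M3 (K = 3 classes by default, the usual convention), M7 (beta
distribution discretized into ten equal-probability categories, each
represented by its exact conditional bin mean computed from incomplete-beta
differences) and M8 (beta plus one class with ω ≥ 1). All classes share κ,
π and branch lengths; class rate matrices share a common scale computed
from the mixture, so relative rates across classes are meaningful. The
fixed-sites pair A/B instead assigns partition-specific ω to a designated
column set (the key positions) versus the rest; model B adds one free
parameter by default (`df = 1`; a partition-specific κ is available,
making `df = 2`).

Site likelihoods are computed by Felsenstein pruning in a compiled
RcppArmadillo kernel, with transition matrices from the symmetrized
eigendecomposition of the reversible generator, per-node column rescaling
against underflow, gap cells treated as missing data (partial-likelihood
vectors of ones), and alignment columns compressed to unique patterns.

## Fitting and testing

`fit_site_model()` maximizes the log-likelihood over κ, branch lengths and
the model-specific class parameters with `nlminb` on transformed parameters
(rates and branch lengths by log, proportions by stick-breaking, the M8
positive-class ω as 1 + exp). Defaults: two jittered restarts plus a short
polish run at tightened tolerance; convergence at relative tolerance 1e-10
(heavier simulation loops in the tests use 1e-7–1e-8, which is ample for
the quantities asserted there). Branch lengths are re-estimated under every
model; `fix_blens` fixes them for speed.

Nested models are compared with `likelihood_ratio_test()` (or `anova()`):
LR = 2Δ against a chi-square upper tail, `df` defaulting to the free
parameter difference (2 for M1a/M2a and M7/M8, 4 for M0/M3, 1 for A/B),
the alternative called tenable at α = 0.05 by default. `site_model_tests()`
orchestrates the four standard strategies and addresses two numerical
hazards of these mixtures:

* **Boundary warm starts.** Each alternative starts from its fitted null
  (positive-class proportion just off zero). Because the ω₂ direction is
  multimodal, a second start with a real positive class (ω₂ ≈ 4, p₂ = 5%)
  is always tried and the better optimum kept.
* **Negative Δ.** The alternative nests the null exactly, so lnL_alt ≥
  lnL_null mathematically. A deficit beyond 1e-4 triggers jittered refits;
  any residual sub-tolerance deficit is clamped to equality (the null's
  solution is itself an admissible alternative solution).

Per-site reports use naive empirical Bayes at the MLEs: posterior class
memberships give P(ω > 1) and the posterior-mean (NEB) ω per column;
columns exceeding the 0.95 posterior threshold are called Positive. The
per-subgroup ω profile is taken from M7, or from M8 when Test 2 rejects —
so positively selected subgroups contribute the model that actually
represents their positive class.

## Counting methods and admission

`ng_pairwise()` implements Nei–Gojobori counting: per-codon synonymous site
fractions (s + n = 3 exactly), difference counts for codon pairs differing
at k > 1 positions averaged over all k! mutational pathways excluding those
through stop codons, and the Jukes–Cantor correction
d = −(3/4) ln(1 − (4/3)p), undefined (flagged saturated) at p ≥ 3/4. The
counting literature uses more than one stop-codon convention, so it is
switchable: by default mutations to stops count as
nonsynonymous when splitting a position's three alternatives; the
alternative convention excludes them from the site split. If every pathway
between a codon pair passes through a stop, all pathways are used (this
never occurs for the standard code, but the fallback keeps the counts
defined).

`subgroup_admission()` applies the subgroup filter: admitted when the
maximum pairwise dN < 1; otherwise the member with the largest mean dN to
the others is removed (ties by label order) until the condition holds or
only three members remain, in which case the subgroup is flagged `N`.
Subgroups with max dS ≥ 3 are retained but flagged `S`. "Maximum average
dN" is read as the maximum over pairs of the pairwise dN (each pairwise
value already averages the two sequences' site normalizations); a
mean-over-pairs variant would be a one-line change in the caller.

## Trees

Protein distances use the JTT maximum-likelihood distance
(`phangorn::dist.ml`) or the closed-form Kimura correction. Neighbor
joining (`ape::nj`) is wrapped to clamp negative branch-length estimates to
zero, shifting the deficit to the adjacent interior branch. Bootstrap
support comes from column resampling with majority-rule consensus; the
replicate count (default 100) and seed are explicit arguments. Trees enter
model fitting as topology plus starting lengths; the likelihood machinery
re-estimates the lengths.

## Profiles, cohorts and diversity

`cohort_null()` contrasts the key-position mean ⟨ω_key⟩ with 200 cohorts of
10 columns sampled uniformly without replacement within a cohort, with
replacement across cohorts. Key columns stay in the sampling pool by
default (pure random draw over the 7TM columns; an exclusion switch
exists). Reported: the cohort-mean distribution's mean and SD, the
z-offset, a 2σ flag, the ratio ⟨ω_key⟩ over the grand mean, and the
ω_key > 0.1 threshold flag used to label subgroups not under strong
negative selection (the cutoff below which all small-molecule subgroups
fall). `category_comparison()` applies the Kruskal–Wallis rank-sum test
across ligand categories (fully tied inputs return H = 0, p = 1 by
convention), and `trend_report()` runs the OLS summaries of ⟨ω_key⟩ against
⟨ω_random7TM⟩ and of their ratio against each mean on a log10 axis.

Column diversity: Shannon entropy in bits with gaps excluded from the
frequencies (a gaps-as-21st-symbol option exists, which changes the
4.32-bit ceiling), Karlin–Brocchieri similarity
m(x,y)/√(m(x,x)m(y,y)) averaged over sequence pairs under BLOSUM80, and
D_key, the mean pairwise JTT-ML distance over the 10-key-column
mini-alignment (per-column averaging available; the concatenated reading is
the default because ML distances on single columns are poorly conditioned).
`diversity_vs_selection()` regresses a diversity measure on
log10⟨ω_key⟩, with a second fit restricted to ⟨ω_key⟩ < 0.1; subgroups
flagged `N` should be excluded via `keep`.

## The synthetic-data generator

The generator is first-class, tested code: every pipeline input can be
produced with known ground truth. `random_subgroup_tree()` draws a random
topology with gamma(2)-distributed edge lengths — substantial terminal
branches, as in paralog families that diverged anciently; coalescent-shaped
trees were rejected because their near-zero recent branches make tips
nearly identical and destroy per-site information — rescaled to a target
maximum tip-to-tip depth (default 1.2 expected substitutions/codon, placing
pairwise dS roughly in 0.5–2). `simulate_codon_alignment()` draws a class
per column, a root codon from π, and walks the tree through the class
transition matrices; truth (per-column class and ω) is attached to the
result.

`make_subgroup_fixture()` emits complete input bundles under three regimes:

* **strong-negative** — key columns at ω = 0.02 over a background of
  ω = 0.05 (55%), 0.3 (35%), 0.9 (10%): the small-molecule receptor
  pattern (strong negative / moderate / near-neutral classes).
* **mixed** — key columns share the background: no distinct key-position
  pressure.
* **positive-at-key** — one key column at ω = 6.3 and two non-key columns
  at ω = 4 over a constrained background (60% at 0.05, 40% at 0.2; other
  keys 0.02), on a balanced equal-edge tree of depth 0.8.

Bundles are guaranteed to satisfy the admission envelope (max dN < 1,
max dS < 3), resampling from derived seeds when a draw violates it; the
same seed yields byte-identical files.

The positive-at-key numbers encode a deliberate trade-off. With exactly
three truly positive columns among 190 at four taxa, the likelihood gain
available to the alternative at each such column is capped by the mixing
proportion (−log p̂₂ ≈ 4 with p₂ ≈ 3/190) against a per-column class
log-likelihood ratio that four sequences can support (≈ 5 at best before
substitution saturation sets in). Raising the non-key ωs or deepening the
tree buys rejection power for Tests 1 and 2 but saturates the posteriors
and randomizes which positive column ranks first; shallower or weaker
settings do the reverse. The chosen design balances the two: the planted
key column carries the strongest signal (ω 6.3 vs 4), and the balanced
shallow tree keeps its posterior distinguishable. Users wanting guaranteed
rejections should plant a larger positive class — with ~8% of columns
positive, as in real subgroups showing broad positive selection, both tests
reject readily.

What passing tests on these fixtures do **not** show about real data: the
generator evolves sites independently under the fitting model's own
assumptions (no indels — gaps only arise from ambiguous nucleotides in real
input, no rate variation beyond the ω classes, no codon-usage structure
beyond stationarity, no alignment error, no recombination). Agreement on
fixtures validates the estimation machinery, not the model's adequacy for
any particular receptor family.

## Problem sizes and runtime choices

The test suite exercises the estimators at sizes chosen to make each
property measurable on one CPU: ω recovery at 8 taxa × 500 codons
(20 replicates per ω), detection on the 4-taxon × 190-codon fixture
(20 seeds), and null calibration on 3-taxon × 150-codon nearly-neutral
simulations (100 replicates) — subgroups of three members are the modal
size in the motivating application. The convergence statement for the
cohort null is asserted on the median standardized deviation over five
seeds, because a single 2-standard-error draw is a 95% interval and fails
one seed in twenty by construction.

## Known limitations

* NEB posteriors ignore MLE uncertainty (no Bayes empirical Bayes); with
  3–10 sequences the posteriors are accordingly optimistic.
* The chi-square reference for Tests 1 and 2 is conservative at the
  boundary; calibration is asserted as "not anti-conservative" rather than
  exact.
* Branch models, branch-site models, and amino-acid- or nucleotide-level
  likelihood models are out of scope.
* PROTDIST's discretized JTT tables are not reproduced bit-for-bit; the
  JTT-ML distances here serve topology building and rough distance
  reporting.
* The admission filter treats saturated (undefined) pairwise distances as
  exceeding their bound, which is the conservative direction.
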