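# siteomega

Site-level selection pressure in small paralog subgroups from codon
substitution models, with the seven-transmembrane (7TM) domains of class A
G protein-coupled receptors (GPCRs) as the motivating application.

## The scientific problem

GPCR paralog subgroups (3–10 closely related receptors) differ widely in the
evolutionary pressure acting on the ten "key" binding-cavity positions of the
7TM bundle. The ratio of nonsynonymous to synonymous substitution rates,
ω = dN/dS, measures that pressure per codon site: ω < 1 indicates purifying
selection, ω = 1 neutral evolution, ω > 1 positive selection. `siteomega`
estimates per-site ω for a subgroup alignment and asks whether the key
positions are under distinct pressure — for example, whether receptors for
small-molecule ligands keep their binding cavity under strong negative
selection (ω < 0.05), or whether a subgroup shows statistically supported
positive selection at a key position.

The core is a 61-state codon substitution model (Goldman–Yang
parameterization): for sense codons i ≠ j differing at one nucleotide,

    q_ij = π_j · { 1, κ, ω, ωκ }

for synonymous transversions, synonymous transitions, nonsynonymous
transversions and nonsynonymous transitions respectively, scaled to one
expected substitution per codon per unit time. Site-to-site variation in ω
is modeled with the standard site-class mixtures:

| model | ω structure | free class parameters |
|-------|-------------|----------------------|
| M0 | one ratio | ω |
| M1a | nearly neutral | ω₀ < 1, p₀ (ω₁ = 1 fixed) |
| M2a | M1a + positive class | + p₂, ω₂ > 1 |
| M3 | K discrete classes | ω₁..ω_K, p₁..p_{K−1} |
| M7 | beta(p, q) in 10 equal-probability bins | p, q |
| M8 | M7 + positive class | + p₁₀, ω₁₀ ≥ 1 |
| fixed-sites A/B | per-partition ω (key vs rest) | ω_key, ω_rest |

Likelihoods are computed by Felsenstein pruning over all site classes
(RcppArmadillo kernel), maximized over κ, branch lengths and class
parameters, and compared by likelihood ratio tests between nested pairs:
Test 1 (M1a vs M2a), Test 2 (M7 vs M8), Test 3 (fixed-sites A vs B), Test 4
(M0 vs M3), with LR = 2Δ = 2(lnL_alt − lnL_null) against a chi-square tail.
Per-site naive empirical Bayes (NEB) posteriors give P(ω > 1) and the
posterior-mean ω per alignment column.

Around the core: Nei–Gojobori pathway counting of synonymous/nonsynonymous
sites and differences with Jukes–Cantor correction (the subgroup admission
filter max dN < 1, flag at max dS ≥ 3), JTT/NJ protein trees with bootstrap
consensus, a 200-cohort random-position null for ⟨ω_key⟩, and
alignment-column diversity (Shannon entropy, Karlin–Brocchieri BLOSUM80
similarity, JTT distance over the key columns).

## Worked example

Simulate a five-paralog subgroup in which ~7% of columns — among them key
position 3.29 (MSA column 68) — evolve under positive selection (ω = 6)
over a purifying background, then fit the beta site models and test:

```r
library(siteomega)

set.seed(5)
omega_true <- sample(c(0.05, 0.4), 190, replace = TRUE, prob = c(0.7, 0.3))
pos <- c(68, sort(sample(setdiff(1:190, 68), 13)))   # 14 positive columns
omega_true[pos] <- 6
tree <- random_subgroup_tree(5, depth = 1.0, seed = 6, edges = "equal")
aln <- simulate_codon_alignment(tree, 190, site_omega = omega_true, seed = 7)

res <- site_model_tests(aln, tree, tests = 2, restarts = 0)
res$lrt$test2
#> LRT M8 vs M7: Delta = 36.7981, LR = 2 Delta = 73.5963, df = 2, p = 1.04e-16
#>   tenable model at alpha = 0.05 : M8

rep8 <- neb_site_report(res$fits$M8, position_map = gpcr_key_positions())
rep8[rep8$column == 68, ]
#>    column bw_index  key P_positive neb_omega     call
#> 68     68     3.29 TRUE      0.959      7.92 Positive

sum(order(-rep8$P_positive)[1:14] %in% pos)
#> [1] 14
```

M8 is tenable over M7 — the data carry a positive-selection class the
beta-only model cannot express — the key position 3.29 is called Positive
at posterior 0.959 with posterior-mean ω ≈ 7.9, and all 14 truly positive
columns occupy the top 14 posterior ranks. The fit objects expose the
classic methods
(`print`, `summary`, `coef`, `logLik`, `fitted`, `plot`, `simulate`,
`anova`), and `run_pipeline()` drives the whole analysis (admission → tree →
fits → LRTs → profile → cohorts → diversity) from a YAML config.

The packaged tables `gpcr_subgroups()` and `gpcr_key_positions()` carry the
45 class A receptor subgroups with ligand annotations and the key-position
column map; `classify_subgroups()` reproduces the ligand-category census
(10 small-molecule, 9 lipid, 19 peptide, 6 divergent, 1 orphan).

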