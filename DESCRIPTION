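Package: siteomega
Title: Site-Level Selection Pressure in Paralog Subgroups from Codon Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates evolutionary selection pressure (omega = dN/dS) at amino
    acid positions of multiple sequence alignments of small paralog subgroups,
    with G protein-coupled receptor 7TM domains as the motivating application.
    Implements a 61-state codon substitution model with site-class mixtures
    (M0, M1a, M2a, M3, M7, M8 and fixed-sites partition models), maximum
    likelihood fitting with likelihood ratio tests between nested models, and
    naive empirical Bayes per-site posteriors. Also provides Nei-Gojobori
    pathway counting of synonymous and nonsynonymous substitutions with
    Jukes-Cantor correction and a subgroup admission filter, neighbor-joining
    protein trees with bootstrap consensus, random-cohort null comparisons for
    designated key positions, alignment-column diversity statistics (Shannon
    entropy, Karlin-Brocchieri BLOSUM80 similarity, JTT distances), and a
    forward codon-alignment simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
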