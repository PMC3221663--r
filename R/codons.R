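## Genetic-code tables shared by the rate matrix, the Nei-Gojobori counters and
## the simulator. Built once per session from Biostrings::GENETIC_CODE.

.siteomega <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons, in the conventional
#'   T/C/A/G lexicographic order (stop codons removed).
#' @export
sense_codons <- function() codon_tables()$codons

## Internal: memoised codon bookkeeping.
## $codons   61 sense codons; $aa their amino acids; $nt 61x3 nucleotide index
## $adj      list over ordered pairs differing at one position
codon_tables <- function() {
  if (!is.null(.siteomega$codon)) return(.siteomega$codon)
  gc_tab <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_tab)
  sense <- all_codons[gc_tab != "*"]
  aa <- unname(gc_tab[sense])
  nt <- t(vapply(strsplit(sense, ""), function(x)
    match(x, c("T", "C", "A", "G")), integer(3)))
  rownames(nt) <- sense

  n <- length(sense)
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(nt[, p], nt[, p], "!=")
  ## single-nucleotide neighbours: position and transition/transversion flag
  one <- which(ndiff == 1L, arr.ind = TRUE)
  pos <- integer(nrow(one)); ts <- logical(nrow(one))
  for (r in seq_len(nrow(one))) {
    i <- one[r, 1]; j <- one[r, 2]
    p <- which(nt[i, ] != nt[j, ])
    pos[r] <- p
    ## purines A,G are indices 3,4; pyrimidines T,C are 1,2
    ts[r] <- (nt[i, p] <= 2) == (nt[j, p] <= 2)
  }
  syn <- aa[one[, 1]] == aa[one[, 2]]

  .siteomega$codon <- list(
    codons = sense, aa = aa, nt = nt, ndiff = ndiff,
    pairs = data.frame(i = one[, 1], j = one[, 2], pos = pos,
                       transition = ts, synonymous = syn),
    stop_codons = all_codons[gc_tab == "*"],
    genetic_code = gc_tab
  )
  .siteomega$codon
}

## Translate a vector of codon strings ("ATG", ...) to amino acids; gaps and
## ambiguous codons give NA.
translate_codons <- function(codons) {
  gc_tab <- codon_tables()$genetic_code
  out <- unname(gc_tab[codons])
  out
}

codon_index <- function(codons) match(codons, codon_tables()$codons)
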