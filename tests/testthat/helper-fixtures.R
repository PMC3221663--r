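# Shared helpers: tiny in-code fixtures and independent oracles used across
# test files. Oracles are deliberately written as naive re-derivations,
# independent of the package's implementation paths.

write_temp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) cat(">", nm, "\n", seqs[[nm]], "\n", sep = "", file = con)
  close(con)
  path
}

# A small fixed unrooted 4-taxon tree.
tree4 <- function(blens = c(0.2, 0.15, 0.3, 0.1, 0.25)) {
  tr <- ape::read.tree(text = "((seq1:1,seq2:1):1,seq3:1,seq4:1);")
  tr$edge.length <- blens[seq_len(nrow(tr$edge))]
  tr
}

# Independent brute-force likelihood for an unrooted 4-taxon tree under a
# single-class codon model: sums over both internal-node states explicitly.
brute_force_lnL_4taxa <- function(aln, tree, kappa, omega, pi) {
  Q <- build_rate_matrix(kappa, omega, pi)
  trp <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  P <- lapply(seq_len(nrow(trp$edge)), function(e)
    transition_probabilities(Q, trp$edge.length[e]))
  n_tip <- length(trp$tip.label)
  root <- trp$edge[nrow(trp$edge), 1]
  other <- setdiff(unique(as.vector(trp$edge)), c(seq_len(n_tip), root))
  idx <- matrix(match(aln$codons[trp$tip.label, ], sense_codons()),
                nrow = n_tip)
  total <- 0
  for (h in seq_len(ncol(idx))) {
    s <- idx[, h]
    tot <- 0
    for (a in 1:61) for (b in 1:61) {
      term <- pi[a]
      for (e in seq_len(nrow(trp$edge))) {
        par <- trp$edge[e, 1]; ch <- trp$edge[e, 2]
        from <- if (par == root) a else b
        to <- if (ch <= n_tip) s[ch] else b
        if (is.na(to)) next  # gap: marginalize by skipping the factor
        term <- term * P[[e]][from, to]
      }
      tot <- tot + term
    }
    total <- total + log(tot)
  }
  total
}

# Independent Nei-Gojobori difference-count oracle: depth-first walk over
# codon states enumerating every complete mutational path, then averaging
# synonymous/nonsynonymous step counts over stop-free paths (over all paths
# iff every path passes a stop).
oracle_ng_diff <- function(a, b) {
  gc_tab <- Biostrings::GENETIC_CODE
  paths <- list()
  walk <- function(cur, sd, nd, blocked) {
    if (cur == b) {
      paths[[length(paths) + 1]] <<- c(sd, nd, as.numeric(blocked))
      return(invisible())
    }
    cur_ch <- strsplit(cur, "")[[1]]; tgt_ch <- strsplit(b, "")[[1]]
    for (pos in which(cur_ch != tgt_ch)) {
      nxt_ch <- cur_ch; nxt_ch[pos] <- tgt_ch[pos]
      nxt <- paste(nxt_ch, collapse = "")
      syn <- identical(unname(gc_tab[cur]), unname(gc_tab[nxt]))
      walk(nxt, sd + syn, nd + !syn,
           blocked || (unname(gc_tab[nxt]) == "*" && nxt != b))
    }
  }
  walk(a, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}
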