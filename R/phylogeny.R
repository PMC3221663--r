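## Protein distance matrices (JTT maximum-likelihood or Kimura-corrected),
## neighbor-joining with non-negative branch lengths, and column-resampling
## bootstrap with majority-rule consensus.

#' Pairwise protein distance matrix
#'
#' `"JTT-ML"` maximizes, independently for each pair, the likelihood of the
#' divergence time under the JTT replacement matrix (via
#' [phangorn::dist.ml()]; ambiguous and gap characters act as missing data,
#' equivalent to pairwise deletion). `"Kimura"` applies the Kimura correction
#' `d = -ln(1 - p - 0.2 p^2)` to the observed proportion of differences with
#' pairwise deletion of gap columns.
#'
#' @param aa_alignment Character matrix of aligned residues (rows named).
#' @param model `"JTT-ML"` or `"Kimura"`.
#' @return Symmetric matrix of distances (substitutions per site), zero
#'   diagonal.
#' @export
protein_distance_matrix <- function(aa_alignment, model = c("JTT-ML", "Kimura")) {
  model <- match.arg(model)
  labs <- rownames(aa_alignment)
  n <- nrow(aa_alignment)
  if (n < 2) stop("need >= 2 sequences")
  if (model == "JTT-ML") {
    pd <- phangorn::phyDat(aa_alignment, type = "AA")
    D <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
    return(D[labs, labs])
  }
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- aa_alignment[i, ]; b <- aa_alignment[j, ]
    keep <- a != "-" & b != "-" & a != "X" & b != "X"
    if (!any(keep)) stop("no shared ungapped columns for pair ",
                         labs[i], " / ", labs[j])
    p <- mean(a[keep] != b[keep])
    arg <- 1 - p - 0.2 * p^2
    D[i, j] <- D[j, i] <- if (arg > 0) -log(arg) else NA_real_
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]). Negative branch-length
#' estimates are clamped to zero with the deficit shifted to the adjacent
#' branch toward the tree interior, preserving path lengths between leaves as
#' closely as possible.
#'
#' @param D Symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return An unrooted `ape::phylo` with non-negative branch lengths.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D)) || any(!is.finite(D))) stop("distance matrix has NA/NaN entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric")
  if (nrow(D) < 3) stop("need >= 3 taxa")
  tr <- ape::nj(as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    ## shift the deficit onto the edge above the parent (toward the interior)
    up <- which(tr$edge[, 2] == parent)
    if (length(up) == 1) tr$edge.length[up] <- tr$edge.length[up] + deficit
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a distance matrix in PHYLIP lower-triangle format
#'
#' @param D Symmetric distance matrix with row names.
#' @param path Output path.
#' @export
write_phylip_dist <- function(D, path) {
  D <- as.matrix(D)
  labs <- rownames(D)
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("%5d\n", nrow(D)), file = con)
  for (i in seq_len(nrow(D))) {
    row <- if (i > 1) paste(sprintf("%.6f", D[i, seq_len(i - 1)]), collapse = "  ")
           else ""
    cat(sprintf("%-10s%s\n", substr(labs[i], 1, 10), row), file = con)
  }
  invisible(path)
}

#' Bootstrap majority-rule consensus tree from a protein alignment
#'
#' Resamples alignment columns with replacement, rebuilds a distance + NJ tree
#' per replicate, and returns the majority-rule (> 50%) consensus with
#' bipartition support percentages as node labels.
#'
#' @param aa_alignment Character matrix of aligned residues.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Random seed (required; no hidden state).
#' @param model Distance model, see [protein_distance_matrix()].
#' @return An `ape::phylo` consensus tree; `node.label` holds support (%).
#' @export
bootstrap_consensus <- function(aa_alignment, n_reps = 100, seed, model = "JTT-ML") {
  if (missing(seed)) stop("seed is required")
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  nc <- ncol(aa_alignment)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    D <- protein_distance_matrix(aa_alignment[, cols, drop = FALSE], model = model)
    trees[[r]] <- neighbor_joining(D)
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- round(100 * counts / n_reps, 1)
  cons
}
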