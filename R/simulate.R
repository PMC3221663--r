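## Forward simulation of codon alignments under the site-class model, random
## subgroup-shaped trees, and complete synthetic input bundles (protein FASTA,
## CDS FASTA, position map, subgroup table) with known ground truth.

#' Random subgroup-shaped tree
#'
#' Random topology (via [ape::rtree()]) with independent gamma-distributed
#' edge lengths (shape 2, so terminal branches are substantial, as in paralog
#' families that diverged anciently), rescaled to a target maximum tip-to-tip
#' path length in expected substitutions per codon. The default depth keeps
#' pairwise synonymous divergence inside the admission envelope (dS roughly
#' 0.5-2).
#'
#' @param n_taxa Number of tips (3-10 for subgroup emulation).
#' @param depth Target maximum pairwise path length (substitutions/codon).
#' @param seed Random seed (required).
#' @return An `ape::phylo` with labels `seq1..seqN`.
#' @export
random_subgroup_tree <- function(n_taxa, depth = 1.2, seed,
                                 edges = c("gamma", "equal")) {
  if (missing(seed)) stop("seed is required")
  edges <- match.arg(edges)
  set.seed(seed)
  tr <- ape::rtree(n_taxa, tip.label = paste0("seq", seq_len(n_taxa)))
  tr$edge.length <- if (edges == "gamma")
    stats::rgamma(nrow(tr$edge), shape = 2, rate = 2) else rep(1, nrow(tr$edge))
  d <- max(ape::cophenetic.phylo(tr))
  tr$edge.length <- tr$edge.length * depth / d
  ape::unroot(tr)
}

#' Simulate a codon alignment along a tree under a site-class model
#'
#' Per column, a site class is drawn with probability `props` (or taken from
#' `site_omega`), the root codon is drawn from the equilibrium distribution,
#' and states evolve down the tree through the class transition probabilities.
#' All class rate matrices share `kappa` and `pi` and the common scaling, so
#' branch lengths are expected substitutions per codon averaged over classes.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param n_codons Number of codon columns.
#' @param kappa Transition/transversion ratio.
#' @param pi Equilibrium codon frequencies (61-vector; default equal).
#' @param props,omegas Site-class mixture (ignored if `site_omega` given).
#' @param site_omega Optional explicit per-column omega vector (length
#'   `n_codons`), for planted designs.
#' @param seed Optional seed (set it for reproducibility).
#' @return A `codon_alignment` with attributes `site_class` (true class index
#'   per column), `site_omega` (true omega per column), and `tree`.
#' @export
simulate_codon_alignment <- function(tree, n_codons = 190, kappa = 2,
                                     pi = rep(1 / 61, 61), props = 1, omegas = 0.2,
                                     site_omega = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (abs(sum(props) - 1) > 1e-8) stop("class proportions must sum to 1")
  tabs <- codon_tables()
  if (!is.null(site_omega)) {
    stopifnot(length(site_omega) == n_codons)
    omegas <- sort(unique(site_omega))
    cls <- match(site_omega, omegas)
    props <- tabulate(cls, length(omegas)) / n_codons
  } else {
    cls <- sample.int(length(omegas), n_codons, replace = TRUE, prob = props)
  }
  ## common scale over classes
  Qs <- lapply(omegas, function(w) build_rate_matrix(kappa, w, pi, scale = FALSE))
  mu <- sum(props * vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1)))
  Qs <- lapply(Qs, function(Q) { Q2 <- Q / mu; attr(Q2, "pi") <- pi; Q2 })

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  edges_pre <- rev(seq_len(nrow(tr$edge)))  # preorder: root-to-tip
  root <- tr$edge[nrow(tr$edge), 1]
  n_nodes <- n_tip + tr$Nnode

  states <- matrix(0L, n_nodes, n_codons)
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  ## per-class transition matrices per edge
  for (e in edges_pre) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t_e <- tr$edge.length[e]
    for (k in seq_along(omegas)) {
      idx <- which(cls == k)
      if (!length(idx)) next
      if (t_e == 0) { states[child, idx] <- states[parent, idx]; next }
      P <- transition_probabilities(Qs[[k]], t_e)
      ps <- states[parent, idx]
      for (s0 in unique(ps)) {
        at <- idx[ps == s0]
        states[child, at] <- sample.int(61, length(at), replace = TRUE,
                                        prob = P[s0, ])
      }
    }
  }
  codons <- matrix(tabs$codons[states[seq_len(n_tip), , drop = FALSE]],
                   nrow = n_tip, dimnames = list(tr$tip.label, NULL))
  aln <- structure(list(codons = codons, labels = tr$tip.label,
                        column_count = n_codons),
                   class = "codon_alignment")
  attr(aln, "site_class") <- cls
  attr(aln, "site_omega") <- omegas[cls]
  attr(aln, "tree") <- tree
  aln
}

#' Generate a complete synthetic subgroup input bundle
#'
#' Emits the files a real analysis would consume -- aligned protein FASTA,
#' unaligned CDS FASTA, a position map TSV flagging 10 key columns, and a
#' subgroup membership TSV -- for a subgroup of paralogs simulated with known
#' per-column selection regimes:
#' \describe{
#'   \item{strong-negative}{key columns at omega 0.02; background mixture of
#'     omega 0.05 (55%), 0.3 (35%) and 0.9 (10%) -- the small-molecule
#'     receptor pattern (strong negative, moderate, near-neutral classes).}
#'   \item{mixed}{key columns share the background mixture -- no distinct
#'     pressure at key positions.}
#'   \item{positive-at-key}{one key column planted at omega 6.3 plus two
#'     non-key columns at omega 4, over a constrained background (omega 0.05
#'     at 60%, 0.2 at 40%; remaining key columns 0.02) on a shallower,
#'     balanced tree -- the MRGX1-like pattern with the key position carrying
#'     the strongest positive signal.}
#' }
#' Emitted bundles are guaranteed to satisfy the admission filter
#' (max pairwise dN < 1, max dS < 3), resampling up to `max_tries` seeds
#' derived from `seed` if a draw violates it.
#'
#' @param dir Output directory (created if needed).
#' @param category Ligand category recorded in the subgroup table.
#' @param regime `"strong-negative"`, `"mixed"`, or `"positive-at-key"`.
#' @param n_taxa Number of paralogs (3-10).
#' @param n_codons Aligned codon columns (default 190).
#' @param seed Random seed (required; same seed, byte-identical files).
#' @param subgroup_id Identifier recorded in the subgroup table.
#' @param max_tries Resampling attempts to satisfy admission.
#' @return List of file `paths` plus the ground truth: `site_omega`,
#'   `key_columns`, `planted_key_column` (positive regime), `tree`,
#'   `alignment`.
#' @export
make_subgroup_fixture <- function(dir, category = "small",
                                  regime = c("strong-negative", "mixed", "positive-at-key"),
                                  n_taxa = 4, n_codons = 190, seed,
                                  subgroup_id = 1, max_tries = 20) {
  regime <- match.arg(regime)
  if (missing(seed)) stop("seed is required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- round(seq(0.3, 0.95, length.out = 10) * n_codons)

  draw <- function(s) {
    set.seed(s)
    planted <- NA_integer_
    if (regime == "positive-at-key") {
      site_omega <- sample(c(0.05, 0.2), n_codons, replace = TRUE,
                           prob = c(0.6, 0.4))
      site_omega[keys] <- 0.02
      planted <- keys[3]
      site_omega[planted] <- 6.3
      nonkey <- setdiff(seq_len(n_codons), keys)
      site_omega[sample(nonkey, 2)] <- 4
      tree <- random_subgroup_tree(n_taxa, depth = 0.8, seed = s + 1,
                                   edges = "equal")
    } else {
      site_omega <- sample(c(0.05, 0.3, 0.9), n_codons, replace = TRUE,
                           prob = c(0.55, 0.35, 0.10))
      if (regime == "strong-negative") site_omega[keys] <- 0.02
      tree <- random_subgroup_tree(n_taxa, depth = 1.2, seed = s + 1)
    }
    aln <- simulate_codon_alignment(tree, n_codons, kappa = 2,
                                    site_omega = site_omega, seed = s + 2)
    list(aln = aln, tree = tree, site_omega = site_omega, planted = planted)
  }

  sim <- NULL
  for (try in seq_len(max_tries)) {
    cand <- draw(seed + 1000 * (try - 1))
    adm <- subgroup_admission(pairwise_rate_table(cand$aln))
    if (adm$pass && !("S" %in% adm$flags)) { sim <- cand; break }
  }
  if (is.null(sim)) stop("could not draw an admissible subgroup in ",
                         max_tries, " tries")

  aa <- translate_alignment(sim$aln)
  prot <- apply(aa, 1, paste, collapse = "")
  cds <- apply(sim$aln$codons, 1, function(r) paste(r[r != "---"], collapse = ""))
  paths <- list(
    protein = file.path(dir, "protein.fasta"),
    cds = file.path(dir, "cds.fasta"),
    position_map = file.path(dir, "position_map.tsv"),
    subgroups = file.path(dir, "subgroups.tsv"),
    tree = file.path(dir, "tree.nwk"))
  write_fasta(prot, paths$protein)
  write_fasta(cds, paths$cds)
  pm <- data.frame(column_index = seq_len(n_codons),
                   bw_index = ifelse(seq_len(n_codons) %in% keys,
                                     paste0("k.", match(seq_len(n_codons), keys)), ""),
                   is_key = as.integer(seq_len(n_codons) %in% keys))
  utils::write.table(pm, paths$position_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sg <- data.frame(subgroup_id = subgroup_id, label = sim$aln$labels,
                   ligand = "synthetic", class = category, orphan = 0,
                   flags = "", included = 1)
  utils::write.table(sg, paths$subgroups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(sim$tree, paths$tree)
  list(paths = paths, site_omega = sim$site_omega, key_columns = keys,
       planted_key_column = sim$planted, tree = sim$tree, alignment = sim$aln,
       regime = regime, seed = seed)
}
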