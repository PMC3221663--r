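## Nei-Gojobori counting of synonymous/nonsynonymous sites and differences,
## Jukes-Cantor correction, pairwise dN/dS tables and the subgroup admission
## filter (max pairwise dN < 1, flag when max dS >= 3).

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' Each of the three positions contributes one site, split into a synonymous
#' fraction (number of the three single-nucleotide changes at that position
#' that preserve the amino acid, over 3) and a nonsynonymous remainder, so
#' s + n = 3 exactly. Changes to stop codons are counted as nonsynonymous by
#' default; with `stop_handling = "exclude"` the position's site is split over
#' its non-stop alternatives only.
#'
#' @param codon A sense codon string, e.g. `"TTT"`.
#' @param stop_handling `"nonsynonymous"` (default) or `"exclude"`.
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n == 3`.
#' @export
ng_site_counts <- function(codon, stop_handling = c("nonsynonymous", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  tabs <- codon_tables()
  i <- match(codon, tabs$codons)
  if (is.na(i)) stop("not a sense codon: ", codon)
  s <- 0
  nts <- c("T", "C", "A", "G")
  chars <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    alt <- nts[nts != chars[p]]
    mut <- vapply(alt, function(a) {
      x <- chars; x[p] <- a; paste(x, collapse = "")
    }, character(1))
    aa_mut <- translate_codons(mut)
    is_stop <- mut %in% tabs$stop_codons
    n_syn <- sum(!is_stop & aa_mut == tabs$aa[i])
    denom <- if (stop_handling == "exclude") sum(!is_stop) else 3L
    if (denom > 0) s <- s + n_syn / denom
  }
  c(s = s, n = 3 - s)
}

## Pathway-averaged synonymous/nonsynonymous difference counts between two
## sense codons: average over the k! orderings of the k differing positions,
## excluding pathways passing through stop codons (unless all are blocked, in
## which case all pathways are used with stop steps counted by amino-acid
## identity). Returns c(sd, nd).
ng_diff_counts_one <- function(a, b, exclude_stop_paths = TRUE) {
  tabs <- codon_tables()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  d <- which(ca != cb)
  k <- length(d)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(1L), list(1:2, 2:1),
                  { p <- expand.grid(1:3, 1:3, 1:3)
                    p <- p[apply(p, 1, function(r) length(unique(r)) == 3), ]
                    lapply(seq_len(nrow(p)), function(r) as.integer(p[r, ])) })
  score_path <- function(ord) {
    cur <- ca; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in d[ord]) {
      nxt <- cur; nxt[pos] <- cb[pos]
      cod_cur <- paste(cur, collapse = ""); cod_nxt <- paste(nxt, collapse = "")
      if (cod_nxt %in% tabs$stop_codons && !identical(cod_nxt, b)) blocked <- TRUE
      aa_cur <- unname(tabs$genetic_code[cod_cur])
      aa_nxt <- unname(tabs$genetic_code[cod_nxt])
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(perms, score_path)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (exclude_stop_paths && any(ok)) res <- res[ok]
  sd <- mean(vapply(res, `[[`, numeric(1), "sd"))
  nd <- mean(vapply(res, `[[`, numeric(1), "nd"))
  c(sd = sd, nd = nd)
}

## Memoised 61x61 tables of pathway-averaged difference counts and per-codon
## site counts.
ng_tables <- function(stop_handling = "nonsynonymous") {
  key <- paste0("ng_", stop_handling)
  if (!is.null(.siteomega[[key]])) return(.siteomega[[key]])
  tabs <- codon_tables()
  n <- length(tabs$codons)
  sites <- t(vapply(tabs$codons, ng_site_counts, numeric(2),
                    stop_handling = stop_handling))
  sd <- matrix(0, n, n); nd <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      cnt <- ng_diff_counts_one(tabs$codons[i], tabs$codons[j])
      sd[i, j] <- sd[j, i] <- cnt["sd"]
      nd[i, j] <- nd[j, i] <- cnt["nd"]
    }
  }
  .siteomega[[key]] <- list(sites = sites, sd = sd, nd = nd)
  .siteomega[[key]]
}

#' Jukes-Cantor distance from a proportion of differing sites
#' @param p Proportion in `[0, 3/4)`; larger values give `NA` (saturated).
#' @return `-(3/4) * log(1 - (4/3) p)`; `NA_real_` when `p >= 3/4`.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
}

#' Nei-Gojobori pairwise dN and dS for two codon sequences
#'
#' Codon columns with a gap in either sequence are removed (complete pairwise
#' deletion). Site totals are averaged over the two sequences; difference
#' counts for codon pairs differing at more than one position are averaged
#' over all mutational pathways, excluding pathways through stop codons.
#' Proportions are Jukes-Cantor corrected; a proportion at or beyond 3/4 gives
#' an `NA` distance with a saturation flag.
#'
#' @param seq_a,seq_b Character vectors of codons (gaps `"---"` allowed).
#' @param stop_handling Stop-codon convention for site counting, see
#'   [ng_site_counts()].
#' @return List with `dN`, `dS`, `pN`, `pS`, site totals `N`, `S`, difference
#'   totals `Nd`, `Sd`, compared codon count `L`, and flags
#'   `saturated_dN`, `saturated_dS`.
#' @export
ng_pairwise <- function(seq_a, seq_b, stop_handling = "nonsynonymous") {
  if (length(seq_a) != length(seq_b))
    stop("length mismatch: ", length(seq_a), " vs ", length(seq_b))
  keep <- seq_a != "---" & seq_b != "---"
  if (!any(keep)) stop("all codon columns gapped in one of the sequences")
  a <- codon_index(seq_a[keep]); b <- codon_index(seq_b[keep])
  if (anyNA(a) || anyNA(b)) stop("invalid codon in input")
  tab <- ng_tables(stop_handling)
  S <- (sum(tab$sites[a, "s"]) + sum(tab$sites[b, "s"])) / 2
  N <- (sum(tab$sites[a, "n"]) + sum(tab$sites[b, "n"])) / 2
  Sd <- sum(tab$sd[cbind(a, b)])
  Nd <- sum(tab$nd[cbind(a, b)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- if (is.na(pS)) NA_real_ else jukes_cantor(pS)
  dN <- if (is.na(pN)) NA_real_ else jukes_cantor(pN)
  list(dN = dN, dS = dS, pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd,
       L = sum(keep),
       saturated_dN = isTRUE(!is.na(pN) && pN >= 0.75),
       saturated_dS = isTRUE(!is.na(pS) && pS >= 0.75))
}

#' Pairwise dN/dS rate table over a codon alignment
#'
#' @param alignment A `codon_alignment`.
#' @param stop_handling See [ng_site_counts()].
#' @return A `pairwise_rate_table`: list with symmetric matrices `dN`, `dS`
#'   (zero diagonal), logical flag matrices `saturated_dN`, `saturated_dS`,
#'   and `labels`.
#' @export
pairwise_rate_table <- function(alignment, stop_handling = "nonsynonymous") {
  stopifnot(inherits(alignment, "codon_alignment"))
  labs <- alignment$labels
  n <- length(labs)
  dN <- dS <- matrix(0, n, n, dimnames = list(labs, labs))
  satN <- satS <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- ng_pairwise(alignment$codons[i, ], alignment$codons[j, ],
                     stop_handling = stop_handling)
    dN[i, j] <- dN[j, i] <- r$dN
    dS[i, j] <- dS[j, i] <- r$dS
    satN[i, j] <- satN[j, i] <- r$saturated_dN
    satS[i, j] <- satS[j, i] <- r$saturated_dS
  }
  structure(list(labels = labs, dN = dN, dS = dS,
                 saturated_dN = satN, saturated_dS = satS),
            class = "pairwise_rate_table")
}

#' @export
print.pairwise_rate_table <- function(x, ...) {
  off <- upper.tri(x$dN)
  cat("pairwise_rate_table over", length(x$labels), "sequences\n")
  cat(sprintf("  max dN = %.3f; max dS = %.3f; saturated pairs: %d\n",
              suppressWarnings(max(x$dN[off], na.rm = TRUE)),
              suppressWarnings(max(x$dS[off], na.rm = TRUE)),
              sum(x$saturated_dN[off] | x$saturated_dS[off])))
  invisible(x)
}

#' Subgroup admission filter on pairwise dN/dS
#'
#' A subgroup is admitted when the maximum pairwise dN over its members is
#' below `dn_max` (default 1). If not, the member with the largest mean dN to
#' all others is removed iteratively (ties broken by label order) until the
#' condition holds or fewer than three members remain; an irreducible subgroup
#' is flagged `"N"`. Subgroups whose maximum pairwise dS reaches `ds_max`
#' (default 3) are retained but flagged `"S"`. Saturated (undefined) distances
#' count as exceeding the bound.
#'
#' @param table A `pairwise_rate_table`.
#' @param dn_max,ds_max Admission bounds on the pairwise dN and dS statistic.
#' @param statistic `"max"` (default) applies the bounds to the maximum over
#'   pairs; `"mean"` to the mean over pairs.
#' @return List with `pass`, `flags` (subset of `"N"`, `"S"`), `members`
#'   (retained labels), `removed`, `max_dN`, `max_dS` (over retained members),
#'   and `offending_pairs` (label pairs violating the dN bound in the input).
#' @export
subgroup_admission <- function(table, dn_max = 1, ds_max = 3,
                               statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  stat <- function(m) {
    v <- m[upper.tri(m)]
    if (statistic == "max") max(v) else mean(v)
  }
  stopifnot(inherits(table, "pairwise_rate_table"))
  if (length(table$labels) < 3) stop("admission needs >= 3 members")
  eff <- function(m, sat) { m[sat] <- Inf; m[is.na(m)] <- Inf; m }
  dN <- eff(table$dN, table$saturated_dN)
  dS <- eff(table$dS, table$saturated_dS)
  diag(dN) <- diag(dS) <- 0
  keep <- table$labels
  off <- which(dN[keep, keep] >= dn_max & upper.tri(dN[keep, keep]), arr.ind = TRUE)
  offending <- if (nrow(off)) data.frame(a = keep[off[, 1]], b = keep[off[, 2]],
                                         dN = table$dN[cbind(off[, 1], off[, 2])])
               else data.frame(a = character(), b = character(), dN = numeric())
  removed <- character()
  flags <- character()
  repeat {
    sub <- dN[keep, keep, drop = FALSE]
    if (stat(sub) < dn_max) break
    if (length(keep) <= 3) { flags <- union(flags, "N"); break }
    mean_dn <- rowMeans(sub)
    worst <- keep[which.max(mean_dn)]  # which.max breaks ties by order
    keep <- setdiff(keep, worst)
    removed <- c(removed, worst)
  }
  max_dn <- stat(dN[keep, keep])
  max_ds <- stat(dS[keep, keep])
  if (max_ds >= ds_max) flags <- union(flags, "S")
  pass <- max_dn < dn_max
  list(pass = pass, flags = flags, members = keep, removed = removed,
       max_dN = max_dn, max_dS = max_ds, offending_pairs = offending)
}
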