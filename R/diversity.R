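## Alignment-column amino-acid diversity: Shannon entropy (bits),
## Karlin-Brocchieri normalized BLOSUM80 similarity, JTT-ML distance over the
## key-position mini-alignment, and regressions of diversity on selection.

#' Shannon entropy of an alignment column
#'
#' Plug-in entropy of the empirical residue frequencies, in bits. Gaps are
#' excluded from the frequencies by default; with `count_gaps = TRUE` the gap
#' is a 21st symbol.
#'
#' @param column Character vector of residues (one per sequence).
#' @param count_gaps Count `-` as a symbol?
#' @return Entropy in bits; `NA` (with a warning) for an all-gap column.
#' @export
shannon_entropy <- function(column, count_gaps = FALSE) {
  x <- column
  if (!count_gaps) x <- x[x != "-"]
  if (length(x) == 0) {
    warning("all-gap column: entropy undefined")
    return(NA_real_)
  }
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

## BLOSUM80 from Biostrings, loaded once.
blosum80 <- function() {
  if (is.null(.siteomega$blosum80)) {
    e <- new.env()
    utils::data("BLOSUM80", package = "Biostrings", envir = e)
    .siteomega$blosum80 <- e$BLOSUM80
  }
  .siteomega$blosum80
}

#' Karlin-Brocchieri column similarity under a substitution matrix
#'
#' For each unordered pair of sequences (r, s) with residues (x, y) at the
#' column, the normalized score is
#' `M(x, y) = m(x, y) / sqrt(m(x, x) m(y, y))`; the column similarity is the
#' average of `M` over all pairs. Gap residues are excluded pairwise.
#'
#' @param column Character vector of residues.
#' @param substitution_table Square scoring matrix (default BLOSUM80 as
#'   shipped with Biostrings).
#' @return Column similarity score (1 for an invariant column).
#' @export
karlin_similarity <- function(column, substitution_table = blosum80()) {
  x <- column[column != "-"]
  if (length(x) < 2) stop("need >= 2 non-gap residues")
  bad <- setdiff(unique(x), rownames(substitution_table))
  if (length(bad)) stop("residue absent from substitution table: ",
                        paste(bad, collapse = ", "))
  n <- length(x)
  tot <- 0; np <- 0
  for (r in seq_len(n - 1)) for (s in (r + 1):n) {
    m_xy <- substitution_table[x[r], x[s]]
    tot <- tot + m_xy / sqrt(substitution_table[x[r], x[r]] *
                               substitution_table[x[s], x[s]])
    np <- np + 1
  }
  tot / np
}

#' JTT distance over the key-position mini-alignment
#'
#' Builds the alignment restricted to the key columns (concatenated, the
#' default) and computes JTT maximum-likelihood pairwise distances; `D_key` is
#' their mean over pairs. With `mode = "per-column"` distances are computed
#' per key column and averaged. `-log10(D_key)` is reported alongside
#' (infinite when the key residues are identical across the subgroup).
#'
#' @param aa_alignment Character residue matrix (rows named).
#' @param key_columns Integer vector of key columns.
#' @param mode `"concatenated"` or `"per-column"`.
#' @return List with `D_key`, `neg_log10_D_key`, and `identical` (flag).
#' @export
column_distance <- function(aa_alignment, key_columns,
                            mode = c("concatenated", "per-column")) {
  mode <- match.arg(mode)
  if (nrow(aa_alignment) < 2) stop("need >= 2 sequences")
  if (length(key_columns) == 0) stop("empty key column set")
  mini <- aa_alignment[, key_columns, drop = FALSE]
  ident <- all(apply(mini, 2, function(cl) {
    r <- cl[cl != "-"]; length(unique(r)) <= 1
  }))
  if (ident) return(list(D_key = 0, neg_log10_D_key = Inf, identical = TRUE))
  mean_pairs <- function(m) {
    D <- protein_distance_matrix(m, model = "JTT-ML")
    mean(D[upper.tri(D)])
  }
  D_key <- if (mode == "concatenated") mean_pairs(mini) else {
    ## per-column distances need variation within the column to be meaningful;
    ## invariant columns contribute 0
    mean(vapply(seq_along(key_columns), function(j)
      tryCatch(mean_pairs(mini[, j, drop = FALSE]), error = function(e) 0),
      numeric(1)))
  }
  list(D_key = D_key,
       neg_log10_D_key = if (D_key > 0) -log10(D_key) else Inf,
       identical = FALSE)
}

#' Key-position diversity summary for one subgroup alignment
#'
#' @param aa_alignment Character residue matrix.
#' @param key_columns Integer vector of key columns.
#' @return List with per-key-column `entropy` and `blosum80` vectors, their
#'   averages `H_key`, `BLO80_key`, and the distance pair `D_key`,
#'   `neg_log10_D_key`.
#' @export
diversity_profile <- function(aa_alignment, key_columns) {
  H <- vapply(key_columns, function(j) shannon_entropy(aa_alignment[, j]),
              numeric(1))
  C <- vapply(key_columns, function(j) karlin_similarity(aa_alignment[, j]),
              numeric(1))
  d <- column_distance(aa_alignment, key_columns)
  list(entropy = H, blosum80 = C,
       H_key = mean(H, na.rm = TRUE), BLO80_key = mean(C),
       D_key = d$D_key, neg_log10_D_key = d$neg_log10_D_key)
}

#' Regress a diversity measure on the key-position selection pressure
#'
#' Ordinary least squares of the diversity measure on `log10(omega_key)`,
#' with a second fit restricted to subgroups with `omega_key < 0.1`.
#' Subgroups failing the admission filter (flag `"N"`) should be excluded by
#' the caller via `keep`.
#'
#' @param diversity Numeric per-subgroup diversity values (e.g. mean key
#'   entropy).
#' @param omega_key Numeric per-subgroup key-position mean omega (> 0).
#' @param keep Logical vector of subgroups to retain (default all).
#' @return List with `full` and `restricted` summaries (`R`, `r_squared`,
#'   `p_value`, `slope`, `n`).
#' @export
diversity_vs_selection <- function(diversity, omega_key, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(diversity))
  ok <- keep & is.finite(diversity) & is.finite(omega_key) & omega_key > 0
  d <- data.frame(y = diversity[ok], x = log10(omega_key[ok]))
  if (nrow(d) < 3) stop("fewer than 3 points after filtering")
  fit1 <- function(dd) {
    m <- stats::lm(y ~ x, data = dd); s <- summary(m)
    r <- sqrt(s$r.squared) * sign(stats::coef(m)[2])
    list(R = unname(r), r_squared = s$r.squared,
         p_value = unname(s$coefficients[2, 4]),
         slope = unname(stats::coef(m)[2]), n = nrow(dd))
  }
  res <- d[d$x < log10(0.1), , drop = FALSE]
  list(full = fit1(d),
       restricted = if (nrow(res) >= 3) fit1(res) else NULL)
}
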