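## Goldman-Yang style 61-state codon rate matrix, equilibrium codon frequency
## estimators, matrix exponentials via reversible-model symmetrization, and
## equal-probability beta discretization for M7/M8.

#' Estimate equilibrium codon frequencies from a codon alignment
#'
#' @param alignment A `codon_alignment` (or codon character matrix).
#' @param scheme `"F3x4"` (position-specific nucleotide frequencies, the
#'   default), `"F1x4"` (overall nucleotide frequencies), `"F61"` (empirical
#'   codon frequencies with a pseudocount), or `"equal"`.
#' @return Numeric 61-vector summing to 1, named by sense codon.
#' @export
codon_frequencies <- function(alignment, scheme = c("F3x4", "F1x4", "F61", "equal")) {
  scheme <- match.arg(scheme)
  tabs <- codon_tables()
  m <- if (inherits(alignment, "codon_alignment")) alignment$codons else alignment
  cods <- as.vector(m); cods <- cods[cods != "---"]
  idx <- codon_index(cods); idx <- idx[!is.na(idx)]
  pi61 <- switch(scheme,
    equal = rep(1 / 61, 61),
    F61 = {
      cnt <- tabulate(idx, 61) + 0.5
      cnt / sum(cnt)
    },
    F1x4 = {
      nt_cnt <- tabulate(as.vector(tabs$nt[idx, ]), 4) + 0.5
      f <- nt_cnt / sum(nt_cnt)
      p <- f[tabs$nt[, 1]] * f[tabs$nt[, 2]] * f[tabs$nt[, 3]]
      p / sum(p)
    },
    F3x4 = {
      f <- sapply(1:3, function(p) {
        cnt <- tabulate(tabs$nt[idx, p], 4) + 0.5
        cnt / sum(cnt)
      })
      p <- f[tabs$nt[, 1], 1] * f[tabs$nt[, 2], 2] * f[tabs$nt[, 3], 3]
      p / sum(p)
    })
  names(pi61) <- tabs$codons
  pi61
}

#' Build the codon substitution rate matrix Q
#'
#' Off-diagonal rates are zero for codon pairs differing at more than one
#' nucleotide; otherwise `pi_j` times 1, `kappa`, `omega`, or `omega * kappa`
#' for synonymous transversions, synonymous transitions, nonsynonymous
#' transversions, and nonsynonymous transitions. Rows sum to zero. By default
#' the matrix is scaled so the expected number of substitutions per codon per
#' unit time at equilibrium is 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @param codon_frequencies Numeric 61-vector of equilibrium frequencies.
#' @param scale Scale to one expected substitution per codon per unit time?
#' @return 61 x 61 generator matrix with the stationary distribution attached
#'   as attribute `"pi"`.
#' @export
build_rate_matrix <- function(kappa, omega, codon_frequencies, scale = TRUE) {
  if (kappa <= 0 || omega <= 0) stop("kappa and omega must be > 0")
  tabs <- codon_tables()
  pi61 <- codon_frequencies / sum(codon_frequencies)
  Q <- matrix(0, 61, 61, dimnames = list(tabs$codons, tabs$codons))
  p <- tabs$pairs
  rate <- ifelse(p$transition, kappa, 1) * ifelse(p$synonymous, 1, omega)
  Q[cbind(p$i, p$j)] <- rate * pi61[p$j]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi61 * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  attr(Q, "pi") <- pi61
  Q
}

#' Transition probability matrix exp(Q t)
#'
#' Computed by symmetrizing the reversible generator with the stationary
#' distribution and eigendecomposing; tiny negative entries (>-1e-12) from
#' round-off are clamped to zero and rows renormalized.
#'
#' @param Q Generator from [build_rate_matrix()] (carries `attr(, "pi")`).
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length must be >= 0")
  pi61 <- attr(Q, "pi")
  if (is.null(pi61)) stop("Q must carry its stationary distribution as attr 'pi'")
  if (t == 0) return(diag(61))
  sq <- sqrt(pi61)
  B <- Q * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- outer(1 / sq, sq) * (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  if (min(P) < -1e-12) stop("matrix exponential produced negative entries")
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Equal-probability discretization of a beta distribution of omega
#'
#' Splits Beta(p, q) into `K` equal-probability categories; each category's
#' omega is the conditional mean of the density over its quantile bin,
#' computed from incomplete-beta differences (exact, no numerical
#' integration).
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of categories (default 10).
#' @return data.frame with `proportion` (each `1/K`) and `omega` (increasing,
#'   all in (0, 1)).
#' @export
discretize_beta <- function(p, q, K = 10) {
  if (p <= 0 || q <= 0) stop("beta parameters must be > 0")
  br <- stats::qbeta((0:K) / K, p, q)
  ## conditional mean over (br[i], br[i+1]]: mean * (I_{p+1,q}(hi)-I_{p+1,q}(lo)) * K
  mass_upper <- stats::pbeta(br, p + 1, q)
  omega <- (p / (p + q)) * diff(mass_upper) * K
  omega <- pmin(pmax(omega, 1e-12), 1 - 1e-12)
  data.frame(proportion = rep(1 / K, K), omega = omega)
}
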