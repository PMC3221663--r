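ctrl_fast <- list(rel.tol = 1e-8)

test_that("M0 recovers the generating omega on a small simulation", {
  tr <- random_subgroup_tree(6, depth = 1.0, seed = 41)
  aln <- simulate_codon_alignment(tr, n_codons = 300, kappa = 2, omegas = 0.25,
                                  seed = 42)
  fit <- fit_site_model(aln, tr, "M0", restarts = 0, control = ctrl_fast)
  expect_lt(abs(fit$mle$omegas[1] - 0.25), 0.07)
  expect_lt(abs(fit$mle$kappa - 2), 0.7)
  expect_true(is.finite(fit$lnL))
  # single-class model: posterior is degenerate, NEB profile constant
  expect_equal(unique(fit$neb_omega), fit$mle$omegas[1])
  expect_equal(fitted(fit), fit$neb_omega)
})

test_that("nested models never lose likelihood and posteriors normalize", {
  fx <- make_subgroup_fixture(tempfile(), regime = "mixed", n_taxa = 4,
                              n_codons = 120, seed = 51)
  aln <- fx$alignment; tr <- fx$tree
  res <- site_model_tests(aln, tr, tests = c(1, 2, 4), restarts = 0,
                          seed = 5, control = ctrl_fast)
  expect_gte(res$fits$M2a$lnL, res$fits$M1a$lnL - 1e-6)
  expect_gte(res$fits$M8$lnL, res$fits$M7$lnL - 1e-6)
  expect_gte(res$fits$M3$lnL, res$fits$M0$lnL - 1e-6)
  for (f in res$fits) {
    if (!inherits(f, "site_model_fit")) next
    expect_equal(rowSums(f$posteriors), rep(1, f$n_col), tolerance = 1e-8)
    expect_true(all(f$neb_omega >= min(f$mle$omegas) - 1e-10))
    expect_true(all(f$neb_omega <= max(f$mle$omegas) + 1e-10))
    expect_equal(abs(sum(f$mle$props) - 1), 0, tolerance = 1e-10)
  }
  # LRT arithmetic and tenable calls
  for (lr in res$lrt) {
    expect_equal(lr$LR, 2 * lr$Delta)
    expect_gte(lr$p_value, 0)
    expect_lte(lr$p_value, 1)
  }
})

test_that("LRT arithmetic matches chi-square tail values", {
  f0 <- structure(list(lnL = -1000, np = 10, model = "M1a"), class = "site_model_fit")
  f1 <- structure(list(lnL = -991.10, np = 12, model = "M2a"), class = "site_model_fit")
  lr <- likelihood_ratio_test(f0, f1)
  expect_equal(lr$Delta, 8.90)
  expect_equal(lr$LR, 17.8)
  expect_equal(lr$df, 2)
  expect_equal(lr$p_value, pchisq(17.8, 2, lower.tail = FALSE))
  expect_lt(lr$p_value, 5e-4)
  expect_equal(lr$tenable, "M2a")

  # Delta = 0 -> p = 1, null tenable
  f1b <- structure(list(lnL = -1000, np = 12, model = "M2a"), class = "site_model_fit")
  lr0 <- likelihood_ratio_test(f0, f1b)
  expect_equal(lr0$p_value, 1)
  expect_equal(lr0$tenable, "M1a")

  # meaningful negative deficit errors out
  f1c <- structure(list(lnL = -1000.01, np = 12, model = "M2a"), class = "site_model_fit")
  expect_error(likelihood_ratio_test(f0, f1c), "optimizer failure")
})

test_that("NEB report flags positive columns and respects the threshold", {
  fx <- make_subgroup_fixture(tempfile(), regime = "positive-at-key",
                              n_taxa = 4, n_codons = 190, seed = 61)
  aln <- fx$alignment; tr <- fx$tree
  f8 <- fit_site_model(aln, tr, "M8", restarts = 0,
                       init = fit_site_model(aln, tr, "M7", restarts = 0,
                                             control = ctrl_fast),
                       control = ctrl_fast)
  rep8 <- neb_site_report(f8, threshold = 0.95)
  expect_equal(nrow(rep8), 190)
  expect_true(all(rep8$P_positive >= 0 & rep8$P_positive <= 1))
  expect_setequal(unique(rep8$call[rep8$P_positive > 0.95]), "Positive")
  # planted truly-positive columns are enriched in P(omega > 1)
  pos_cols <- which(fx$site_omega > 1)
  expect_gt(mean(rep8$P_positive[pos_cols]), mean(rep8$P_positive[-pos_cols]))
  # with a position map, the Ballesteros-Weinstein columns come through
  pm <- data.frame(column_index = 1:190,
                   bw_index = as.character(1:190),
                   is_key = seq_len(190) %in% fx$key_columns)
  rep_pm <- neb_site_report(f8, position_map = pm)
  expect_true(all(rep_pm$key[fx$key_columns]))
})

test_that("fit methods expose coefficients, logLik and simulation", {
  tr <- random_subgroup_tree(4, depth = 0.8, seed = 71)
  aln <- simulate_codon_alignment(tr, n_codons = 60, omegas = 0.3, seed = 72)
  fit <- fit_site_model(aln, tr, "M0", restarts = 0, control = ctrl_fast)
  co <- coef(fit)
  expect_true(all(c("kappa", "omega0") %in% names(co)))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$lnL)
  expect_equal(attr(ll, "df"), fit$np)
  sims <- simulate(fit, nsim = 2, seed = 9, n_codons = 20)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$column_count, 20)
  expect_output(print(fit), "Codon site model M0")
  expect_output(print(summary(fit)), "mean NEB omega")
})
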