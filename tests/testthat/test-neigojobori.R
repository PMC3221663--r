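test_that("site counts match hand enumeration and conserve s + n = 3", {
  expect_equal(ng_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng_site_counts("ATG"), c(s = 0, n = 3))
  # conservation over every sense codon
  for (cod in sense_codons()) {
    sn <- ng_site_counts(cod)
    expect_equal(unname(sum(sn)), 3)
  }
  expect_error(ng_site_counts("TAA"), "sense")
})

test_that("stop-excluding site convention redistributes stop-adjacent sites", {
  # TAT (Tyr), third position: TAC synonymous, TAA/TAG stops. Counting stop
  # mutations as nonsynonymous gives s = 1/3; excluding them leaves TAC as
  # the only alternative, s = 1. Both conventions conserve s + n = 3.
  expect_equal(unname(ng_site_counts("TAT", "nonsynonymous")["s"]), 1 / 3)
  expect_equal(unname(ng_site_counts("TAT", "exclude")["s"]), 1)
  expect_equal(unname(sum(ng_site_counts("TAT", "exclude"))), 3)
  # codons with no stop neighbours are unchanged
  expect_equal(ng_site_counts("CTT", "exclude"), ng_site_counts("CTT"))
})

test_that("pairwise dN/dS handles identity, saturation and gaps", {
  r0 <- ng_pairwise(c("ATG", "TTT"), c("ATG", "TTT"))
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)

  # one synonymous difference over a third of a synonymous site: saturated dS
  r <- ng_pairwise("TTT", "TTC")
  expect_equal(r$pN, 0)
  expect_equal(r$dN, 0)
  expect_true(r$pS >= 0.75)
  expect_true(r$saturated_dS)
  expect_true(is.na(r$dS))

  expect_error(ng_pairwise(c("ATG"), c("ATG", "TTT")), "length mismatch")
  expect_error(ng_pairwise("---", "ATG"), "gapped")
  # gap columns are deleted pairwise
  rg <- ng_pairwise(c("ATG", "---", "TTT"), c("ATG", "AAA", "TTT"))
  expect_equal(rg$L, 2)
  expect_equal(rg$dN, 0)
})

test_that("pathway-averaged difference counts equal the path-walk oracle", {
  tabs <- sense_codons()
  set.seed(7)
  # all two- and three-position pairs among a random sample, plus known cases
  sample_pairs <- cbind(sample(tabs, 150, replace = TRUE),
                        sample(tabs, 150, replace = TRUE))
  sample_pairs <- rbind(sample_pairs,
                        c("TTT", "GGG"), c("ATG", "TGG"), c("TCA", "ACT"),
                        c("AAA", "AAG"), c("CGA", "AGG"))
  for (i in seq_len(nrow(sample_pairs))) {
    a <- sample_pairs[i, 1]; b <- sample_pairs[i, 2]
    got <- siteomega:::ng_diff_counts_one(a, b)
    want <- oracle_ng_diff(a, b)
    expect_equal(got, want, tolerance = 1e-12,
                 label = paste("pair", a, b))
  }
})

test_that("pairwise counting is symmetric and conserves total sites", {
  set.seed(11)
  tabs <- sense_codons()
  for (rep in 1:5) {
    a <- sample(tabs, 30, replace = TRUE)
    b <- sample(tabs, 30, replace = TRUE)
    r1 <- ng_pairwise(a, b)
    r2 <- ng_pairwise(b, a)
    expect_equal(r1[c("pN", "pS", "N", "S")], r2[c("pN", "pS", "N", "S")])
    expect_equal(r1$N + r1$S, 3 * 30)
  }
})

test_that("Jukes-Cantor correction is monotone and exceeds p", {
  p <- seq(0.01, 0.7, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_true(is.na(jukes_cantor(0.75)))
})

test_that("admission filter passes, reduces, and flags as specified", {
  mk_table <- function(dN, labels) {
    dS <- matrix(0.5, nrow(dN), ncol(dN)); diag(dS) <- 0
    dimnames(dN) <- dimnames(dS) <- list(labels, labels)
    structure(list(labels = labels, dN = dN, dS = dS,
                   saturated_dN = matrix(FALSE, nrow(dN), ncol(dN)),
                   saturated_dS = matrix(FALSE, nrow(dN), ncol(dN))),
              class = "pairwise_rate_table")
  }
  labs <- paste0("s", 1:4)
  # all zero: pass untouched
  adm0 <- subgroup_admission(mk_table(matrix(0, 4, 4), labs))
  expect_true(adm0$pass)
  expect_length(adm0$removed, 0)

  # one outlier with dN = 1.5 to everyone: that member removed, rest pass
  dN <- matrix(0.2, 4, 4); diag(dN) <- 0
  dN[4, 1:3] <- dN[1:3, 4] <- 1.5
  adm1 <- subgroup_admission(mk_table(dN, labs))
  expect_true(adm1$pass)
  expect_equal(adm1$removed, "s4")
  expect_setequal(adm1$members, labs[1:3])

  # high dS but low dN: retained with flag S
  tb <- mk_table(matrix(0.4, 4, 4) - diag(0.4, 4), labs)
  tb$dS <- matrix(3.2, 4, 4, dimnames = list(labs, labs)); diag(tb$dS) <- 0
  adm2 <- subgroup_admission(tb)
  expect_true(adm2$pass)
  expect_true("S" %in% adm2$flags)

  # irreducible trio: flagged N, not passing
  dN3 <- matrix(1.4, 3, 3); diag(dN3) <- 0
  adm3 <- subgroup_admission(mk_table(dN3, paste0("s", 1:3)))
  expect_false(adm3$pass)
  expect_true("N" %in% adm3$flags)
})

test_that("admission can use the mean-over-pairs statistic", {
  labs <- paste0("s", 1:4)
  dN <- matrix(0.9, 4, 4); diag(dN) <- 0
  dN[1, 2] <- dN[2, 1] <- 1.4   # one pair over the max bound
  dS <- matrix(0.5, 4, 4); diag(dS) <- 0
  dimnames(dN) <- dimnames(dS) <- list(labs, labs)
  tb <- structure(list(labels = labs, dN = dN, dS = dS,
                       saturated_dN = matrix(FALSE, 4, 4),
                       saturated_dS = matrix(FALSE, 4, 4)),
                  class = "pairwise_rate_table")
  # max statistic trips the filter; the mean (below 1) does not
  expect_gt(length(subgroup_admission(tb)$removed), 0)
  adm_mean <- subgroup_admission(tb, statistic = "mean")
  expect_true(adm_mean$pass)
  expect_length(adm_mean$removed, 0)
})
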