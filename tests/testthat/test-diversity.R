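test_that("Shannon entropy spans its theoretical range", {
  expect_equal(shannon_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(shannon_entropy(c("A", "C", "D", "E")), 2)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(round(shannon_entropy(aa20), 2), 4.32)
  # gaps excluded by default; counted as a 21st symbol on request
  expect_equal(shannon_entropy(c("A", "A", "-", "-")), 0)
  expect_equal(shannon_entropy(c("A", "A", "-", "-"), count_gaps = TRUE), 1)
  expect_warning(h <- shannon_entropy(c("-", "-")), "all-gap")
  expect_true(is.na(h))
})

test_that("entropy is permutation- and relabeling-invariant", {
  set.seed(41)
  for (i in 1:10) {
    col <- sample(strsplit("ACDEFGHIKL", "")[[1]], 12, replace = TRUE)
    expect_equal(shannon_entropy(sample(col)), shannon_entropy(col))
    relabeled <- chartr("ACDEFGHIKL", "MNPQRSTVWY", col)
    expect_equal(shannon_entropy(relabeled), shannon_entropy(col))
    expect_lte(shannon_entropy(col), log2(min(20, length(col))) + 1e-12)
  }
})

test_that("Karlin-Brocchieri similarity matches direct table lookups", {
  expect_equal(karlin_similarity(c("W", "W", "W")), 1)
  # two-sequence column: single normalized entry
  b80 <- siteomega:::blosum80()
  for (pair in list(c("A", "R"), c("L", "I"), c("C", "W"))) {
    want <- b80[pair[1], pair[2]] /
      sqrt(b80[pair[1], pair[1]] * b80[pair[2], pair[2]])
    expect_equal(karlin_similarity(pair), want)
  }
  # order invariance
  col <- c("A", "R", "N", "D", "A")
  expect_equal(karlin_similarity(rev(col)), karlin_similarity(col))
  expect_error(karlin_similarity(c("A", "1")), "absent")
  expect_error(karlin_similarity(c("A", "-")), ">= 2")
})

test_that("column similarity equals the brute-force double loop", {
  set.seed(51)
  b80 <- siteomega:::blosum80()
  for (i in 1:8) {
    col <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 7, replace = TRUE)
    acc <- 0; np <- 0
    for (r in 1:6) for (s in (r + 1):7) {
      acc <- acc + b80[col[r], col[s]] / sqrt(b80[col[r], col[r]] * b80[col[s], col[s]])
      np <- np + 1
    }
    expect_equal(karlin_similarity(col), acc / np)
  }
})

test_that("key-column distances flag identity and grow with divergence", {
  m_id <- rbind(a = rep("A", 10), b = rep("A", 10), c = rep("A", 10))
  d0 <- column_distance(m_id, 1:10)
  expect_equal(d0$D_key, 0)
  expect_true(is.infinite(d0$neg_log10_D_key))

  # two sequences differing at all 10 key columns: d > 1 substitution/site
  m2 <- rbind(a = strsplit("ACDEFGHIKL", "")[[1]],
              b = strsplit("MNPQRSTVWY", "")[[1]])
  d2 <- column_distance(m2, 1:10)
  expect_gt(d2$D_key, 1)

  # monotone in the number of differing key columns
  base <- strsplit("ACDEFGHIKL", "")[[1]]
  d_at <- function(k) {
    other <- base
    if (k > 0) other[seq_len(k)] <- strsplit("MNPQRSTVWY", "")[[1]][seq_len(k)]
    column_distance(rbind(a = base, b = other), 1:10)$D_key
  }
  dvals <- vapply(c(2, 5, 8, 10), d_at, numeric(1))
  expect_true(all(diff(dvals) > 0))
  expect_error(column_distance(m2[1, , drop = FALSE], 1:10), ">= 2")
})

test_that("diversity profile aggregates key-column measures", {
  set.seed(61)
  m <- matrix(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 5 * 30,
                     replace = TRUE), 5, 30,
              dimnames = list(paste0("s", 1:5), NULL))
  keys <- c(2, 7, 11, 19, 25)
  dv <- diversity_profile(m, keys)
  expect_length(dv$entropy, 5)
  expect_length(dv$blosum80, 5)
  expect_equal(dv$H_key, mean(dv$entropy))
  expect_equal(dv$BLO80_key, mean(dv$blosum80))
  expect_true(all(dv$blosum80 >= -1 & dv$blosum80 <= 1))
})

test_that("diversity-selection regressions recover planted correlations", {
  # perfectly correlated
  ok <- 10^seq(-2.5, -0.3, length.out = 20)
  dv <- 1 + 0.5 * log10(ok)
  r1 <- diversity_vs_selection(dv, ok)
  expect_equal(r1$full$R, 1, tolerance = 1e-10)
  expect_equal(r1$full$r_squared, 1, tolerance = 1e-10)

  # independent pairs: |R| small on average over replicates
  set.seed(71)
  rs <- replicate(40, {
    d <- rnorm(40); o <- 10^runif(40, -3, 0)
    diversity_vs_selection(d, o)$full$R
  })
  expect_lt(abs(mean(rs)), 0.12)
  expect_lt(mean(abs(rs) > 0.45), 0.1)

  # planted R ~ 0.5 recovered within sampling tolerance, restricted fit runs
  set.seed(72)
  o <- 10^runif(40, -3, 0)
  d <- scale(log10(o))[, 1] * 0.5 + rnorm(40, 0, sqrt(1 - 0.25))
  r3 <- diversity_vs_selection(d, o)
  expect_lt(abs(r3$full$R - 0.5), 0.3)
  expect_false(is.null(r3$restricted))
  expect_lte(r3$restricted$n, r3$full$n)
  # admission filter excludes flagged subgroups
  keep <- rep(TRUE, 40); keep[1:35] <- FALSE
  expect_error(diversity_vs_selection(d[1:2], o[1:2]), "fewer than 3")
})
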