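test_that("three-taxon neighbor joining solves the three-point formulas", {
  D <- matrix(c(0, 5, 8, 5, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 6))
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(101)
  for (rep in 1:5) {
    true <- ape::unroot(ape::rtree(5, tip.label = paste0("t", 1:5)))
    true$edge.length <- runif(nrow(true$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(est), true), 0, ignore_attr = TRUE)
    # patristic distances reproduced
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("ultrametric equal-distance four-taxon matrix collapses internals", {
  D <- matrix(2, 4, 4) - diag(2, 4)
  dimnames(D) <- list(paste0("t", 1:4), paste0("t", 1:4))
  tr <- neighbor_joining(D)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_equal(sum(tr$edge.length[internal]), 0, tolerance = 1e-10)
  expect_true(all(tr$edge.length >= 0))
})

test_that("distance matrix validation rejects malformed input", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2)), ">= 3")
  bad <- matrix(0, 3, 3); bad[1, 2] <- 1; bad[2, 1] <- 2
  expect_error(neighbor_joining(bad), "symmetric")
  nas <- matrix(0, 3, 3); nas[1, 2] <- nas[2, 1] <- NA
  expect_error(neighbor_joining(nas), "NA")
})

test_that("Kimura-corrected protein distance matches its closed form", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 99), "R"), collapse = "")
  m <- rbind(x = strsplit(a, "")[[1]], y = strsplit(b, "")[[1]])
  D <- protein_distance_matrix(m, model = "Kimura")
  p <- 0.01
  expect_equal(D["x", "y"], -log(1 - p - 0.2 * p^2), tolerance = 1e-12)
  expect_equal(D["x", "x"], 0)
})

test_that("JTT-ML distances increase with observed differences", {
  set.seed(111)
  base <- sample(c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L"),
                 120, replace = TRUE)
  d_at <- function(k) {
    other <- base
    other[seq_len(k)] <- ifelse(base[seq_len(k)] == "A", "V", "A")
    m <- rbind(x = base, y = other)
    protein_distance_matrix(m, model = "JTT-ML")["x", "y"]
  }
  d <- vapply(c(5, 15, 30, 60), d_at, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_equal(d_at(0), 0, tolerance = 1e-8)
})

test_that("bootstrap consensus recovers strong signal and is deterministic", {
  # clean 5-taxon alignment with two well-separated clades
  set.seed(121)
  n <- 60
  block <- function(ch, n) strsplit(paste(rep(ch, n), collapse = ""), "")[[1]]
  m <- rbind(a = block("A", n), b = block("A", n), c = block("S", n),
             d = block("S", n), e = block("T", n))
  jitter_cols <- sample(n, 25)
  for (j in jitter_cols) m[sample(5, 1), j] <- sample(c("G", "P", "W"), 1)
  cons1 <- bootstrap_consensus(m, n_reps = 30, seed = 7)
  cons2 <- bootstrap_consensus(m, n_reps = 30, seed = 7)
  expect_equal(ape::write.tree(cons1), ape::write.tree(cons2))
  # the (a,b) clade is recovered with high support
  parts <- ape::prop.part(cons1)
  labs <- attr(parts, "labels")
  has_ab <- any(vapply(parts, function(p)
    setequal(labs[p], c("a", "b")) || setequal(labs[p], c("c", "d", "e")),
    logical(1)))
  expect_true(has_ab)

  # single replicate: consensus equals that replicate, all supports 100
  cons_one <- bootstrap_consensus(m, n_reps = 1, seed = 3)
  expect_true(all(as.numeric(cons_one$node.label) == 100))
})

test_that("newick round trip preserves topology, lengths and supports", {
  set.seed(131)
  tr <- ape::rtree(6)
  tr$node.label <- c("", round(runif(tr$Nnode - 1) * 100, 1))
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  tr2 <- ape::read.tree(path)
  expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_equal(tr2$node.label, tr$node.label)
})

test_that("PHYLIP lower-triangle distance files round-trip numerically", {
  D <- matrix(c(0, 5, 8, 5, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("alpha", "beta", "gamma"), NULL))
  path <- tempfile()
  write_phylip_dist(D, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_match(lines[3], "^beta\\s+5\\.000000$")
  expect_match(lines[4], "^gamma\\s+8\\.000000\\s+9\\.000000$")
})
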