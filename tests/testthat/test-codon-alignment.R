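test_that("protein alignment reading validates shape and content", {
  p <- write_temp_fasta(c(a = "AC-", b = "AD-"))
  m <- read_protein_alignment(p)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m[, 3]), c("-", "-"))
  expect_equal(rownames(m), c("a", "b"))

  ragged <- write_temp_fasta(c(a = "ACD", b = "AC"))
  expect_error(read_protein_alignment(ragged), "ragged")

  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_protein_alignment(empty))

  dup <- write_temp_fasta(c(a = "AC", a = "AD"))
  expect_error(read_protein_alignment(dup), "duplicate")
})

test_that("back-translation assembles codon alignments and cross-checks", {
  m <- matrix(c("M"), 1, 1, dimnames = list("x", NULL))
  ca <- build_codon_alignment(m, c(x = "ATG"))
  expect_equal(unname(ca$codons[1, 1]), "ATG")

  m2 <- matrix(c("M", "K"), 1, 2, dimnames = list("x", NULL))
  expect_error(build_codon_alignment(m2, c(x = "ATGAAT")),
               "back-translation error")
  # internal stop (a trailing stop codon is tolerated and dropped)
  m3 <- matrix(c("M", "X", "M"), 1, 3, dimnames = list("x", NULL))
  expect_error(build_codon_alignment(m3, c(x = "ATGTAAATG")), "stop")
  ca_trail <- build_codon_alignment(matrix("M", 1, 1, dimnames = list("x", NULL)),
                                    c(x = "ATGTAA"))
  expect_equal(unname(ca_trail$codons[1, 1]), "ATG")
  # ambiguous codon becomes a gap
  m4 <- matrix(c("M", "K"), 1, 2, dimnames = list("x", NULL))
  ca4 <- build_codon_alignment(m4, c(x = "ATGANA"))
  expect_equal(unname(ca4$codons[1, 2]), "---")
})

test_that("codon alignments round-trip through translation", {
  fx <- make_subgroup_fixture(tempfile(), regime = "strong-negative",
                              n_taxa = 5, n_codons = 40, seed = 42)
  aa <- read_protein_alignment(fx$paths$protein)
  cds <- read_cds(fx$paths$cds)
  ca <- build_codon_alignment(aa, cds)
  expect_equal(ca$codons, fx$alignment$codons[rownames(aa), ])
  expect_identical(translate_alignment(ca), aa)
})

test_that("ligand-category rules follow the orphan and unanimity order", {
  # all orphans
  expect_equal(classify_subgroup(c(NA, NA, NA)), "orphan")
  # more than two orphans dominates even with a unanimous class
  expect_equal(classify_subgroup(c("lipid", NA, NA, NA, NA)), "divergent")
  # exactly two orphans: the unanimous class wins
  expect_equal(classify_subgroup(c("peptide", "peptide", NA, NA)), "peptide")
  # mixed chemical classes
  expect_equal(classify_subgroup(c("small", "lipid", "small")), "divergent")
  expect_equal(classify_subgroup(rep("small", 5)), "small")
  expect_error(classify_subgroup(c("small", NA), orphan = c(FALSE, FALSE)),
               "classification error")
})

test_that("packaged subgroup table reproduces the published category counts", {
  sg <- gpcr_subgroups()
  cc <- classify_subgroups(sg)
  counts <- table(cc$category)
  expect_equal(unname(counts["small"]), 10L)
  expect_equal(unname(counts["lipid"]), 9L)
  expect_equal(unname(counts["peptide"]), 19L)
  expect_equal(unname(counts["divergent"]), 6L)
  expect_equal(unname(counts["orphan"]), 1L)
  # subgroup sizes within the 3-10 range
  expect_true(all(cc$n_members >= 3 & cc$n_members <= 10))
  # muscarinic subgroup -> small; all-orphan subgroup 45 -> orphan
  expect_equal(cc$category[cc$subgroup_id == "1"], "small")
  expect_equal(cc$category[cc$subgroup_id == "45"], "orphan")
  # subgroup 39 (four orphans of five) -> divergent
  expect_equal(cc$category[cc$subgroup_id == "39"], "divergent")
})

test_that("key-position map has ten unique key columns", {
  pm <- gpcr_key_positions()
  expect_equal(sum(pm$is_key), 10L)
  keys <- key_columns(pm)
  expect_equal(keys, c(68, 71, 72, 114, 117, 121, 124, 168, 171, 175))
  bw <- pm$bw_index[pm$is_key]
  expect_setequal(bw, c("3.29", "3.32", "3.33", "4.60", "5.35", "5.39",
                        "5.42", "6.55", "7.35", "7.39"))
})
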