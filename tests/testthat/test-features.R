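test_that("composition handles homopolymers, dipeptides and exclusion modes", {
  c1 <- composition("AAAA", order = 1)
  expect_equal(c1[["A"]], 1)
  expect_equal(sum(c1), 1)
  expect_length(c1, 20)

  # adjacent pairs of ACAC enumerated by hand: AC, CA, AC over length 4
  c2 <- composition("ACAC", order = 2)
  expect_length(c2, 400)
  expect_equal(c2[["AC"]], 0.5)
  expect_equal(c2[["CA"]], 0.25)
  expect_equal(sum(c2 > 0), 2)

  # every adjacent pair of ACAC contains a C, so drop_CH zeroes the space
  c2d <- composition("ACAC", order = 2, exclusion_mode = "drop_CH")
  expect_length(c2d, 324)
  expect_true(all(c2d == 0))
  expect_false(any(grepl("[CH]", names(c2d))))
  expect_length(composition("AAAA", order = 1, exclusion_mode = "drop_CH"), 18)

  # masking CxxCH zeroes the motif residues but keeps the denominator L
  cm <- composition("MCAACHKL", order = 1, exclusion_mode = "mask_CxxCH")
  expect_equal(cm[["M"]], 1 / 8)
  expect_equal(cm[["K"]], 1 / 8)
  expect_equal(cm[["C"]], 0)
  expect_equal(cm[["A"]], 0)
})

test_that("composition rejects bad input and names the offending symbol", {
  expect_error(composition("ACBD", 1), "B")
  expect_error(composition("A", 2), "too short")
  expect_error(composition("", 1))
})

test_that("composition matches a naive double-loop oracle on random sequences", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_sequence(sample(2:50, 1))
    for (ord in 1:2) {
      expect_equal(unclass(composition(s, order = ord))[],
                   naive_composition(s, ord),
                   ignore_attr = TRUE)
    }
  }
})

test_that("frequency normalisation follows the count/L convention", {
  set.seed(7)
  for (i in 1:20) {
    len <- sample(5:80, 1)
    s <- random_sequence(len)
    expect_equal(sum(composition(s, 1)), 1)
    expect_equal(sum(composition(s, 2)), (len - 1) / len)
  }
})

test_that("composition_matrix featurizes regions using the cleavage index", {
  prot <- tibble::tibble(id = c("p1", "p2"),
                         sequence = c("MKKLLLLLLAAAWWWDDD", "MRRVVVVVVAGAYYYEEE"),
                         cleavage = c(12L, 12L))
  full <- composition_matrix(prot, region = "full", order = 1)
  expect_equal(dim(full), c(2, 21))
  sp <- composition_matrix(prot, region = "sp", order = 1)
  expect_equal(sp$W[1], 0)
  mature <- composition_matrix(prot, region = "mature", order = 1)
  expect_equal(mature$W[1], 0.5)
  expect_equal(mature$D[1], 0.5)
  prot$cleavage <- NULL
  expect_error(composition_matrix(prot, region = "mature"), "cleavage")
})

test_that("gravy matches the Kyte-Doolittle closed forms", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("IR"), 0)
  expect_equal(gravy("IVLK"), gravy("KLVI"))
})

test_that("aliphatic index matches Ikai's closed forms", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VV"), 290)
  expect_equal(aliphatic_index("GGGG"), 0)
  expect_equal(aliphatic_index("IL"), 390)
})

test_that("gravy and aliphatic index are permutation- and repeat-invariant", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_sequence(sample(5:40, 1))
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(gravy(s), gravy(perm))
    expect_equal(aliphatic_index(s), aliphatic_index(perm))
    expect_equal(gravy(s), gravy(paste0(s, s)))
    expect_equal(aliphatic_index(s), aliphatic_index(paste0(s, s)))
  }
})

test_that("physchem profile reports class prevalences as fractions", {
  prof <- physchem_profile(tibble::tibble(id = "x", sequence = "ILVA"))
  expect_equal(prof$ILV, 0.75)
  expect_equal(prof$AILVMFWYC, 1)
  expect_equal(prof$KR, 0)
  expect_equal(prof$gravy, gravy("ILVA"))
  prof2 <- physchem_profile(tibble::tibble(id = "y", sequence = random_sequence(60)))
  cls <- prof2[, !(names(prof2) %in% c("id", "gravy", "aliphatic_index"))]
  expect_true(all(cls >= 0 & cls <= 1))
  expect_true(prof2$aliphatic_index >= 0 && prof2$aliphatic_index <= 390)
})

test_that("redundancy filter removes near-identical sequences deterministically", {
  # identical pair: one survivor
  two <- tibble::tibble(id = c("a", "b"), sequence = c("PEPTIDE", "PEPTIDE"))
  expect_equal(redundancy_filter(two)$id, "a")

  # unrelated sequences: both kept
  disjoint <- tibble::tibble(id = c("a", "b"), sequence = c("PPPPPP", "KKKKKK"))
  expect_equal(nrow(redundancy_filter(disjoint)), 2)

  # duplicate plus unrelated: two survivors
  three <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = c("PEPTIDE", "PEPTIDE", "KKKKKK"))
  expect_equal(redundancy_filter(three)$id, c("a", "c"))

  # the shorter member of a redundant pair is dropped
  pair <- tibble::tibble(id = c("short", "long"),
                         sequence = c("MKTAYIAKQRQISFVK", "MKTAYIAKQRQISFVKSH"))
  expect_equal(redundancy_filter(pair, identity_threshold = 0.8)$id, "long")

  expect_equal(nrow(redundancy_filter(two[1, ])), 1)
})
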