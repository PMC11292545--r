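test_that("family_of strips exactly one terminal isoform suffix", {
  expect_equal(family_of("P68363-2"), "P68363")
  expect_equal(family_of("P68363"), "P68363")
  expect_equal(family_of("AB-CD-3"), "AB-CD")
  expect_equal(family_of(c("Q1-1", "Q1-10")), c("Q1", "Q1"))
})

test_that("peptide classification covers the four sharing patterns", {
  cat <- make_catalog(list(P1 = 1, Q1 = 2, R1 = 1, S1 = 1))
  expect_equal(classify_peptide("P1", cat), "UNIQUE")
  expect_equal(classify_peptide("Q1-1", cat), "ISOFORM_SPECIFIC")
  expect_equal(classify_peptide("Q1-2", cat), "ISOFORM_SPECIFIC")
  expect_equal(classify_peptide(c("Q1-1", "Q1-2"), cat), "SHARED_ISOFORMS")
  expect_equal(classify_peptide(c("R1", "S1"), cat), "SHARED_MULTI")
  expect_equal(classify_peptide(c("P1", "Q1-1"), cat), "SHARED_MULTI")
  expect_error(classify_peptide("ZZZ", cat), "unknown accession")
})

test_that("classification agrees with the brute-force membership oracle", {
  set.seed(42)
  for (i in 1:300) {
    case <- random_classify_case()
    expect_equal(classify_peptide(case$accessions, case$catalog),
                 oracle_classify(case$accessions, case$catalog),
                 info = paste(case$accessions, collapse = ","))
  }
})

test_that("composition sums member areas over observed values", {
  cat <- make_catalog(list(Q1 = 2))
  tab <- make_area_table(matrix(c(10, NA, 5, 7), nrow = 2, byrow = TRUE,
                                dimnames = list(NULL, c("s1", "s2"))),
                         sequences = c("AAAGGGK", "CCCDDDK"))
  map <- make_map(list(AAAGGGK = "Q1-1", CCCDDDK = "Q1-1"))
  pgm <- compose_protein_groups(tab, map, cat, "include_shared")
  expect_equal(nrow(pgm$areas), 1L)
  expect_equal(pgm$areas["Q1-1", "s1"], 15)
  # partner missing in s2: sum over the observed member only
  expect_equal(pgm$areas["Q1-1", "s2"], 7)
  expect_equal(pgm$groups$pclass, "ISOFORM_SPECIFIC")
  expect_equal(pgm$groups$n_peptides, 2L)
})

test_that("cross-family shared peptides follow the composition policy", {
  cat <- make_catalog(list(R1 = 1, S1 = 1))
  tab <- make_area_table(matrix(c(3, 4), nrow = 2,
                                dimnames = list(NULL, "s1")),
                         sequences = c("AAAGGGK", "CCCDDDK"))
  map <- make_map(list(AAAGGGK = c("R1", "S1"), CCCDDDK = "R1"))
  inc <- compose_protein_groups(tab, map, cat, "include_shared")
  expect_true("SHARED_MULTI" %in% inc$groups$pclass)
  expect_equal(inc$groups$family[inc$groups$pclass == "SHARED_MULTI"], "MULTI")
  exc <- compose_protein_groups(tab, map, cat, "exclude_shared")
  expect_false("SHARED_MULTI" %in% exc$groups$pclass)
  expect_equal(unname(exc$dropped[["shared_multi"]]), 1L)
})

test_that("summed area is conserved through composition", {
  set.seed(42)
  cat <- make_catalog(list(P1 = 1, Q1 = 2, R1 = 3, S1 = 1))
  n <- 30
  seqs <- vapply(seq_len(n), pepseq, "")
  sets <- lapply(seq_len(n), function(i) {
    case <- sample(list("P1", "Q1-1", c("Q1-1", "Q1-2"), c("P1", "S1"),
                        c("R1-1", "R1-2", "R1-3")), 1)[[1]]
    case
  })
  names(sets) <- seqs
  mat <- matrix(rlnorm(n * 4, 10, 1), n,
                dimnames = list(NULL, sprintf("s%d", 1:4)))
  mat[sample(length(mat), 20)] <- NA
  tab <- make_area_table(mat, seqs)
  map <- make_map(sets)
  for (policy in c("include_shared", "exclude_shared")) {
    pgm <- compose_protein_groups(tab, map, cat, policy)
    kept <- unlist(pgm$membership)
    per_sample_in <- colSums(tab$areas[kept, , drop = FALSE], na.rm = TRUE)
    per_sample_out <- colSums(pgm$areas, na.rm = TRUE)
    expect_equal(per_sample_out, per_sample_in, tolerance = 1e-6)
    # each contributing peptide belongs to exactly one group
    expect_false(anyDuplicated(kept) > 0)
  }
})

test_that("composition is invariant to input row order and idempotent", {
  set.seed(7)
  cat <- make_catalog(list(P1 = 1, Q1 = 2))
  seqs <- vapply(1:8, pepseq, "")
  sets <- stats::setNames(
    list("P1", "P1", "Q1-1", "Q1-2", c("Q1-1", "Q1-2"), "P1", "Q1-1",
         c("Q1-1", "Q1-2")), seqs)
  mat <- matrix(rlnorm(16, 8, 1), 8, dimnames = list(NULL, c("s1", "s2")))
  tab <- make_area_table(mat, seqs)
  perm <- sample(8)
  tab2 <- make_area_table(mat[perm, ], seqs[perm])
  map <- make_map(sets)
  a <- compose_protein_groups(tab, map, cat)
  b <- compose_protein_groups(tab2, map, cat)
  expect_equal(a$areas, b$areas)
  expect_equal(a$groups, b$groups)

  # one peptide per distinct accession set: composing is the identity
  seqs1 <- vapply(1:3, pepseq, "")
  sets1 <- stats::setNames(list("P1", "Q1-1", c("Q1-1", "Q1-2")), seqs1)
  mat1 <- matrix(rlnorm(6, 8, 1), 3, dimnames = list(NULL, c("s1", "s2")))
  tab1 <- make_area_table(mat1, seqs1)
  pgm1 <- compose_protein_groups(tab1, make_map(sets1), cat)
  expect_equal(rownames(pgm1$areas), c("P1", "Q1-1", "Q1-1;Q1-2"))
  expect_equal(unname(pgm1$areas), unname(mat1), tolerance = 1e-9)
})

test_that("unmapped and unknown-accession peptides are counted, not fatal", {
  cat <- make_catalog(list(P1 = 1))
  tab <- make_area_table(matrix(c(1, 2, 3), 3, dimnames = list(NULL, "s1")),
                         sequences = c("AAAGGGK", "CCCDDDK", "EEEFFFK"))
  map <- make_map(list(AAAGGGK = "P1", CCCDDDK = "CONTAM9"))
  pgm <- compose_protein_groups(tab, map, cat)
  expect_equal(unname(pgm$dropped[["unmapped"]]), 1L)
  expect_equal(unname(pgm$dropped[["unknown_accession"]]), 1L)
  expect_equal(nrow(pgm$areas), 1L)

  map_none <- make_map(list(MMMWWWK = "P1"))
  expect_error(compose_protein_groups(tab, map_none, cat),
               "no peptide of the area table is mappable")
})
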