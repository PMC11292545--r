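test_that("identical config and seed give byte-identical output files", {
  cfg <- sim_config(n_families = 40, isoform_fraction = 0.2, n_de = 5,
                    n_splice = 2, seed = 42)
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  generate_dataset(cfg, out_dir = d1)
  generate_dataset(cfg, out_dir = d2)
  for (f in c("peptide_areas.tsv", "peptide_map.tsv", "design.tsv",
              "truth.tsv", "proteins.fasta"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("the configured family and cohort structure is realized exactly", {
  cfg <- sim_config(n_families = 200, isoform_fraction = 0.1, n_de = 10,
                    n_splice = 3, seed = 42)
  ds <- generate_dataset(cfg)
  sz <- lengths(ds$catalog$families)
  expect_equal(length(sz), 200L)
  expect_equal(sum(sz >= 2), 20L)            # round(200 * 0.1)
  expect_true(all(sz[sz >= 2] %in% 2:3))
  expect_equal(as.integer(table(ds$design$cohort)[c("A", "B")]), c(12L, 11L))
  expect_equal(sum(ds$truth$kind == "de"), 10L)
  expect_equal(sum(ds$truth$kind == "splice"), 3L)
  expect_false(any(duplicated(ds$truth$family)))
  expect_true(all(ds$truth$family %in% names(ds$catalog$families)))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(isoform_fraction = 0, specific_peptide_rate = 0.3),
               "infeasible")
  expect_error(sim_config(n_families = 50, isoform_fraction = 0.02,
                          n_de = 0, n_splice = 6),
               "exceeds the number of multi-isoform families")
  expect_error(sim_config(n_families = 10, n_de = 9, n_splice = 2),
               "exceeds n_families")
  expect_error(sim_config(de_fold_range = c(8, 2)), "fold ranges")
})

test_that("singleton-only catalogs yield no isoform-specific peptides", {
  cfg <- sim_config(n_families = 30, isoform_fraction = 0,
                    specific_peptide_rate = 0, n_de = 3, n_splice = 0,
                    seed = 42)
  ds <- generate_dataset(cfg)
  cls <- classify_peptides(ds$map, ds$catalog)
  expect_true(all(cls %in% c("UNIQUE", "SHARED_MULTI")))
})

test_that("digesting the emitted sequences reproduces the designed roles", {
  cfg <- sim_config(n_families = 60, isoform_fraction = 0.2, n_de = 5,
                    n_splice = 3, shared_multi_rate = 0.05, seed = 42)
  ds <- generate_dataset(cfg)
  cls <- stats::setNames(classify_peptides(ds$map, ds$catalog),
                         ds$map$sequence)
  roles <- ds$peptide_roles
  expected <- c(unique = "UNIQUE", common = "SHARED_ISOFORMS",
                specific = "ISOFORM_SPECIFIC", shared_multi = "SHARED_MULTI")
  expect_equal(unname(cls[roles$peptide]), unname(expected[roles$role]))
  expect_gt(sum(roles$role == "shared_multi"), 0)
})

test_that("planted abundance shifts are recovered empirically", {
  cfg <- sim_config(n_families = 150, isoform_fraction = 0.1, n_de = 30,
                    n_splice = 0, cv = 0.3, missing_rate = 0.1, seed = 42)
  ds <- generate_dataset(cfg)
  # peptide-level log2 areas, median-centered to remove loading offsets
  lg <- log2(ds$areas$areas)
  lg <- sweep(lg, 2, apply(lg, 2, stats::median, na.rm = TRUE), "-")
  inA <- ds$design$cohort[match(colnames(lg), ds$design$sample_id)] == "A"
  de <- ds$truth[ds$truth$kind == "de", ]
  roles <- ds$peptide_roles
  err <- vapply(seq_len(nrow(de)), function(i) {
    peps <- roles$peptide[roles$family == de$family[i] &
                            roles$role != "shared_multi"]
    x <- lg[rownames(lg) %in% swathsplice:::pep_key(peps, ""), ,
            drop = FALSE]
    emp <- mean(rowMeans(x[, !inA, drop = FALSE], na.rm = TRUE) -
                  rowMeans(x[, inA, drop = FALSE], na.rm = TRUE))
    abs(emp - de$log2_shift[i]) * log(2)  # natural-log scale
  }, 0)
  tol <- 3 * (cfg$cv / sqrt(min(12, 11)))
  expect_gte(mean(err <= tol), 0.95)
})
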