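test_that("students_t matches the pooled-variance reference and t.test", {
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3)),
               list(t_stat = 0, p = 1, df = 4L))
  res <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_stat, -3.674235, tolerance = 1e-3)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 0.021312, tolerance = 1e-3)
  expect_error(students_t(c(0, 0, 0), c(1, 1, 1)), "degenerate variance")
  expect_error(students_t(1, c(1, 2)), ">= 2 observed values")

  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1))
    ours <- students_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("students_t is antisymmetric and shift-invariant", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(4, 1)
    ab <- students_t(a, b); ba <- students_t(b, a)
    expect_equal(ab$t_stat, -ba$t_stat)
    expect_equal(ab$p, ba$p)
    sh <- students_t(a + 3.3, b + 3.3)
    expect_equal(sh$t_stat, ab$t_stat, tolerance = 1e-9)
  }
})

test_that("vectorized row t-statistics agree with per-row t.test under NAs", {
  set.seed(42)
  X <- matrix(rnorm(200), 20, 10)
  X[sample(200, 25)] <- NA
  res <- swathsplice:::row_t_stats(X, 1:5, 6:10, min_obs = 2L)
  for (i in 1:20) {
    a <- X[i, 1:5]; b <- X[i, 6:10]
    if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
      ref <- stats::t.test(a[!is.na(a)], b[!is.na(b)], var.equal = TRUE)
      expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-9)
      expect_equal(res$p[i], ref$p.value, tolerance = 1e-9)
    } else {
      expect_true(is.na(res$p[i]))
    }
  }
})

test_that("permutation FDR equals exhaustive enumeration on a 3-vs-3 toy", {
  set.seed(42)
  mat <- matrix(rlnorm(20 * 6, 12, 0.5), 20, 6,
                dimnames = list(NULL, sprintf("s%d", 1:6)))
  mat[1:3, 4:6] <- mat[1:3, 4:6] * 8  # a few real effects
  pgm <- compose_simple(mat)
  nm <- median_center(log2_transform(pgm))
  design <- sample_design(sprintf("s%d", 1:6), rep(c("A", "B"), each = 3))
  th <- analysis_thresholds(min_obs_per_group = 2, permutations = 1000)
  q <- permutation_fdr(nm, design, th)
  expect_true(attr(q, "exhaustive"))
  expect_equal(attr(q, "n_permutations"), 20L)
  idxA <- match(design$sample_id[design$cohort == "A"], colnames(nm$areas))
  idxB <- match(design$sample_id[design$cohort == "B"], colnames(nm$areas))
  expect_equal(as.vector(q), unname(oracle_perm_q(nm$areas, idxA, idxB)),
               tolerance = 1e-12)
  # any B >= number of distinct splits gives the identical exhaustive answer
  q20 <- permutation_fdr(nm, design, analysis_thresholds(
    min_obs_per_group = 2, permutations = 20))
  expect_equal(as.vector(q20), as.vector(q))
})

test_that("features constant across samples get q = 1", {
  mat <- matrix(5, 8, 6, dimnames = list(NULL, sprintf("s%d", 1:6)))
  nm <- median_center(log2_transform(compose_simple(mat)))
  design <- sample_design(sprintf("s%d", 1:6), rep(c("A", "B"), each = 3))
  q <- permutation_fdr(nm, design,
                       analysis_thresholds(min_obs_per_group = 2,
                                           permutations = 50))
  expect_equal(as.vector(q), rep(1, 8))
})

test_that("differential records apply the p-and-fold filter and obs-count rule", {
  set.seed(42)
  n <- 40
  mat <- matrix(rlnorm(n * 23, 12, 0.3), n,
                dimnames = list(NULL, c(sprintf("A%02d", 1:12),
                                        sprintf("B%02d", 1:11))))
  mat[1, 13:23] <- mat[1, 13:23] * 4       # planted 4-fold shift
  mat[2, c(3:12)] <- NA                    # observed in only 2 cohort-A samples
  design <- make_design(12, 11)
  nm <- median_center(log2_transform(compose_simple(mat)))
  rec <- differential_abundance(nm, design,
                                analysis_thresholds(permutations = 200))
  r1 <- rec[rec$group_id == "P001", ]
  expect_true(r1$significant)
  expect_equal(r1$fold, 4, tolerance = 4 * 0.3)
  expect_equal(r1$direction, "higher_in_B")
  r2 <- rec[rec$group_id == "P002", ]
  expect_false(r2$testable)
  expect_false(r2$significant)
  expect_true(is.na(r2$p))
  # sorted by p, untestable last
  expect_false(is.unsorted(rec$p, na.rm = TRUE))
  expect_true(all(which(!rec$testable) > max(which(rec$testable))))
})

test_that("discordance verdicts codify the common-vs-specific contrast", {
  cat <- make_catalog(list(Q1 = 2, W1 = 2, V1 = 2))
  th <- analysis_thresholds()
  # specific peptide strongly shifted, common flat -> discordant
  rec <- rbind(
    fake_record("Q1", "SHARED_ISOFORMS", p = 0.8, log2fc = 0.1),
    fake_record("Q1", "ISOFORM_SPECIFIC", p = 1e-9, log2fc = -4),
    # both shifted the same way -> concordant
    fake_record("W1", "SHARED_ISOFORMS", p = 1e-5, log2fc = 2),
    fake_record("W1", "ISOFORM_SPECIFIC", p = 1e-4, log2fc = 2.2),
    # no usable specific record -> untestable
    fake_record("V1", "SHARED_ISOFORMS", p = 0.5, log2fc = 0.1))
  calls <- call_isoform_discordance(rec, cat, th)
  v <- stats::setNames(calls$verdict, calls$family)
  expect_equal(v[["Q1"]], "SPLICING_DISCORDANT")
  expect_equal(v[["W1"]], "ABUNDANCE_CONCORDANT")
  expect_equal(v[["V1"]], "UNTESTABLE")
  expect_equal(calls$specific_fold[calls$family == "Q1"], 16)

  # a differentially abundant common group blocks the discordance call
  rec2 <- rbind(
    fake_record("Q1", "SHARED_ISOFORMS", p = 1e-6, log2fc = 2),
    fake_record("Q1", "ISOFORM_SPECIFIC", p = 1e-9, log2fc = 4))
  expect_equal(call_isoform_discordance(rec2, cat, th)$verdict[1],
               "ABUNDANCE_CONCORDANT")
  # an untestable common group blocks any verdict
  rec3 <- rbind(
    fake_record("Q1", "SHARED_ISOFORMS", p = NA, log2fc = 0,
                testable = FALSE),
    fake_record("Q1", "ISOFORM_SPECIFIC", p = 1e-9, log2fc = 4))
  expect_equal(call_isoform_discordance(rec3, cat, th)$verdict[1],
               "UNTESTABLE")
  # a weak specific shift below the fold gate is not called
  rec4 <- rbind(
    fake_record("Q1", "SHARED_ISOFORMS", p = 0.9, log2fc = 0.01),
    fake_record("Q1", "ISOFORM_SPECIFIC", p = 1e-4, log2fc = 0.5))
  expect_equal(call_isoform_discordance(rec4, cat, th)$verdict[1],
               "UNTESTABLE")
})

test_that("PCA separates duplicated profiles and rejects degenerate input", {
  set.seed(42)
  prof1 <- rlnorm(30, 10, 1); prof2 <- prof1 * rlnorm(30, 1, 1)
  mat <- cbind(s1 = prof1, s2 = prof1, s3 = prof2, s4 = prof2)
  nm <- median_center(log2_transform(compose_simple(mat)))
  design <- sample_design(sprintf("s%d", 1:4), c("A", "A", "B", "B"))
  qc <- pca_qc(nm, design)
  expect_gt(qc$explained_variance[1], 0.999)
  expect_true(is.infinite(qc$separation) || qc$separation > 10)
  pc1 <- qc$scores$PC1
  expect_gt(abs(mean(pc1[1:2]) - mean(pc1[3:4])), 0)

  flat <- matrix(3, 10, 4, dimnames = list(NULL, sprintf("s%d", 1:4)))
  nmf <- median_center(log2_transform(compose_simple(flat)))
  expect_error(pca_qc(nmf, design), "insufficient data")
})

test_that("pooled proportion comparison reproduces the worked example", {
  res <- compare_proportions(149, 4891, 851, 4263)
  expect_equal(round(100 * res$p1), 3)
  expect_equal(round(100 * res$p2), 20)
  expect_equal(res$p1, 149 / 4891)
  expect_lt(res$p, 1e-10)

  same <- compare_proportions(5, 10, 5, 10)
  expect_equal(same$diff, 0)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  extreme <- compare_proportions(0, 10, 10, 10)
  expect_equal(extreme$p1, 0)
  expect_equal(extreme$p2, 1)
  expect_equal(extreme$chi2, 20)

  expect_error(compare_proportions(11, 10, 1, 10), "k > n")
})
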