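# Two-sample statistics, permutation-based FDR, the abundance and isoform
# filters, the splicing-discordance caller, PCA QC, and the pooled
# two-proportion comparison for count phenotypes.

#' Two-sided equal-variance Student's t-test
#'
#' Pooled-variance two-sample t; `t_stat` follows the `t.test(a, b)`
#' convention (positive when group A's mean is larger), with
#' `df = |A| + |B| - 2`. When both groups have zero variance: equal means
#' give the defined limit `t = 0, p = 1`; unequal means are a
#' degenerate-variance error.
#'
#' @param values_A,values_B numeric vectors, each of length >= 2 (NAs
#'   removed first).
#' @return List with `t_stat`, `p`, `df`.
#' @export
students_t <- function(values_A, values_B) {
  a <- values_A[!is.na(values_A)]
  b <- values_B[!is.na(values_B)]
  if (length(a) < 2L || length(b) < 2L)
    stop("students_t: each group needs >= 2 observed values")
  nA <- length(a); nB <- length(b)
  df <- nA + nB - 2L
  ssA <- sum((a - mean(a))^2)
  ssB <- sum((b - mean(b))^2)
  pooled <- (ssA + ssB) / df
  delta <- mean(a) - mean(b)
  if (pooled <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5)
      return(list(t_stat = 0, p = 1, df = df))
    stop("students_t: degenerate variance (both groups constant, unequal means)")
  }
  t_stat <- delta / sqrt(pooled * (1 / nA + 1 / nB))
  list(t_stat = t_stat, p = 2 * stats::pt(-abs(t_stat), df), df = df)
}

# Vectorized NA-aware pooled t over the rows of a matrix. Rows with fewer
# than min_obs observed values in either column set are untestable (NA).
# Constant rows get t = 0, p = 1 (the defined limit).
row_t_stats <- function(X, idxA, idxB, min_obs = 2L) {
  XA <- X[, idxA, drop = FALSE]
  XB <- X[, idxB, drop = FALSE]
  oA <- !is.na(XA); oB <- !is.na(XB)
  nA <- rowSums(oA); nB <- rowSums(oB)
  sA <- rowSums(XA, na.rm = TRUE); sB <- rowSums(XB, na.rm = TRUE)
  mA <- sA / nA; mB <- sB / nB
  ssA <- rowSums(XA^2, na.rm = TRUE) - nA * mA^2
  ssB <- rowSums(XB^2, na.rm = TRUE) - nB * mB^2
  df <- nA + nB - 2
  testable <- nA >= min_obs & nB >= min_obs
  pooled <- pmax(ssA + ssB, 0) / df
  se <- sqrt(pooled * (1 / nA + 1 / nB))
  delta <- mA - mB
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- testable & pooled <= 0
  if (any(zero_var)) {
    eq <- zero_var & abs(delta) < .Machine$double.eps^0.5
    t[eq] <- 0; p[eq] <- 1
    t[zero_var & !eq] <- sign(delta[zero_var & !eq]) * Inf
    p[zero_var & !eq] <- 0
  }
  t[!testable] <- NA_real_; p[!testable] <- NA_real_
  list(t_stat = t, p = p, df = df, n_A = nA, n_B = nB,
       mean_A = mA, mean_B = mB, testable = testable)
}

# All distinct ways to relabel n samples with nA "A" labels, as an
# index matrix (one split per column), or NULL when there are too many
# to enumerate.
enumerate_label_splits <- function(n, nA, limit) {
  n_splits <- choose(n, nA)
  if (n_splits > limit) return(NULL)
  utils::combn(n, nA)
}

#' Permutation-based FDR for per-group two-sample t-tests
#'
#' For each group's observed p-value, the q-value is the average number of
#' permutation-null p-values at or below it per label permutation, divided
#' by the observed number of p-values at or below it, clipped to [0, 1]
#' and made monotone nondecreasing in p. When the number of distinct
#' cohort-label splits is at most `thresholds$permutations`, all splits
#' are enumerated exhaustively instead of sampled.
#'
#' @param matrix a `normalized_matrix` (or any `protein_group_matrix` on
#'   the log2 scale).
#' @param design a `sample_design` covering the matrix's samples.
#' @param thresholds an [analysis_thresholds()] (uses `min_obs_per_group`,
#'   `permutations`, `seed`).
#' @return Named numeric vector of q-values (NA for untestable groups),
#'   with attributes `n_permutations` and `exhaustive`.
#' @export
permutation_fdr <- function(matrix, design, thresholds = analysis_thresholds()) {
  stopifnot(inherits(matrix, "protein_group_matrix"),
            inherits(design, "sample_design"))
  idx <- match_design(matrix, design)
  res <- row_t_stats(matrix$areas, idx$A, idx$B,
                     thresholds$min_obs_per_group)
  q <- perm_q(matrix$areas, idx$A, idx$B, res$p,
              thresholds$min_obs_per_group, thresholds$permutations,
              thresholds$seed)
  structure(stats::setNames(q$q, rownames(matrix$areas)),
            n_permutations = q$n_permutations, exhaustive = q$exhaustive)
}

perm_q <- function(X, idxA, idxB, p_obs, min_obs, B, seed) {
  n <- length(idxA) + length(idxB)
  nA <- length(idxA)
  cols <- c(idxA, idxB)
  testable <- !is.na(p_obs)
  q <- rep(NA_real_, length(p_obs))
  if (!any(testable))
    return(list(q = q, n_permutations = 0L, exhaustive = FALSE))
  Xt <- X[testable, cols, drop = FALSE]
  splits <- enumerate_label_splits(n, nA, B)
  exhaustive <- !is.null(splits)
  if (!exhaustive) {
    set.seed(seed)
    splits <- replicate(B, sample.int(n, nA))
  }
  B_used <- ncol(splits)
  null_p <- vector("list", B_used)
  all_idx <- seq_len(n)
  for (b in seq_len(B_used)) {
    pa <- splits[, b]
    pb <- setdiff(all_idx, pa)
    rp <- row_t_stats(Xt, pa, pb, min_obs)$p
    null_p[[b]] <- rp[!is.na(rp)]
  }
  null_sorted <- sort(unlist(null_p, use.names = FALSE))
  po <- p_obs[testable]
  obs_sorted <- sort(po)
  E <- findInterval(po, null_sorted) / B_used
  R <- findInterval(po, obs_sorted)
  qt <- pmin(pmax(E / R, 0), 1)
  # monotone nondecreasing in p: sweep from the largest p downward
  ord <- order(po, decreasing = TRUE)
  qt[ord] <- cummin(qt[ord])
  q[testable] <- qt
  list(q = q, n_permutations = B_used, exhaustive = exhaustive)
}

match_design <- function(matrix, design) {
  samp <- colnames(matrix$areas)
  miss <- setdiff(samp, design$sample_id)
  if (length(miss))
    stop("design: sample '", miss[1], "' of the matrix is not in the design")
  cohort <- design$cohort[match(samp, design$sample_id)]
  idxA <- which(cohort == "A"); idxB <- which(cohort == "B")
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop("design: each cohort needs >= 2 samples present in the matrix")
  list(A = idxA, B = idxB)
}

#' Differential abundance between cohorts
#'
#' Runs the per-group equal-variance t-test on a normalized matrix,
#' estimates q-values by label permutation, and applies the combined
#' p-and-fold-change filter. One record is returned per group (testable or
#' not); `significant` is `TRUE` iff the group is testable with
#' `p < p_de` and `fold >= fc_de`. Records are sorted by p (untestable
#' last). For the primary cohort comparison the matrix should be composed
#' under the `exclude_shared` policy.
#'
#' @param matrix a `normalized_matrix`.
#' @param design a `sample_design`.
#' @param thresholds an [analysis_thresholds()].
#' @return Data frame of differential records: group metadata, per-cohort
#'   observed counts and means, `log2fc` (mean of cohort B minus mean of
#'   cohort A), `fold` (`2^|log2fc|`), `direction`, `t_stat`, `p`, `q`,
#'   `testable`, `significant`.
#' @export
differential_abundance <- function(matrix, design,
                                   thresholds = analysis_thresholds()) {
  stopifnot(inherits(matrix, "protein_group_matrix"))
  if (!identical(matrix$scale, "log2"))
    stop("differential_abundance: expected a log2-scale (normalized) matrix")
  idx <- match_design(matrix, design)
  res <- row_t_stats(matrix$areas, idx$A, idx$B,
                     thresholds$min_obs_per_group)
  if (!any(res$testable))
    warning("differential_abundance: no testable groups")
  qv <- perm_q(matrix$areas, idx$A, idx$B, res$p,
               thresholds$min_obs_per_group, thresholds$permutations,
               thresholds$seed)
  log2fc <- res$mean_B - res$mean_A
  rec <- data.frame(matrix$groups,
                    n_A = res$n_A, n_B = res$n_B,
                    mean_A = res$mean_A, mean_B = res$mean_B,
                    log2fc = log2fc,
                    fold = 2^abs(log2fc),
                    direction = ifelse(is.na(log2fc) | log2fc == 0, "none",
                                       ifelse(log2fc > 0, "higher_in_B",
                                              "lower_in_B")),
                    t_stat = res$t_stat, p = res$p, q = qv$q,
                    testable = res$testable,
                    stringsAsFactors = FALSE)
  rec$mean_A[res$n_A == 0L] <- NA_real_
  rec$mean_B[res$n_B == 0L] <- NA_real_
  rec$significant <- rec$testable & !is.na(rec$p) &
    rec$p < thresholds$p_de & rec$fold >= thresholds$fc_de
  rec <- rec[order(rec$p, na.last = TRUE), ]
  rownames(rec) <- NULL
  attr(rec, "n_permutations") <- qv$n_permutations
  attr(rec, "exhaustive") <- qv$exhaustive
  rec
}

#' Call isoform-discordant ("putative alternative splicing") events
#'
#' For each multi-isoform family represented in the records (which must
#' come from an `include_shared` composition so isoform-common groups are
#' present), contrasts the family's isoform-specific protein groups
#' against its isoform-common (shared-among-isoforms) group:
#'
#' * `SPLICING_DISCORDANT` — some testable isoform-specific group passes
#'   the isoform filter (`p < p_iso` and `fold >= fc_iso`) while the
#'   common group is testable and does not itself pass the abundance
#'   filter (`p < p_de` and `fold >= fc_de`): specific signal moves,
#'   total protein does not — the protein-level signature of an
#'   isoform-usage change.
#' * `ABUNDANCE_CONCORDANT` — the common group passes the abundance
#'   filter and some testable specific group passes it in the same
#'   direction: a whole-protein abundance shift.
#' * `UNTESTABLE` — no testable specific group, no testable common group,
#'   or neither pattern holds.
#'
#' @param records differential records from [differential_abundance()] run
#'   on an `include_shared` composition.
#' @param catalog an [isoform_catalog()].
#' @param thresholds an [analysis_thresholds()].
#' @return Data frame of splicing calls, one row per multi-isoform family,
#'   with the common group's and the best specific group's statistics.
#' @export
call_isoform_discordance <- function(records, catalog,
                                     thresholds = analysis_thresholds()) {
  stopifnot(is.data.frame(records), inherits(catalog, "isoform_catalog"),
            all(c("family", "pclass", "p", "fold", "testable",
                  "direction", "group_id") %in% names(records)))
  multi <- names(catalog$families)[lengths(catalog$families) >= 2L]
  fams <- intersect(multi, unique(records$family))
  calls <- lapply(fams, function(f) {
    fr <- records[records$family == f, , drop = FALSE]
    specs <- fr[fr$pclass == "ISOFORM_SPECIFIC", , drop = FALSE]
    common <- fr[fr$pclass == "SHARED_ISOFORMS", , drop = FALSE]
    st <- specs[specs$testable, , drop = FALSE]
    common_ok <- nrow(common) >= 1L && isTRUE(common$testable[1])
    verdict <- "UNTESTABLE"
    best <- NULL
    if (nrow(st) && common_ok) {
      common_de <- common$p[1] < thresholds$p_de &&
        common$fold[1] >= thresholds$fc_de
      hit <- st$p < thresholds$p_iso & st$fold >= thresholds$fc_iso
      conc <- st$p < thresholds$p_de & st$fold >= thresholds$fc_de &
        st$direction == common$direction[1]
      if (any(hit) && !common_de) {
        verdict <- "SPLICING_DISCORDANT"
        best <- st[hit, , drop = FALSE]
      } else if (common_de && any(conc)) {
        verdict <- "ABUNDANCE_CONCORDANT"
        best <- st[conc, , drop = FALSE]
      }
    }
    if (is.null(best)) best <- st
    best <- if (nrow(best)) best[which.min(best$p), , drop = FALSE] else NULL
    data.frame(family = f,
               n_isoforms = length(catalog$families[[f]]),
               n_specific_groups = nrow(specs),
               n_specific_testable = nrow(st),
               common_present = nrow(common) >= 1L,
               common_p = if (nrow(common)) common$p[1] else NA_real_,
               common_q = if (nrow(common)) common$q[1] else NA_real_,
               common_fold = if (nrow(common)) common$fold[1] else NA_real_,
               common_log2fc = if (nrow(common)) common$log2fc[1] else NA_real_,
               specific_group = if (!is.null(best)) best$group_id else NA_character_,
               specific_p = if (!is.null(best)) best$p else NA_real_,
               specific_q = if (!is.null(best)) best$q else NA_real_,
               specific_fold = if (!is.null(best)) best$fold else NA_real_,
               specific_log2fc = if (!is.null(best)) best$log2fc else NA_real_,
               specific_direction = if (!is.null(best)) best$direction else NA_character_,
               verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(family = character(0), n_isoforms = integer(0),
                      n_specific_groups = integer(0),
                      n_specific_testable = integer(0),
                      common_present = logical(0), common_p = numeric(0),
                      common_q = numeric(0), common_fold = numeric(0),
                      common_log2fc = numeric(0),
                      specific_group = character(0), specific_p = numeric(0),
                      specific_q = numeric(0), specific_fold = numeric(0),
                      specific_log2fc = numeric(0),
                      specific_direction = character(0),
                      verdict = character(0), stringsAsFactors = FALSE)
  out[order(out$specific_p, na.last = TRUE), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Principal component QC of a normalized matrix
#'
#' Centered PCA of the samples over complete features (groups with no
#' missing value across samples). Reports sample scores,
#' explained-variance fractions, and a cohort separation score on PC1:
#' the absolute difference of cohort mean scores in units of the pooled
#' within-cohort standard deviation.
#'
#' @param matrix a `normalized_matrix`.
#' @param design a `sample_design`.
#' @return List with `scores` (data frame: sample_id, cohort, PC columns),
#'   `explained_variance` (fractions), `separation` (PC1 cohort
#'   separation), `n_features` (complete features used).
#' @export
pca_qc <- function(matrix, design) {
  stopifnot(inherits(matrix, "protein_group_matrix"),
            inherits(design, "sample_design"))
  idx <- match_design(matrix, design)
  X <- matrix$areas[stats::complete.cases(matrix$areas), , drop = FALSE]
  if (nrow(X) < 2L)
    stop("pca_qc: insufficient data (< 2 complete features)")
  if (sum(apply(X, 1L, stats::var) > 0) < 2L)
    stop("pca_qc: insufficient data (no variance across samples)")
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  cohort <- rep("B", ncol(X)); cohort[idx$A] <- "A"
  pc1 <- pc$x[, 1]
  mA <- mean(pc1[idx$A]); mB <- mean(pc1[idx$B])
  vA <- stats::var(pc1[idx$A]); vB <- stats::var(pc1[idx$B])
  pooled_sd <- sqrt(((length(idx$A) - 1) * vA + (length(idx$B) - 1) * vB) /
                      (length(idx$A) + length(idx$B) - 2))
  sep <- if (pooled_sd > 0) abs(mA - mB) / pooled_sd else Inf
  scores <- data.frame(sample_id = colnames(X), cohort = cohort,
                       pc$x, stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  list(scores = scores, explained_variance = ev, separation = sep,
       n_features = nrow(X))
}

#' Pooled two-proportion comparison
#'
#' Compares two pooled counts (e.g. defective sperm heads over total sperm
#' heads counted) with a 2x2 chi-square test on 1 degree of freedom,
#' without continuity correction by default. Percentages are rounded to
#' the nearest integer for display.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param correct logical; apply Yates' continuity correction (default
#'   `FALSE`).
#' @return A `proportion_comparison`: list with `k1`, `n1`, `k2`, `n2`,
#'   `p1`, `p2`, `diff` (`p2 - p1`), `chi2`, `p`.
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  for (v in list(k1, n1, k2, n2))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("compare_proportions: counts must be single nonnegative integers")
  if (k1 > n1 || k2 > n2)
    stop("compare_proportions: successes exceed trials (k > n)")
  if (n1 < 1L || n2 < 1L) stop("compare_proportions: n must be >= 1")
  p1 <- k1 / n1; p2 <- k2 / n2
  if (p1 == p2) {
    # identical proportions include the degenerate all-zero/all-one margins
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(
      matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE),
      correct = correct))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 p1 = p1, p2 = p2, diff = p2 - p1, chi2 = chi2, p = p),
            class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("group 1: %d/%d = %d%%\n", x$k1, x$n1, round(100 * x$p1)))
  cat(sprintf("group 2: %d/%d = %d%%\n", x$k2, x$n2, round(100 * x$p2)))
  cat(sprintf("difference %.4f; chi-square (1 df, %s) = %.4g, p = %.3g\n",
              x$diff,
              "no continuity correction", x$chi2, x$p))
  invisible(x)
}
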