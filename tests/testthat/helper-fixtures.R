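# Fixtures are built in code: tiny TSV/FASTA files under tempdir() and
# small constructed objects shared across test files.

# deterministic valid amino-acid "sequence" for an integer id, ending in K
pepseq <- function(i, prefix = "T") {
  enc <- chartr("0123456789", "ACDEFGHILM", as.character(i))
  paste0(prefix, "PEPT", enc, "K")
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# area table from a numeric matrix (NA written as 0, the export convention)
make_area_table <- function(mat, sequences, samples = colnames(mat),
                            zero_as_missing = TRUE) {
  stopifnot(nrow(mat) == length(sequences))
  vals <- mat
  vals[is.na(vals)] <- 0
  rows <- apply(vals, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = "\t"))
  lines <- c(paste(c("sequence", "modification", samples), collapse = "\t"),
             paste(sequences, "", rows, sep = "\t"))
  read_peptide_area_table(write_tsv_lines(lines),
                          zero_as_missing = zero_as_missing)
}

# peptide map from a named list: peptide sequence -> accession vector
make_map <- function(sets) {
  lines <- c("sequence\tmodification\taccessions",
             vapply(names(sets), function(s)
               paste(s, "", paste(sets[[s]], collapse = ";"), sep = "\t"), ""))
  read_distinct_peptide_summary(write_tsv_lines(lines))
}

make_design <- function(n_A = 3, n_B = 3) {
  sample_design(c(sprintf("A%02d", seq_len(n_A)),
                  sprintf("B%02d", seq_len(n_B))),
                rep(c("A", "B"), c(n_A, n_B)))
}

# catalog from a named list: family -> number of isoforms
make_catalog <- function(fams) {
  acc <- unlist(lapply(names(fams), function(f) {
    k <- fams[[f]]
    if (k == 1) f else sprintf("%s-%d", f, seq_len(k))
  }))
  isoform_catalog(acc)
}

# Independent classification oracle: enumerates catalog families directly
# and counts membership, without reusing the package's decision path.
oracle_classify <- function(accessions, catalog) {
  hit_fams <- Filter(function(f) any(accessions %in% catalog$families[[f]]),
                     names(catalog$families))
  if (length(hit_fams) != 1L) return("SHARED_MULTI")
  members <- catalog$families[[hit_fams]]
  n_in <- sum(members %in% accessions)
  if (length(members) == 1L) "UNIQUE"
  else if (n_in == length(members)) "SHARED_ISOFORMS"
  else "ISOFORM_SPECIFIC"
}

# random (catalog, accession set) pair for property tests
random_classify_case <- function() {
  n_fam <- sample(1:4, 1)
  sizes <- sample(1:3, n_fam, replace = TRUE)
  fams <- stats::setNames(as.list(sizes), sprintf("F%d", seq_len(n_fam)))
  catalog <- make_catalog(fams)
  universe <- unname(unlist(catalog$families))
  accs <- sample(universe, sample(seq_along(universe), 1))
  list(catalog = catalog, accessions = unique(accs))
}

# one protein group per row: distinct singleton accession per peptide
compose_simple <- function(mat) {
  n <- nrow(mat)
  seqs <- vapply(seq_len(n), pepseq, "")
  cat <- make_catalog(stats::setNames(as.list(rep(1, n)),
                                      sprintf("P%03d", seq_len(n))))
  map <- make_map(stats::setNames(as.list(sprintf("P%03d", seq_len(n))), seqs))
  compose_protein_groups(make_area_table(mat, seqs), map, cat)
}

# differential-style record rows built by hand for the discordance caller
fake_record <- function(family, pclass, p, log2fc, testable = TRUE,
                        group_id = paste0(family, "-", pclass), q = p) {
  data.frame(group_id = group_id, accessions = group_id, family = family,
             pclass = pclass, n_peptides = 2L, n_A = 5L, n_B = 5L,
             mean_A = 0, mean_B = log2fc, log2fc = log2fc,
             fold = 2^abs(log2fc),
             direction = if (log2fc > 0) "higher_in_B" else
               if (log2fc < 0) "lower_in_B" else "none",
             t_stat = 0, p = p, q = q, testable = testable,
             significant = FALSE, stringsAsFactors = FALSE)
}

# Independent q-value oracle: enumerate every label split with t.test and
# apply the definition (average null exceedance per permutation over
# observed exceedance, clipped, monotone) with plain loops.
oracle_perm_q <- function(X, idxA, idxB) {
  n <- ncol(X); nA <- length(idxA)
  splits <- utils::combn(n, nA)
  p_obs <- apply(X, 1, function(r)
    stats::t.test(r[idxA], r[idxB], var.equal = TRUE)$p.value)
  null_p <- c()
  for (b in seq_len(ncol(splits))) {
    pa <- splits[, b]; pb <- setdiff(seq_len(n), pa)
    null_p <- c(null_p, apply(X, 1, function(r)
      stats::t.test(r[pa], r[pb], var.equal = TRUE)$p.value))
  }
  q <- vapply(p_obs, function(p) {
    E <- sum(null_p <= p) / ncol(splits)
    R <- sum(p_obs <= p)
    min(max(E / R, 0), 1)
  }, 0)
  ord <- order(p_obs, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  q
}
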