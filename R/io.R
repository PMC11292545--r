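# Readers/writers for the pipeline's tab-separated files. All files are
# UTF-8, tab-separated, header mandatory, decimal point ".".

pep_key <- function(sequence, modification) {
  paste(sequence, modification, sep = "\x1f")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequences <- function(sequence, context = "peptide") {
  if (any(!nzchar(sequence)))
    stop(sprintf("%s: empty sequence at row %d", context,
                 which(!nzchar(sequence))[1]))
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), sequence)
  if (any(bad))
    stop(sprintf("%s: non-standard residue in sequence '%s' (row %d)",
                 context, sequence[which(bad)[1]], which(bad)[1]))
  invisible(TRUE)
}

new_peptide_area_table <- function(peptides, samples, areas) {
  stopifnot(is.data.frame(peptides),
            all(c("sequence", "modification") %in% names(peptides)),
            is.matrix(areas),
            nrow(areas) == nrow(peptides),
            ncol(areas) == length(samples))
  keys <- pep_key(peptides$sequence, peptides$modification)
  if (anyDuplicated(keys))
    stop("peptide area table: duplicate peptide key (sequence='",
         peptides$sequence[which(duplicated(keys))[1]], "', modification='",
         peptides$modification[which(duplicated(keys))[1]], "')")
  if (anyDuplicated(samples) || any(!nzchar(samples)))
    stop("peptide area table: sample ids must be unique and non-empty")
  if (any(areas < 0, na.rm = TRUE))
    stop("peptide area table: negative area at row ",
         which(apply(areas < 0, 1, any, na.rm = TRUE))[1])
  check_sequences(peptides$sequence, "peptide area table")
  rownames(areas) <- keys
  colnames(areas) <- samples
  structure(list(peptides = peptides, samples = as.character(samples),
                 areas = areas),
            class = "peptide_area_table")
}

#' Read a peptide-by-sample area export
#'
#' Reads the peptide-level quantification table of a DIA/SWATH experiment:
#' a TSV whose first two columns are `sequence` and `modification`
#' (modification may be empty) and whose remaining columns are samples,
#' with cells holding summed ion areas.
#'
#' Non-detections in SWATH exports are conventionally encoded as 0; by
#' default zeros (and blank cells) are mapped to missing values, since
#' treating structural zeros as measurements biases group means downstream.
#'
#' @param path path to the TSV file.
#' @param zero_as_missing logical; map cells equal to 0 to missing
#'   (default `TRUE`).
#' @return A `peptide_area_table`: list with `peptides` (data frame of
#'   sequence and modification), `samples`, and `areas` (peptide x sample
#'   numeric matrix with `NA` for missing).
#' @export
read_peptide_area_table <- function(path, zero_as_missing = TRUE) {
  if (!file.exists(path)) stop("peptide area table: no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  nm <- names(raw)
  if (length(nm) < 3L)
    stop("peptide area table: header must have sequence, modification and ",
         "at least one sample column")
  if (tolower(nm[1]) != "sequence")
    stop("peptide area table: malformed header; first column is '", nm[1],
         "', expected 'sequence'")
  if (tolower(nm[2]) != "modification")
    stop("peptide area table: malformed header; second column is '", nm[2],
         "', expected 'modification'")
  peptides <- data.frame(sequence = toupper(trimws(raw[[1]])),
                         modification = ifelse(is.na(raw[[2]]), "",
                                               trimws(raw[[2]])),
                         stringsAsFactors = FALSE)
  samples <- nm[-(1:2)]
  areas <- matrix(NA_real_, nrow(raw), length(samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 2L]]))
    bad <- !is.na(raw[[j + 2L]]) & is.na(v)
    if (any(bad))
      stop("peptide area table: non-numeric area '", raw[[j + 2L]][bad][1],
           "' in column '", samples[j], "', row ", which(bad)[1])
    areas[, j] <- v
  }
  neg <- which(apply(areas, 1L, function(r) any(r < 0, na.rm = TRUE)))
  if (length(neg))
    stop("peptide area table: negative area at row ", neg[1])
  if (zero_as_missing) areas[!is.na(areas) & areas == 0] <- NA_real_
  new_peptide_area_table(peptides, samples, areas)
}

#' Write a peptide area table
#'
#' Inverse of [read_peptide_area_table()]; missing values are written as 0,
#' matching the zero-as-missing convention of SWATH exports.
#'
#' @param x a `peptide_area_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_area_table <- function(x, path) {
  stopifnot(inherits(x, "peptide_area_table"))
  areas <- x$areas
  areas[is.na(areas)] <- 0
  df <- data.frame(sequence = x$peptides$sequence,
                   modification = x$peptides$modification,
                   as.data.frame(areas, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.peptide_area_table <- function(x, ...) {
  cat(sprintf("Peptide area table: %d peptides x %d samples (%.1f%% missing)\n",
              nrow(x$areas), ncol(x$areas), 100 * mean(is.na(x$areas))))
  invisible(x)
}

new_peptide_protein_map <- function(sequence, modification, accessions) {
  stopifnot(length(sequence) == length(modification),
            length(sequence) == length(accessions),
            is.list(accessions))
  n_acc <- lengths(accessions)
  if (any(n_acc == 0L))
    stop("peptide map: peptide '", sequence[which(n_acc == 0L)[1]],
         "' maps to no accession")
  accessions <- lapply(accessions, function(a) sort(unique(as.character(a))))
  keys <- pep_key(sequence, modification)
  if (anyDuplicated(keys))
    stop("peptide map: duplicate peptide key '",
         sequence[which(duplicated(keys))[1]], "'")
  structure(list(sequence = as.character(sequence),
                 modification = as.character(modification),
                 accessions = accessions,
                 keys = keys),
            class = "peptide_protein_map")
}

#' Read a distinct peptide summary (peptide-to-protein-group map)
#'
#' Reads the search-engine table listing, for each identified peptide, the
#' set of protein accessions it matches (its protein group). Expected TSV
#' columns: `sequence`, `modification`, `accessions` with the accession
#' list ";"-delimited (surrounding whitespace is stripped).
#'
#' Rows repeating a peptide with an identical accession set collapse to one
#' entry; repeating it with a conflicting set is an error (no silent union).
#'
#' @param path path to the TSV file.
#' @return A `peptide_protein_map`: parallel vectors `sequence`,
#'   `modification` and a list `accessions` of sorted accession sets.
#' @export
read_distinct_peptide_summary <- function(path) {
  if (!file.exists(path)) stop("peptide map: no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  nm <- tolower(names(raw))
  need <- c("sequence", "modification", "accessions")
  if (length(nm) < 3L || !all(nm[1:3] == need))
    stop("peptide map: malformed header; expected columns ",
         paste(need, collapse = ", "), ", got ",
         paste(names(raw), collapse = ", "))
  seqs <- toupper(trimws(raw[[1]]))
  mods <- ifelse(is.na(raw[[2]]), "", trimws(raw[[2]]))
  accf <- raw[[3]]
  if (any(is.na(accf) | !nzchar(trimws(accf))))
    stop("peptide map: empty accession field at row ",
         which(is.na(accf) | !nzchar(trimws(accf)))[1])
  acc <- lapply(strsplit(accf, ";", fixed = TRUE), function(a) {
    a <- trimws(a)
    sort(unique(a[nzchar(a)]))
  })
  keys <- pep_key(seqs, mods)
  if (anyDuplicated(keys)) {
    keep <- !duplicated(keys)
    for (k in unique(keys[duplicated(keys)])) {
      sets <- acc[keys == k]
      canon <- vapply(sets, paste, "", collapse = ";")
      if (length(unique(canon)) > 1L)
        stop("peptide map: peptide '", seqs[keys == k][1],
             "' listed with conflicting accession sets (",
             paste(unique(canon), collapse = " vs "), ")")
    }
    seqs <- seqs[keep]; mods <- mods[keep]; acc <- acc[keep]
  }
  check_sequences(seqs, "peptide map")
  new_peptide_protein_map(seqs, mods, acc)
}

#' Write a peptide-to-protein-group map
#'
#' Emits the same dialect [read_distinct_peptide_summary()] reads.
#'
#' @param map a `peptide_protein_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_map <- function(map, path) {
  stopifnot(inherits(map, "peptide_protein_map"))
  df <- data.frame(sequence = map$sequence,
                   modification = map$modification,
                   accessions = vapply(map$accessions, paste, "",
                                       collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.peptide_protein_map <- function(x, ...) {
  cat(sprintf("Peptide-protein map: %d peptides, %d distinct accessions\n",
              length(x$sequence), length(unique(unlist(x$accessions)))))
  invisible(x)
}

# Cohort labels accepted in design files, mapped onto the canonical A/B.
default_cohort_aliases <- function() {
  c(a = "A", fertile = "A", control = "A",
    b = "B", infertile = "B", case = "B")
}

#' Read a sample design table
#'
#' Two-column TSV `sample_id`, `cohort`. Cohort labels are mapped through
#' an alias table (by default fertile/control -> A, infertile/case -> B);
#' anything unmapped is an error. Each cohort must contain at least two
#' samples.
#'
#' @param path path to the TSV file.
#' @param aliases named character vector mapping lower-case labels to
#'   "A"/"B"; defaults accept A/B, fertile/infertile and control/case.
#' @return A `sample_design` data frame with columns `sample_id`, `cohort`.
#' @export
read_design <- function(path, aliases = default_cohort_aliases()) {
  if (!file.exists(path)) stop("design: no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  nm <- tolower(names(raw))
  if (length(nm) < 2L || nm[1] != "sample_id" || nm[2] != "cohort")
    stop("design: malformed header; expected columns sample_id, cohort")
  sample_design(trimws(raw[[1]]), trimws(raw[[2]]), aliases = aliases)
}

#' Construct a sample design
#'
#' @param sample_id character vector of unique, non-empty sample ids.
#' @param cohort character vector of cohort labels, one per sample.
#' @param aliases alias map as in [read_design()].
#' @return A `sample_design` data frame.
#' @export
sample_design <- function(sample_id, cohort,
                          aliases = default_cohort_aliases()) {
  stopifnot(length(sample_id) == length(cohort))
  if (any(!nzchar(sample_id)) || anyDuplicated(sample_id))
    stop("design: sample ids must be unique and non-empty")
  mapped <- unname(aliases[tolower(trimws(cohort))])
  bad <- is.na(mapped)
  if (any(bad))
    stop("design: unknown cohort label '", cohort[bad][1], "' for sample '",
         sample_id[bad][1], "'")
  tab <- table(factor(mapped, levels = c("A", "B")))
  if (any(tab < 2L))
    stop("design: each cohort needs >= 2 samples (A: ", tab[["A"]],
         ", B: ", tab[["B"]], ")")
  structure(data.frame(sample_id = as.character(sample_id),
                       cohort = mapped, stringsAsFactors = FALSE),
            class = c("sample_design", "data.frame"))
}

#' Write a sample design table
#'
#' @param design a `sample_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a results table
#'
#' Writes any per-group results data frame (differential records, splicing
#' calls, PCA scores) as a TSV with a stable column order and full numeric
#' precision, so that [read_results()] round-trips the content.
#'
#' @param records a data frame (possibly with zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) NA_character_ else sprintf("%.15g", v), "")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path path to the TSV file.
#' @return A data frame with column types restored by standard heuristics.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results: no such file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = "NA", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read a run configuration file
#'
#' A flat YAML document with optional blocks `thresholds` (fields of
#' [analysis_thresholds()]), `io` (e.g. `zero_as_missing`), `simulate`
#' (fields of [sim_config()]) and `inputs` (paths `areas`, `peptide_map`,
#' `design`, optional `fasta`).
#'
#' @param path path to a YAML file.
#' @return A named list with a validated `thresholds` element.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config: expected a YAML mapping at top level")
  cfg$thresholds <- as_analysis_thresholds(cfg$thresholds)
  cfg
}
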