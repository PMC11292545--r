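# In-silico tryptic digestion: re-creates the peptide-to-protein-group
# substrate normally exported by a database search, from an isoform-aware
# FASTA.

#' Digestion parameters
#'
#' @param enzyme only `"trypsin"` is supported: cleavage C-terminal to K or
#'   R except when the next residue is P; fully tryptic peptides only.
#' @param missed_cleavages maximum number of internal cleavage sites left
#'   uncut (0..5, default 2).
#' @param min_len,max_len peptide length window retained (defaults 6 and
#'   50, the typical detectable range for bottom-up MS).
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = "trypsin", missed_cleavages = 2L,
                          min_len = 6L, max_len = 50L) {
  enzyme <- match.arg(enzyme)
  missed_cleavages <- as.integer(missed_cleavages)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (missed_cleavages < 0L || missed_cleavages > 5L)
    stop("digest: missed_cleavages must be in 0..5")
  if (min_len > max_len) stop("digest: min_len must be <= max_len")
  structure(list(enzyme = enzyme, missed_cleavages = missed_cleavages,
                 min_len = min_len, max_len = max_len),
            class = "digest_params")
}

# 0-missed-cleavage fragments; their concatenation reconstructs the input.
tryptic_fragments <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  substring(sequence, starts, ends)
}

#' Tryptic digestion of one protein sequence
#'
#' Cleaves C-terminal to K or R except before P, then forms all fully
#' tryptic peptides with up to `missed_cleavages` internal sites, filtered
#' to the configured length window. Peptides generated more than once from
#' one protein are returned once, with their multiplicity in the
#' `"multiplicity"` attribute.
#'
#' @param sequence amino-acid sequence (20 standard residues).
#' @param params a [digest_params()] object.
#' @return Character vector of unique peptides (order of first occurrence),
#'   with an integer `"multiplicity"` attribute.
#' @export
digest_sequence <- function(sequence, params = digest_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_sequences(sequence, "digest")
  frags <- tryptic_fragments(sequence)
  nf <- length(frags)
  peps <- character(0)
  for (mc in 0:min(params$missed_cleavages, nf - 1L)) {
    i <- seq_len(nf - mc)
    peps <- c(peps, vapply(i, function(k)
      paste(frags[k:(k + mc)], collapse = ""), ""))
  }
  len <- nchar(peps)
  peps <- peps[len >= params$min_len & len <= params$max_len]
  if (!length(peps))
    return(structure(character(0), multiplicity = integer(0)))
  tab <- table(factor(peps, levels = unique(peps)))
  structure(names(tab), multiplicity = as.integer(tab))
}

#' Build an isoform catalog and peptide map from a FASTA database
#'
#' Digests every entry of an isoform-aware FASTA and inverts the digest:
#' each distinct peptide sequence is assigned the set of accessions whose
#' digest contains it. Accessions are grouped into isoform families by
#' stripping a terminal "-<integer>" suffix (UniProt isoform naming);
#' accessions without the suffix are their own canonical.
#'
#' @param fasta path to a FASTA file whose header first token is the
#'   accession.
#' @param params a [digest_params()] object.
#' @return A list with `catalog` (an `isoform_catalog`) and `map` (a
#'   `peptide_protein_map` keyed by sequence, empty modification).
#' @export
build_peptide_map_from_fasta <- function(fasta, params = digest_params()) {
  seqs <- Biostrings::readAAStringSet(fasta)
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(acc))
    stop("fasta: duplicate accession '", acc[duplicated(acc)][1], "'")
  sequences <- as.character(seqs)
  names(sequences) <- acc
  peptide_map_from_sequences(sequences, params)
}

# Digest a named set of sequences and invert to peptide -> accession set.
peptide_map_from_sequences <- function(sequences, params = digest_params()) {
  acc <- names(sequences)
  catalog <- isoform_catalog(acc, sequences)
  digests <- lapply(sequences, digest_sequence, params = params)
  pep <- unlist(digests, use.names = FALSE)
  who <- rep(acc, lengths(digests))
  sets <- split(who, pep)
  peptides <- names(sets)
  list(catalog = catalog,
       map = new_peptide_protein_map(peptides,
                                     rep("", length(peptides)),
                                     unname(sets)))
}

#' Write an isoform catalog's sequences as FASTA
#'
#' @param catalog an `isoform_catalog` carrying sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  if (is.null(catalog$sequences))
    stop("catalog carries no sequences to write")
  x <- Biostrings::AAStringSet(catalog$sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
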