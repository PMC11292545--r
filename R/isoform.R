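# The core procedure: classify every peptide by protein/isoform sharing
# and compose protein-group areas by summation over peptides with
# identical protein-group membership.

#' Canonical family of an accession
#'
#' Strips one terminal "-<integer>" isoform suffix if present (UniProt
#' isoform naming, e.g. "P68363-2" belongs to family "P68363"); otherwise
#' the accession is its own canonical.
#'
#' @param accession character vector of accessions.
#' @return Character vector of canonical accessions.
#' @export
family_of <- function(accession) {
  stopifnot(is.character(accession), all(nzchar(accession)))
  sub("-[0-9]+$", "", accession)
}

#' Isoform catalog
#'
#' Groups an accession universe into isoform families by canonical root.
#'
#' @param accessions character vector of all accessions in the database.
#' @param sequences optional named character vector of amino-acid
#'   sequences (names = accessions).
#' @return An `isoform_catalog`: list with `families` (named list,
#'   canonical -> sorted isoform accessions), `accession_family` (named
#'   lookup), and optional `sequences`.
#' @export
isoform_catalog <- function(accessions, sequences = NULL) {
  accessions <- as.character(accessions)
  if (any(!nzchar(accessions))) stop("catalog: empty accession")
  if (anyDuplicated(accessions))
    stop("catalog: duplicate accession '",
         accessions[duplicated(accessions)][1], "'")
  fam <- family_of(accessions)
  families <- lapply(split(accessions, fam), function(a) sort(a))
  accession_family <- stats::setNames(fam, accessions)
  if (!is.null(sequences))
    stopifnot(all(accessions %in% names(sequences)))
  structure(list(families = families, accession_family = accession_family,
                 sequences = sequences),
            class = "isoform_catalog")
}

#' @export
print.isoform_catalog <- function(x, ...) {
  sz <- lengths(x$families)
  cat(sprintf("Isoform catalog: %d accessions in %d families (%d multi-isoform)\n",
              length(x$accession_family), length(x$families), sum(sz > 1L)))
  invisible(x)
}

PEPTIDE_CLASSES <- c("UNIQUE", "ISOFORM_SPECIFIC", "SHARED_ISOFORMS",
                     "SHARED_MULTI")

#' Classify a peptide by its protein/isoform sharing
#'
#' Given the accession set a peptide matches, returns exactly one of:
#' * `UNIQUE` — all evidence points to a single-isoform family;
#' * `ISOFORM_SPECIFIC` — a proper subset of one family's isoforms
#'   (the evidence unit for splicing at the protein level);
#' * `SHARED_ISOFORMS` — all cataloged isoforms of one multi-isoform
#'   family (reports total protein abundance irrespective of splicing);
#' * `SHARED_MULTI` — accessions spanning more than one family.
#'
#' @param accessions character vector (a set) of accessions matched by one
#'   peptide; must be non-empty and present in the catalog.
#' @param catalog an [isoform_catalog()].
#' @return Length-1 character, one of the four classes.
#' @export
classify_peptide <- function(accessions, catalog) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  accessions <- unique(as.character(accessions))
  if (!length(accessions)) stop("classify: empty accession set")
  fam <- catalog$accession_family[accessions]
  if (anyNA(fam))
    stop("classify: unknown accession '", accessions[is.na(fam)][1], "'")
  if (length(unique(fam)) > 1L) return("SHARED_MULTI")
  members <- catalog$families[[fam[[1]]]]
  if (length(members) == 1L) return("UNIQUE")
  if (setequal(accessions, members)) return("SHARED_ISOFORMS")
  "ISOFORM_SPECIFIC"
}

#' Classify every peptide of a map
#'
#' @param map a `peptide_protein_map`.
#' @param catalog an [isoform_catalog()].
#' @return Character vector of classes, parallel to `map$sequence`.
#' @export
classify_peptides <- function(map, catalog) {
  stopifnot(inherits(map, "peptide_protein_map"))
  vapply(map$accessions, classify_peptide, "", catalog = catalog)
}

#' Compose protein-group areas from peptide areas
#'
#' Matches each peptide of the area table against the peptide-to-protein
#' map, groups peptides with identical accession sets, and sums member
#' peptide areas per sample over the observed (non-missing) members; a
#' group is missing in a sample only when all its members are missing
#' there. Group keys carry the peptide class of their accession set.
#'
#' Under `policy = "exclude_shared"`, peptides classified `SHARED_MULTI`
#' (shared across gene-level families) are dropped before grouping — the
#' policy used for the primary cohort comparison. Peptides shared only
#' among isoforms of one family are retained under both policies, since
#' the isoform analysis contrasts isoform-common against isoform-specific
#' signal within a family. Under `policy = "include_shared"` every mapped
#' peptide is kept.
#'
#' Peptides absent from the map, or whose accession set is empty after
#' catalog filtering, are excluded and counted in the `"dropped"`
#' attribute (real exports contain contaminants and decoys), not an error.
#'
#' @param areas a `peptide_area_table`.
#' @param map a `peptide_protein_map`.
#' @param catalog an [isoform_catalog()].
#' @param policy `"exclude_shared"` or `"include_shared"`.
#' @return A `protein_group_matrix`: list with `groups` (data frame:
#'   `group_id`, `accessions`, `family`, `pclass`, `n_peptides`),
#'   `samples`, `areas` (group x sample matrix), `membership` (list of
#'   member peptide keys per group) and a `dropped` count summary.
#' @export
compose_protein_groups <- function(areas, map, catalog,
                                   policy = c("exclude_shared",
                                              "include_shared")) {
  stopifnot(inherits(areas, "peptide_area_table"),
            inherits(map, "peptide_protein_map"),
            inherits(catalog, "isoform_catalog"))
  policy <- match.arg(policy)

  tab_keys <- rownames(areas$areas)
  idx <- match(tab_keys, map$keys)
  unmapped <- is.na(idx)
  acc_sets <- vector("list", length(tab_keys))
  acc_sets[!unmapped] <- map$accessions[idx[!unmapped]]
  # drop accessions absent from the catalog (contaminants/decoys)
  known <- names(catalog$accession_family)
  acc_sets <- lapply(acc_sets, function(a)
    if (is.null(a)) NULL else a[a %in% known])
  unknown_only <- !unmapped & lengths(acc_sets) == 0L
  keep <- !unmapped & !unknown_only

  pclass <- rep(NA_character_, length(tab_keys))
  pclass[keep] <- vapply(acc_sets[keep], classify_peptide, "",
                         catalog = catalog)
  shared_dropped <- 0L
  if (policy == "exclude_shared") {
    drop_shared <- keep & pclass == "SHARED_MULTI"
    shared_dropped <- sum(drop_shared)
    keep <- keep & !drop_shared
  }
  if (!any(keep))
    stop("compose: no peptide of the area table is mappable under the ",
         "given map/catalog")

  group_id <- vapply(acc_sets, function(a)
    if (is.null(a) || !length(a)) NA_character_ else
      paste(sort(a), collapse = ";"), "")
  group_id[!keep] <- NA_character_
  gid <- sort(unique(group_id[keep]))
  gidx <- match(group_id, gid)

  nsamp <- length(areas$samples)
  X <- areas$areas
  obs <- !is.na(X)
  Xz <- ifelse(obs, X, 0)
  ag <- rowsum(Xz[keep, , drop = FALSE], gidx[keep], reorder = TRUE)
  no <- rowsum(obs[keep, , drop = FALSE] + 0L, gidx[keep], reorder = TRUE)
  ag[no == 0L] <- NA_real_
  rownames(ag) <- gid
  colnames(ag) <- areas$samples

  first <- match(gid, group_id)
  g_acc <- acc_sets[first]
  g_class <- pclass[first]
  g_family <- vapply(g_acc, function(a) {
    f <- unique(family_of(a))
    if (length(f) == 1L) f else "MULTI"
  }, "")
  membership <- split(tab_keys[keep], gid[gidx[keep]])
  membership <- membership[gid]
  groups <- data.frame(group_id = gid,
                       accessions = gid,
                       family = g_family,
                       pclass = g_class,
                       n_peptides = lengths(membership),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(groups = groups, samples = areas$samples, areas = ag,
                 membership = membership,
                 dropped = c(unmapped = sum(unmapped),
                             unknown_accession = sum(unknown_only),
                             shared_multi = shared_dropped)),
            class = "protein_group_matrix")
}

#' @export
print.protein_group_matrix <- function(x, ...) {
  cat(sprintf("Protein group matrix: %d groups x %d samples\n",
              nrow(x$areas), ncol(x$areas)))
  print(table(x$groups$pclass))
  d <- x$dropped
  if (any(d > 0))
    cat(sprintf("  dropped peptides: %d unmapped, %d unknown accession, %d shared-multi\n",
                d[["unmapped"]], d[["unknown_accession"]], d[["shared_multi"]]))
  invisible(x)
}

#' Dump a protein-group matrix as TSV
#'
#' Columns: `group_id`, `accessions`, `family`, `pclass`, `n_peptides`,
#' then one column per sample.
#'
#' @param pgm a `protein_group_matrix` (raw, log2 or normalized scale).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_group_matrix <- function(pgm, path) {
  stopifnot(inherits(pgm, "protein_group_matrix"))
  df <- cbind(pgm$groups,
              as.data.frame(pgm$areas, check.names = FALSE))
  write_results(df, path)
}
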