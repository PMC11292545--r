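# End-to-end orchestration: simulate or load inputs, map and classify
# peptides, compose protein groups, normalize, test both analysis
# branches, call isoform discordance, and write results plus a
# machine-readable run manifest.

pgm_subset <- function(pgm, keep) {
  pgm$groups <- pgm$groups[keep, , drop = FALSE]
  rownames(pgm$groups) <- NULL
  pgm$areas <- pgm$areas[keep, , drop = FALSE]
  pgm$membership <- pgm$membership[keep]
  pgm
}

#' Run the full analysis pipeline
#'
#' Executes both analysis branches from one composition/normalization
#' pass: peptides are composed into protein groups under the
#' `include_shared` policy, log2-transformed and median-centered once;
#' the primary differential-abundance branch then runs on the row subset
#' excluding cross-family shared (`SHARED_MULTI`) groups — equivalent to
#' an `exclude_shared` composition, since group values depend only on the
#' accession-set key — and the isoform branch runs on the full matrix,
#' followed by the splicing-discordance caller. PCA QC is computed on the
#' primary branch. Results, a log and a deterministic run manifest are
#' written to the output directory.
#'
#' @param config either a path to a YAML config file (see
#'   [read_run_config()]) or an equivalent named list, with blocks
#'   `simulate` (fields of [sim_config()]) or `inputs` (paths `areas`,
#'   `peptide_map`, `design`, optional `fasta`), plus optional
#'   `thresholds` and `io` (`zero_as_missing`).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return The run manifest (named list), invisibly. Result files:
#'   `differential_abundance.tsv`, `splicing_calls.tsv`,
#'   `pca_scores.tsv`, `manifest.yaml`, `run.log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  thresholds <- as_analysis_thresholds(config$thresholds)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir))
    stop("config: no output directory (set out_dir)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  zero_as_missing <- config$io$zero_as_missing %||% TRUE
  input_checksums <- list()

  if (!is.null(config$simulate)) {
    simc <- do.call(sim_config, config$simulate)
    ds <- generate_dataset(simc, out_dir = file.path(out_dir, "inputs"))
    areas <- ds$areas; map <- ds$map; catalog <- ds$catalog
    design <- ds$design
    input_checksums <- lapply(ds$paths, function(p)
      unname(tools::md5sum(p)))
    seed <- simc$seed
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    for (need in c("areas", "peptide_map", "design"))
      if (is.null(ins[[need]]) || !file.exists(ins[[need]]))
        stop("config: missing or unreadable input file '", need, "'")
    areas <- read_peptide_area_table(ins$areas,
                                     zero_as_missing = zero_as_missing)
    map <- read_distinct_peptide_summary(ins$peptide_map)
    design <- read_design(ins$design)
    if (!is.null(ins$fasta)) {
      catalog <- build_peptide_map_from_fasta(ins$fasta)$catalog
    } else {
      catalog <- isoform_catalog(sort(unique(unlist(map$accessions))))
    }
    input_checksums <- lapply(ins, function(p) unname(tools::md5sum(p)))
    seed <- thresholds$seed
  } else {
    stop("config: needs either a 'simulate' or an 'inputs' block")
  }

  pgm <- compose_protein_groups(areas, map, catalog,
                                policy = "include_shared")
  nm <- median_center(log2_transform(pgm))
  keep_de <- nm$groups$pclass != "SHARED_MULTI"
  nm_de <- pgm_subset(nm, keep_de)

  de <- differential_abundance(nm_de, design, thresholds)
  iso_records <- differential_abundance(nm, design, thresholds)
  calls <- call_isoform_discordance(iso_records, catalog, thresholds)
  pca <- pca_qc(nm_de, design)

  paths <- list(
    differential = file.path(out_dir, "differential_abundance.tsv"),
    isoform_records = file.path(out_dir, "isoform_records.tsv"),
    splicing = file.path(out_dir, "splicing_calls.tsv"),
    pca = file.path(out_dir, "pca_scores.tsv"),
    matrix = file.path(out_dir, "normalized_matrix.tsv"))
  write_results(de, paths$differential)
  write_results(iso_records, paths$isoform_records)
  write_results(calls, paths$splicing)
  write_results(pca$scores, paths$pca)
  write_protein_group_matrix(nm, paths$matrix)

  cfg_snapshot <- config
  cfg_snapshot$thresholds <- unclass(thresholds)
  cfg_path <- file.path(out_dir, "config_snapshot.yaml")
  yaml::write_yaml(cfg_snapshot, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))

  verdicts <- table(factor(calls$verdict,
                           levels = c("SPLICING_DISCORDANT",
                                      "ABUNDANCE_CONCORDANT", "UNTESTABLE")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("swathsplice")),
    seed = seed,
    config_hash = config_hash,
    input_checksums = input_checksums,
    counts = list(
      peptides_read = nrow(areas$areas),
      peptides_unmapped = unname(pgm$dropped[["unmapped"]]),
      peptides_unknown_accession = unname(pgm$dropped[["unknown_accession"]]),
      groups_composed = nrow(nm$areas),
      groups_primary_branch = nrow(nm_de$areas),
      shared_multi_groups_excluded = sum(!keep_de),
      families = length(catalog$families),
      testable = sum(de$testable),
      significant = sum(de$significant),
      splicing_discordant = unname(verdicts[["SPLICING_DISCORDANT"]]),
      abundance_concordant = unname(verdicts[["ABUNDANCE_CONCORDANT"]]),
      untestable_families = unname(verdicts[["UNTESTABLE"]])),
    pca = list(separation = pca$separation,
               pc1_explained = pca$explained_variance[1]),
    outputs = lapply(paths, basename))
  stopifnot(manifest$counts$groups_composed >= manifest$counts$testable,
            manifest$counts$testable >= manifest$counts$significant)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(c(sprintf("swathsplice run"),
               sprintf("config_hash: %s", config_hash),
               sprintf("seed: %d", seed),
               sprintf("peptides: %d (unmapped %d)",
                       manifest$counts$peptides_read,
                       manifest$counts$peptides_unmapped),
               sprintf("groups: %d (primary branch %d)",
                       manifest$counts$groups_composed,
                       manifest$counts$groups_primary_branch),
               sprintf("significant: %d of %d testable",
                       manifest$counts$significant,
                       manifest$counts$testable),
               sprintf("splicing discordant families: %d",
                       manifest$counts$splicing_discordant)),
             file.path(out_dir, "run.log"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
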