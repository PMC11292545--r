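# Truth-bearing synthetic data generator. Emulates the structure of a
# two-cohort DIA/SWATH experiment: ~1400 protein families with a minority
# carrying 2-3 isoforms, lognormal peptide areas around per-protein
# levels, per-sample loading offsets, missing values, planted
# whole-protein abundance shifts and planted isoform-usage shifts (common
# peptides essentially flat, isoform-specific peptides shifted).

#' Simulation configuration
#'
#' Defaults mirror the study design the generator emulates: 12 vs 11
#' samples, 1400 families with ~10% multi-isoform, 369 planted abundance
#' shifts of 2-8-fold, and 6 planted isoform-usage shifts of 6-50-fold.
#'
#' @param n_A,n_B cohort sizes (defaults 12 and 11).
#' @param n_families number of protein families (default 1400).
#' @param isoform_fraction fraction of families with 2-3 isoforms
#'   (default 0.1; the count is fixed at `round(n_families * fraction)`).
#' @param peptides_per_protein integer range (length-2) of peptides per
#'   protein (default `c(3, 8)`).
#' @param specific_peptide_rate fraction of a multi-isoform family's
#'   peptides that are isoform-specific (default 0.3; at least one
#'   specific peptide per isoform is always generated).
#' @param shared_multi_rate fraction of peptides additionally shared
#'   across families (default 0.02).
#' @param n_de number of planted whole-protein abundance-shift families
#'   (default 369).
#' @param de_fold_range fold-change range for planted abundance shifts
#'   (default `c(2, 8)`; magnitudes drawn log-uniformly, sign random).
#' @param n_splice number of planted isoform-usage-shift families
#'   (default 6).
#' @param splice_fold_range fold-change range for planted isoform shifts
#'   (default `c(6, 50)`).
#' @param cv lognormal coefficient of variation of the measurement noise
#'   (default 0.3).
#' @param missing_rate missing-at-random masking rate (default 0.1).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output files.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_A = 12L, n_B = 11L, n_families = 1400L,
                       isoform_fraction = 0.1,
                       peptides_per_protein = c(3L, 8L),
                       specific_peptide_rate = 0.3,
                       shared_multi_rate = 0.02,
                       n_de = 369L, de_fold_range = c(2, 8),
                       n_splice = 6L, splice_fold_range = c(6, 50),
                       cv = 0.3, missing_rate = 0.1, seed = 1L) {
  cfg <- list(n_A = as.integer(n_A), n_B = as.integer(n_B),
              n_families = as.integer(n_families),
              isoform_fraction = isoform_fraction,
              peptides_per_protein = as.integer(peptides_per_protein),
              specific_peptide_rate = specific_peptide_rate,
              shared_multi_rate = shared_multi_rate,
              n_de = as.integer(n_de), de_fold_range = as.numeric(de_fold_range),
              n_splice = as.integer(n_splice),
              splice_fold_range = as.numeric(splice_fold_range),
              cv = cv, missing_rate = missing_rate, seed = as.integer(seed))
  if (cfg$n_A < 2L || cfg$n_B < 2L)
    stop("sim config: each cohort needs >= 2 samples")
  rates <- c(cfg$isoform_fraction, cfg$specific_peptide_rate,
             cfg$shared_multi_rate, cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("sim config: rates must lie in [0, 1]")
  if (length(cfg$peptides_per_protein) != 2L ||
      cfg$peptides_per_protein[1] > cfg$peptides_per_protein[2] ||
      cfg$peptides_per_protein[1] < 1L)
    stop("sim config: peptides_per_protein must be an increasing range >= 1")
  if (cfg$n_de + cfg$n_splice > cfg$n_families)
    stop("sim config: n_de + n_splice exceeds n_families")
  if (any(cfg$de_fold_range < 1) || any(cfg$splice_fold_range < 1) ||
      diff(cfg$de_fold_range) < 0 || diff(cfg$splice_fold_range) < 0)
    stop("sim config: fold ranges must be increasing and >= 1")
  n_multi <- round(cfg$n_families * cfg$isoform_fraction)
  if (cfg$isoform_fraction == 0 && cfg$specific_peptide_rate > 0)
    stop("sim config: specific_peptide_rate > 0 is infeasible with ",
         "isoform_fraction = 0")
  if (cfg$n_splice > n_multi)
    stop("sim config: n_splice (", cfg$n_splice,
         ") exceeds the number of multi-isoform families (", n_multi, ")")
  if (cfg$cv <= 0) stop("sim config: cv must be > 0")
  structure(cfg, class = "sim_config")
}

# Random tryptic-friendly peptides: no internal K/R, first residue not P
# (so a preceding cleavage site is never suppressed), C-terminal K or R.
# Uniqueness enforced against `seen`.
random_peptides <- function(n, seen = character(0), len_range = c(7L, 14L)) {
  inner <- setdiff(AA20, c("K", "R"))
  first <- setdiff(AA20, c("K", "R", "P"))
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    L <- sample(len_range[1]:len_range[2], length(need), replace = TRUE)
    cand <- vapply(L, function(l)
      paste0(sample(first, 1L),
             paste(sample(inner, l - 2L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L)), "")
    ok <- !duplicated(cand) & !(cand %in% seen)
    out[need[ok]] <- cand[ok]
    seen <- c(seen, cand[ok])
    need <- need[!ok]
  }
  list(peptides = out, seen = seen)
}

#' Generate a synthetic isoform catalog
#'
#' Builds protein families (a minority with 2-3 isoforms), synthesizing
#' sequences as concatenations of tryptic-friendly peptides (K/R at
#' controlled spacing) so that in-silico digestion with 0 missed
#' cleavages recovers exactly the designed peptide sets. Isoform
#' sequences share the family's common peptides and differ in their
#' specific peptides; a configurable fraction of peptides is injected
#' into a second family to create cross-family shared peptides.
#'
#' @param config a [sim_config()].
#' @return List with `catalog` (an `isoform_catalog` carrying sequences)
#'   and `peptide_roles` (data frame: `peptide`, `family`, `role` in
#'   unique/common/specific/shared_multi, `accession` of the owning
#'   isoform for specific peptides).
#' @export
generate_catalog <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families
  fam_ids <- sprintf("SYN%05d", seq_len(nf))
  n_multi <- round(nf * config$isoform_fraction)
  multi <- sort(sample.int(nf, n_multi))
  is_multi <- logical(nf); is_multi[multi] <- TRUE
  ppr <- config$peptides_per_protein

  seen <- character(0)
  acc_peps <- list()      # accession -> ordered peptide vector
  roles <- list()
  for (i in seq_len(nf)) {
    f <- fam_ids[i]
    if (!is_multi[i]) {
      n_pep <- sample(ppr[1]:ppr[2], 1L)
      g <- random_peptides(n_pep, seen); seen <- g$seen
      acc_peps[[f]] <- g$peptides
      roles[[i]] <- data.frame(peptide = g$peptides, family = f,
                               role = "unique", accession = f,
                               stringsAsFactors = FALSE)
    } else {
      n_iso <- sample(2:3, 1L)
      base <- sample(ppr[1]:ppr[2], 1L)
      n_spec <- max(1L, round(config$specific_peptide_rate * base))
      n_common <- max(1L, base - n_spec)
      g <- random_peptides(n_common, seen); seen <- g$seen
      common <- g$peptides
      fam_roles <- list(data.frame(peptide = common, family = f,
                                   role = "common", accession = NA_character_,
                                   stringsAsFactors = FALSE))
      for (k in seq_len(n_iso)) {
        acc <- sprintf("%s-%d", f, k)
        gs <- random_peptides(n_spec, seen); seen <- gs$seen
        acc_peps[[acc]] <- c(common, gs$peptides)
        fam_roles[[k + 1L]] <- data.frame(peptide = gs$peptides, family = f,
                                          role = "specific", accession = acc,
                                          stringsAsFactors = FALSE)
      }
      roles[[i]] <- do.call(rbind, fam_roles)
    }
  }
  roles <- do.call(rbind, c(roles, list(make.row.names = FALSE)))

  # cross-family shared peptides: move unique peptides of singleton
  # families into one additional singleton family
  singletons <- fam_ids[!is_multi]
  n_shared <- round(config$shared_multi_rate * nrow(roles))
  if (n_shared > 0L && length(singletons) >= 2L) {
    donors <- which(roles$role == "unique")
    pick <- sample(donors, min(n_shared, length(donors)))
    for (j in pick) {
      f_donor <- roles$family[j]
      f_recv <- sample(setdiff(singletons, f_donor), 1L)
      acc_peps[[f_recv]] <- c(acc_peps[[f_recv]], roles$peptide[j])
      roles$role[j] <- "shared_multi"
    }
  }

  sequences <- vapply(acc_peps, paste, "", collapse = "")
  list(catalog = isoform_catalog(names(sequences), sequences),
       peptide_roles = roles)
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Simulates peptide areas on the log2 scale: a per-family abundance
#' level, a per-peptide response offset, a per-sample loading offset
#' (removed downstream by median centering), and lognormal measurement
#' noise of the configured CV. Cohort B multiplies all of a planted
#' abundance-shift family's peptides by `2^shift`; planted isoform-shift
#' families shift only the target isoform's specific peptides, while
#' their common peptides receive a small opposite compensatory drift
#' (at most 1.2-fold). Cells are then masked missing-at-random.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, the area table, peptide
#'   map, design, truth table and FASTA are written there and the paths
#'   returned alongside the objects.
#' @return List with `areas` (`peptide_area_table`), `map`
#'   (`peptide_protein_map` derived by in-silico digestion of the emitted
#'   sequences), `catalog`, `design` (`sample_design`), `truth` (data
#'   frame: `family`, `kind`, `target_accession`, `log2_shift`,
#'   `drift_log2`), `peptide_roles`, and `paths` when `out_dir` is given.
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gen <- generate_catalog(config)  # seeds the RNG with config$seed
  catalog <- gen$catalog
  roles <- gen$peptide_roles

  fam_ids <- names(catalog$families)
  multi_fams <- fam_ids[lengths(catalog$families) >= 2L]
  splice_fams <- if (config$n_splice > 0L)
    sort(sample(multi_fams, config$n_splice)) else character(0)
  de_pool <- setdiff(fam_ids, splice_fams)
  de_fams <- if (config$n_de > 0L)
    sort(sample(de_pool, config$n_de)) else character(0)

  lu <- function(n, range) {  # log-uniform fold magnitudes, on log2 scale
    if (diff(range) == 0) rep(log2(range[1]), n)
    else stats::runif(n, log2(range[1]), log2(range[2]))
  }
  de_shift <- lu(length(de_fams), config$de_fold_range) *
    sample(c(-1, 1), length(de_fams), replace = TRUE)
  splice_shift <- lu(length(splice_fams), config$splice_fold_range) *
    sample(c(-1, 1), length(splice_fams), replace = TRUE)
  splice_target <- vapply(splice_fams, function(f)
    sample(catalog$families[[f]], 1L), "")
  drift <- -sign(splice_shift) *
    stats::runif(length(splice_fams), 0, log2(1.2))

  truth <- rbind(
    data.frame(family = de_fams, kind = rep("de", length(de_fams)),
               target_accession = rep(NA_character_, length(de_fams)),
               log2_shift = de_shift,
               drift_log2 = rep(0, length(de_fams)),
               stringsAsFactors = FALSE),
    data.frame(family = splice_fams,
               kind = rep("splice", length(splice_fams)),
               target_accession = unname(splice_target),
               log2_shift = splice_shift, drift_log2 = drift,
               stringsAsFactors = FALSE))

  samples <- c(sprintf("A%02d", seq_len(config$n_A)),
               sprintf("B%02d", seq_len(config$n_B)))
  cohort <- rep(c("A", "B"), c(config$n_A, config$n_B))
  design <- sample_design(samples, cohort)

  np <- nrow(roles)
  ns <- length(samples)
  fam_level <- stats::setNames(stats::rnorm(length(fam_ids), 17, 2.5), fam_ids)
  pep_level <- fam_level[roles$family] + stats::rnorm(np, 0, 1.5)
  loading <- stats::rnorm(ns, 0, 0.5)
  sdlog2 <- sqrt(log(1 + config$cv^2)) / log(2)

  # per-peptide cohort-B shift on the log2 scale
  shift_b <- numeric(np)
  if (length(de_fams)) {
    hit <- roles$family %in% de_fams & roles$role != "shared_multi"
    shift_b[hit] <- de_shift[match(roles$family[hit], de_fams)]
  }
  if (length(splice_fams)) {
    j <- match(roles$family, splice_fams)
    spec_hit <- !is.na(j) & roles$role == "specific" &
      roles$accession == splice_target[ifelse(is.na(j), 1L, j)]
    shift_b[spec_hit] <- splice_shift[j[spec_hit]]
    com_hit <- !is.na(j) & roles$role == "common"
    shift_b[com_hit] <- drift[j[com_hit]]
  }
  in_B <- cohort == "B"
  mu <- outer(pep_level, loading, "+") +
    outer(shift_b, as.numeric(in_B), "*")
  vals <- 2^(mu + stats::rnorm(np * ns, 0, sdlog2))
  if (config$missing_rate > 0)
    vals[stats::runif(np * ns) < config$missing_rate] <- NA_real_
  dim(vals) <- c(np, ns)

  areas <- new_peptide_area_table(
    data.frame(sequence = roles$peptide,
               modification = rep("", np), stringsAsFactors = FALSE),
    samples, vals)
  pm <- peptide_map_from_sequences(
    catalog$sequences,
    digest_params(missed_cleavages = 0L, min_len = 6L, max_len = 60L))

  out <- list(areas = areas, map = pm$map, catalog = catalog,
              design = design, truth = truth, peptide_roles = roles)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(areas = file.path(out_dir, "peptide_areas.tsv"),
                  peptide_map = file.path(out_dir, "peptide_map.tsv"),
                  design = file.path(out_dir, "design.tsv"),
                  truth = file.path(out_dir, "truth.tsv"),
                  fasta = file.path(out_dir, "proteins.fasta"))
    write_peptide_area_table(areas, paths$areas)
    write_peptide_map(pm$map, paths$peptide_map)
    write_design(design, paths$design)
    write_results(truth, paths$truth)
    write_catalog_fasta(catalog, paths$fasta)
    out$paths <- paths
  }
  out
}
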