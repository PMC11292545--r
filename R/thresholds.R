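#' Analysis thresholds
#'
#' Bundle of the statistical cutoffs used across the pipeline: the
#' differential-abundance filter (`p_de`, `fc_de`), the isoform-specific
#' filter (`p_iso`, `fc_iso`), the minimum number of observed values per
#' cohort for a group to be testable, and the permutation settings for the
#' FDR estimate.
#'
#' @param p_de raw p-value cutoff for the differential-abundance filter
#'   (default 0.05).
#' @param fc_de minimum fold change (linear scale, >= 1) for the
#'   differential-abundance filter (default 2).
#' @param p_iso raw p-value cutoff applied to isoform-specific protein
#'   groups when calling splicing discordance (default 0.01).
#' @param fc_iso minimum fold change an isoform-specific group must show to
#'   support a discordance call (default 2). Guards the raw-p isoform filter
#'   against chance hits among the many specific groups tested.
#' @param min_obs_per_group minimum observed (non-missing) values per cohort
#'   for a group to be testable (default 3).
#' @param permutations number of cohort-label permutations for the FDR
#'   estimate (default 1000). When the number of distinct label splits is
#'   smaller, all splits are enumerated instead.
#' @param seed integer seed for the permutation generator.
#'
#' @return An object of class `analysis_thresholds` (a validated list).
#' @export
analysis_thresholds <- function(p_de = 0.05, fc_de = 2, p_iso = 0.01,
                                fc_iso = 2, min_obs_per_group = 3L,
                                permutations = 1000L, seed = 1L) {
  th <- list(p_de = as.numeric(p_de), fc_de = as.numeric(fc_de),
             p_iso = as.numeric(p_iso), fc_iso = as.numeric(fc_iso),
             min_obs_per_group = as.integer(min_obs_per_group),
             permutations = as.integer(permutations),
             seed = as.integer(seed))
  if (!(th$p_de > 0 && th$p_de < 1))
    stop("thresholds: p_de must lie in (0, 1)")
  if (!(th$p_iso > 0 && th$p_iso < 1))
    stop("thresholds: p_iso must lie in (0, 1)")
  if (th$fc_de < 1) stop("thresholds: fc_de must be >= 1")
  if (th$fc_iso < 1) stop("thresholds: fc_iso must be >= 1")
  if (th$min_obs_per_group < 2L)
    stop("thresholds: min_obs_per_group must be >= 2")
  if (th$permutations < 1L) stop("thresholds: permutations must be >= 1")
  structure(th, class = "analysis_thresholds")
}

#' Coerce a plain list (e.g. from a YAML config) to analysis thresholds
#'
#' Unknown names are rejected so config typos fail loudly.
#'
#' @param x a named list with a subset of the `analysis_thresholds` fields.
#' @return An `analysis_thresholds` object.
#' @export
as_analysis_thresholds <- function(x) {
  if (inherits(x, "analysis_thresholds")) return(x)
  if (is.null(x)) return(analysis_thresholds())
  stopifnot(is.list(x))
  known <- names(formals(analysis_thresholds))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("thresholds: unknown field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_thresholds, x)
}

#' @export
print.analysis_thresholds <- function(x, ...) {
  cat("Analysis thresholds\n")
  cat(sprintf("  differential filter : p < %g and fold >= %g\n", x$p_de, x$fc_de))
  cat(sprintf("  isoform filter      : p < %g and fold >= %g\n", x$p_iso, x$fc_iso))
  cat(sprintf("  min obs per cohort  : %d\n", x$min_obs_per_group))
  cat(sprintf("  permutations        : %d (seed %d)\n", x$permutations, x$seed))
  invisible(x)
}
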