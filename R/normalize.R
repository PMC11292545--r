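# Log2 transform and per-sample median centering of composed group areas
# (the Perseus-style normalization used for label-free intensity data).

#' Log2-transform a protein-group matrix
#'
#' All present values must be strictly positive: zeros encode
#' non-detection and must have been mapped to missing upstream
#' (see [read_peptide_area_table()]).
#'
#' @param pgm a `protein_group_matrix` on the raw area scale.
#' @return The same structure with `areas` on the log2 scale and a
#'   `scale` field set to `"log2"`.
#' @export
log2_transform <- function(pgm) {
  stopifnot(inherits(pgm, "protein_group_matrix"))
  if (identical(pgm$scale, "log2"))
    stop("log2_transform: matrix is already on the log2 scale")
  bad <- which(!is.na(pgm$areas) & pgm$areas <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("log2_transform: nonpositive present value at group '%s', sample '%s'",
                 rownames(pgm$areas)[bad[1, 1]],
                 colnames(pgm$areas)[bad[1, 2]]))
  pgm$areas <- log2(pgm$areas)
  pgm$scale <- "log2"
  pgm
}

# median over present values; even count = mean of the two central order
# statistics (stats::median's convention, fixed here for reproducibility)
present_median <- function(v) stats::median(v, na.rm = TRUE)

#' Per-sample median centering
#'
#' Subtracts each sample's median of present values from that sample's
#' column, removing loading/acquisition offsets. Medians are taken over
#' present values only, so centering is robust to missingness; after
#' centering every sample's median of present values is exactly 0.
#'
#' @param pgm a `protein_group_matrix` on the log2 scale (see
#'   [log2_transform()]).
#' @return A `normalized_matrix` (also a `protein_group_matrix`) with the
#'   subtracted offsets in `sample_medians`.
#' @export
median_center <- function(pgm) {
  stopifnot(inherits(pgm, "protein_group_matrix"))
  if (!identical(pgm$scale, "log2"))
    stop("median_center: expected a log2-scale matrix (run log2_transform first)")
  n_present <- colSums(!is.na(pgm$areas))
  if (any(n_present == 0L))
    stop("median_center: sample '",
         colnames(pgm$areas)[which(n_present == 0L)[1]],
         "' has no present values")
  med <- apply(pgm$areas, 2L, present_median)
  pgm$areas <- sweep(pgm$areas, 2L, med, "-")
  pgm$sample_medians <- stats::setNames(med, colnames(pgm$areas))
  class(pgm) <- unique(c("normalized_matrix", class(pgm)))
  pgm
}
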