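#' Convert counts to relative abundances
#'
#' Column-normalizes each sample to proportions summing to one. These
#' proportions are the weights used by the cohesion statistics and the
#' community-weighted trait means.
#'
#' @param counts wide count tibble (`taxon_id` + one column per sample).
#' @return a tibble of the same shape with proportions.
#' @export
#' @examples
#' to_relative_abundance(tibble::tibble(taxon_id = c("a", "b"),
#'                                      s1 = c(2, 3)))
to_relative_abundance <- function(counts) {
  m <- abund_matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    ngn_abort(sprintf("sample with zero total count: %s",
                      colnames(m)[tot == 0][1L]), "ngn_validate_error")
  }
  matrix_to_tbl(sweep(m, 2, tot, "/"))
}

#' Filter rare taxa before network construction
#'
#' Retains taxa that are present (count > 0) in at least
#' `min_prevalence` of samples and whose mean relative abundance is at
#' least `min_mean_relabund`. Row order is preserved.
#'
#' @param counts wide count tibble.
#' @param min_prevalence prevalence threshold in [0, 1]; default 0.2.
#' @param min_mean_relabund mean relative-abundance threshold in [0, 1];
#'   default 0.
#' @return the filtered count tibble.
#' @export
filter_taxa <- function(counts, min_prevalence = 0.2,
                        min_mean_relabund = 0) {
  if (min_prevalence < 0 || min_prevalence > 1 ||
      min_mean_relabund < 0 || min_mean_relabund > 1) {
    ngn_abort("filter thresholds must lie in [0, 1]", "ngn_config_error")
  }
  m <- abund_matrix(counts)
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  keep <- rowMeans(m > 0) >= min_prevalence &
    rowMeans(rel) >= min_mean_relabund
  if (!any(keep)) {
    ngn_abort("filter removed every taxon", "ngn_validate_error")
  }
  counts[keep, , drop = FALSE]
}

#' Per-sample observed richness
#'
#' @param counts wide count tibble.
#' @return a tibble with columns `sample_id`, `richness` (number of taxa
#'   with count > 0).
#' @export
observed_richness <- function(counts) {
  m <- abund_matrix(counts)
  tibble(sample_id = colnames(m), richness = unname(colSums(m > 0)))
}
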