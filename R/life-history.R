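#' Per-sample copiotroph/oligotroph abundance ratio
#'
#' Ratio of summed relative abundance of copiotroph taxa to that of
#' oligotroph taxa; unclassified taxa are excluded from both sums. A
#' sample with zero oligotroph abundance is flagged undefined (NA).
#'
#' @param abund wide relative-abundance tibble.
#' @param traits trait tibble with `taxon_id`, `guild`.
#' @return a tibble with columns `sample_id`, `copio_oligo_ratio`,
#'   `ratio_defined`.
#' @export
copio_oligo_ratio <- function(abund, traits) {
  m <- abund_matrix(abund)
  guild <- traits$guild[match(rownames(m), traits$taxon_id)]
  guild[is.na(guild)] <- "unclassified"
  if (!any(guild %in% c("copiotroph", "oligotroph"))) {
    ngn_abort("no taxa annotated as copiotroph or oligotroph",
              "ngn_validate_error")
  }
  cop <- colSums(m[guild == "copiotroph", , drop = FALSE])
  oli <- colSums(m[guild == "oligotroph", , drop = FALSE])
  def <- unname(oli > 0)
  tibble(sample_id = colnames(m),
         copio_oligo_ratio = unname(ifelse(def, cop / oli, NA_real_)),
         ratio_defined = def)
}

#' Per-sample community-weighted mean of a taxon trait
#'
#' Abundance-weighted mean of a numeric trait, renormalized over the
#' annotated (non-missing) taxa only. A sample whose annotated taxa all
#' have zero abundance is flagged undefined (NA).
#'
#' @param abund wide relative-abundance tibble.
#' @param trait_values numeric trait vector named by taxon id, or a
#'   trait tibble plus `trait` column name.
#' @param trait when `trait_values` is a data frame, the column to use.
#' @return a tibble with columns `sample_id`, `cwm`, `cwm_defined`.
#' @export
#' @examples
#' ab <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(0.25, 0.75))
#' tr <- tibble::tibble(taxon_id = c("a", "b"), rrn_copies = c(2, 4))
#' community_weighted_mean(ab, tr, "rrn_copies")
community_weighted_mean <- function(abund, trait_values, trait = NULL) {
  m <- abund_matrix(abund)
  if (is.data.frame(trait_values)) {
    if (is.null(trait) || !trait %in% names(trait_values)) {
      ngn_abort("name the trait column to average", "ngn_config_error")
    }
    tv <- stats::setNames(trait_values[[trait]], trait_values$taxon_id)
  } else {
    tv <- trait_values
  }
  tv <- tv[match(rownames(m), names(tv))]
  ann <- !is.na(tv)
  if (!any(ann)) {
    ngn_abort("no annotated taxa for the requested trait",
              "ngn_validate_error")
  }
  w <- m[ann, , drop = FALSE]
  tot <- colSums(w)
  def <- unname(tot > 0)
  cwm <- unname(ifelse(def, as.numeric(crossprod(w, tv[ann])) / tot,
                       NA_real_))
  tibble(sample_id = colnames(m), cwm = cwm, cwm_defined = def)
}

#' Per-sample life-history trait indices
#'
#' Combines the copiotroph/oligotroph ratio and the community-weighted
#' means of rrn copy number and GC content into one table.
#'
#' @param abund wide relative-abundance tibble.
#' @param traits trait tibble (`taxon_id`, `guild`, `rrn_copies`,
#'   `gc_content`).
#' @return a tibble with columns `sample_id`, `copio_oligo_ratio`,
#'   `cwm_rrn`, `cwm_gc`, and definedness flags.
#' @export
trait_indices <- function(abund, traits) {
  ratio <- copio_oligo_ratio(abund, traits)
  rrn <- community_weighted_mean(abund, traits, "rrn_copies")
  gc <- community_weighted_mean(abund, traits, "gc_content")
  tibble(
    sample_id = ratio$sample_id,
    copio_oligo_ratio = ratio$copio_oligo_ratio,
    cwm_rrn = rrn$cwm,
    cwm_gc = gc$cwm,
    defined = ratio$ratio_defined & rrn$cwm_defined & gc$cwm_defined
  )
}

#' Composite r/K-strategy axis (PC1 of the three trait indices)
#'
#' Log-transforms the copiotroph/oligotroph ratio (ratios are
#' scale-asymmetric), z-standardizes the three indices, and returns the
#' first principal component oriented so that its loading on the log
#' ratio is non-negative: higher scores mean a more copiotrophic
#' (r-selected) community. Samples with undefined indices are excluded
#' (NA score) with a record; constant columns are dropped with a note
#' and fewer than two usable columns is an error.
#'
#' @param indices a [trait_indices()] table (>= 3 defined samples).
#' @return the input tibble plus an `rk_pc1` column; attributes
#'   `loadings`, `var_explained`, `dropped`, `excluded`.
#' @export
rk_strategy_pc1 <- function(indices) {
  need <- c("sample_id", "copio_oligo_ratio", "cwm_rrn", "cwm_gc")
  for (nm in need) {
    if (!nm %in% names(indices)) {
      ngn_abort(sprintf("missing column: %s", nm), "ngn_validate_error")
    }
  }
  x <- cbind(log_ratio = log(indices$copio_oligo_ratio),
             cwm_rrn = indices$cwm_rrn,
             cwm_gc = indices$cwm_gc)
  ok <- stats::complete.cases(x) & is.finite(rowSums(x))
  if (sum(ok) < 3) {
    ngn_abort("need at least 3 samples with all three indices defined",
              "ngn_validate_error")
  }
  xs <- x[ok, , drop = FALSE]
  sds <- apply(xs, 2, stats::sd)
  dropped <- colnames(xs)[sds == 0]
  keep <- sds > 0
  if (sum(keep) < 2) {
    ngn_abort("fewer than 2 non-constant trait indices", "ngn_validate_error")
  }
  pc <- stats::prcomp(scale(xs[, keep, drop = FALSE]), center = FALSE,
                      scale. = FALSE)
  orient <- orient_sign(pc$rotation[, 1L],
                        c("log_ratio", "cwm_rrn", "cwm_gc"))
  scores <- rep(NA_real_, nrow(indices))
  scores[ok] <- pc$x[, 1L] * orient
  out <- indices
  out$rk_pc1 <- scores
  loadings <- pc$rotation
  loadings[, 1L] <- loadings[, 1L] * orient
  attr(out, "loadings") <- loadings
  attr(out, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "dropped") <- dropped
  attr(out, "excluded") <- indices$sample_id[!ok]
  out
}

#' Per-sample richness split by life-history guild
#'
#' @param counts wide count tibble.
#' @param traits trait tibble with `taxon_id`, `guild`.
#' @return a tibble with columns `sample_id`, `guild`, `richness`;
#'   guilds include `unclassified`, and the per-sample guild richness
#'   sums to [observed_richness()].
#' @export
richness_by_guild <- function(counts, traits) {
  m <- abund_matrix(counts)
  guild <- traits$guild[match(rownames(m), traits$taxon_id)]
  guild[is.na(guild)] <- "unclassified"
  guilds <- c("copiotroph", "oligotroph", "unclassified")
  purrr::map_dfr(guilds, function(g) {
    rich <- unname(colSums(m[guild == g, , drop = FALSE] > 0))
    tibble(sample_id = colnames(m), guild = g, richness = rich)
  })
}
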