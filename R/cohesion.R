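#' Null-model-corrected pairwise correlations
#'
#' Computes the observed Pearson correlation for every taxon pair and
#' subtracts the expected correlation under a taxa-shuffle null model:
#' each null draw permutes one taxon's abundance vector across samples
#' while holding its partner fixed. Both orientations (permute j,
#' permute k) contribute `n_iter` draws each and are averaged. A
#' row-shuffle alternative (permute abundances among taxa within each
#' sample) is available. Zero-variance taxa get corrected r = 0 against
#' all partners.
#'
#' @param abund wide relative-abundance tibble (`taxon_id` + samples).
#' @param n_iter permutation draws per orientation; >= 100 recommended,
#'   default 200.
#' @param seed integer seed; results are deterministic given it.
#' @param null `"taxa_shuffle"` (default) or `"row_shuffle"`.
#' @param method correlation estimator for the observed and null
#'   correlations; Pearson (default, the original cohesion
#'   construction) or Spearman.
#' @return a symmetric matrix of corrected correlations (diagonal 0)
#'   with attribute `zero_variance`.
#' @export
#' @examples
#' b <- simulate_dataset(sim_config(n_taxa = 10, reps_per_level = 3,
#'                                  seq_depth = 500))
#' cc <- null_corrected_correlations(to_relative_abundance(b$counts),
#'                                   n_iter = 50, seed = 1)
#' range(cc)
null_corrected_correlations <- function(abund, n_iter = 200, seed = 1,
                                        null = c("taxa_shuffle",
                                                 "row_shuffle"),
                                        method = c("pearson", "spearman")) {
  null <- match.arg(null)
  method <- match.arg(method)
  m <- abund_matrix(abund)
  ns <- ncol(m)
  nt <- nrow(m)
  if (ns < 4) {
    ngn_abort("need at least 4 samples for null-corrected correlations",
              "ngn_validate_error")
  }
  if (!is_wholenumber(n_iter) || n_iter < 1) {
    ngn_abort("n_iter must be a positive integer", "ngn_config_error")
  }
  sds <- apply(m, 1, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  obs <- suppressWarnings(stats::cor(t(m), method = method))
  obs[!is.finite(obs)] <- 0
  tm <- t(m)
  null_sum <- matrix(0, nt, nt)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_iter)) {
      perm <- if (null == "taxa_shuffle") {
        # permute each taxon's vector across samples
        t(apply(m, 1, sample, size = ns))
      } else {
        # permute abundances among taxa within each sample
        apply(m, 2, sample, size = nt)
      }
      # entry [j, k]: cor(permuted taxon j, observed taxon k)
      cn <- suppressWarnings(stats::cor(t(perm), tm, method = method))
      cn[!is.finite(cn)] <- 0
      null_sum <- null_sum + cn
    }
  })
  null_mean <- (null_sum + t(null_sum)) / (2 * n_iter)
  corrected <- obs - null_mean
  corrected[flat, ] <- 0
  corrected[, flat] <- 0
  diag(corrected) <- 0
  dimnames(corrected) <- list(rownames(m), rownames(m))
  attr(corrected, "zero_variance") <- rownames(m)[flat]
  attr(corrected, "n_iter") <- n_iter
  corrected
}

#' Per-taxon positive and negative connectedness
#'
#' Positive connectedness of a taxon is the mean of its corrected
#' correlations over partners with positive corrected r; negative
#' connectedness the mean over partners with negative corrected r. An
#' empty partner set gives 0. No significance pre-filter is applied:
#' cohesion is threshold-free by construction.
#'
#' @param corrected symmetric corrected-correlation matrix from
#'   [null_corrected_correlations()].
#' @return a tibble with columns `taxon_id`, `pos` (>= 0), `neg` (<= 0).
#' @export
connectedness <- function(corrected) {
  if (!is.matrix(corrected) || nrow(corrected) != ncol(corrected)) {
    ngn_abort("corrected must be a square matrix", "ngn_validate_error")
  }
  if (max(abs(corrected - t(corrected))) > 1e-8) {
    ngn_abort("corrected matrix must be symmetric", "ngn_validate_error")
  }
  nt <- nrow(corrected)
  pos <- numeric(nt)
  neg <- numeric(nt)
  for (j in seq_len(nt)) {
    v <- corrected[j, -j]
    pv <- v[v > 0]
    nv <- v[v < 0]
    pos[j] <- if (length(pv) > 0) mean(pv) else 0
    neg[j] <- if (length(nv) > 0) mean(nv) else 0
  }
  tibble(taxon_id = rownames(corrected) %||% as.character(seq_len(nt)),
         pos = pos, neg = neg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample cohesion
#'
#' Positive cohesion of a sample is the abundance-weighted sum of
#' positive connectedness over taxa; negative cohesion likewise with
#' negative connectedness. Total cohesion is positive plus the absolute
#' value of negative; the negative:positive ratio indexes competitive
#' versus cooperative strength and is flagged undefined (NA) when
#' positive cohesion is exactly zero.
#'
#' @param abund wide relative-abundance tibble.
#' @param conn a [connectedness()] table for the same taxa.
#' @return a tibble with columns `sample_id`, `pos`, `neg`, `total`,
#'   `neg_pos_ratio`, `ratio_defined`.
#' @export
cohesion <- function(abund, conn) {
  m <- abund_matrix(abund)
  if (!setequal(rownames(m), conn$taxon_id)) {
    ngn_abort("abundance and connectedness taxa differ",
              "ngn_validate_error")
  }
  conn <- conn[match(rownames(m), conn$taxon_id), , drop = FALSE]
  pos <- as.numeric(crossprod(m, conn$pos))
  neg <- as.numeric(crossprod(m, conn$neg))
  ratio_def <- pos > 0
  tibble(
    sample_id = colnames(m),
    pos = pos, neg = neg,
    total = pos + abs(neg),
    neg_pos_ratio = ifelse(ratio_def, abs(neg) / pos, NA_real_),
    ratio_defined = ratio_def
  )
}

#' Cohesion pipeline over a sample grouping
#'
#' Convenience wrapper chaining [null_corrected_correlations()],
#' [connectedness()], and [cohesion()]. With `group = NULL` the
#' connectedness is estimated jointly from all samples; with a metadata
#' grouping column (the pipeline default is the N level) it is
#' estimated within each group, isolating treatment-local covariance
#' from gradient-driven covariance.
#'
#' @param abund wide relative-abundance tibble.
#' @param metadata per-sample metadata (required when grouping).
#' @param group name of a metadata column to group by, or NULL.
#' @param n_iter,seed,null,method passed to
#'   [null_corrected_correlations()]; each group derives its own seed.
#' @return a list with `cohesion` (per-sample tibble, plus the group
#'   column when grouping) and `connectedness` (per-taxon tibble, with
#'   a group column when grouping).
#' @export
compute_cohesion <- function(abund, metadata = NULL, group = NULL,
                             n_iter = 200, seed = 1,
                             null = "taxa_shuffle", method = "pearson") {
  if (is.null(group)) {
    cc <- null_corrected_correlations(abund, n_iter = n_iter, seed = seed,
                                      null = null, method = method)
    conn <- connectedness(cc)
    return(list(cohesion = cohesion(abund, conn), connectedness = conn))
  }
  if (is.null(metadata) || !group %in% names(metadata)) {
    ngn_abort(sprintf("grouping column %s not found in metadata", group),
              "ngn_validate_error")
  }
  sid <- sample_ids(abund)
  meta <- metadata[match(sid, metadata$sample_id), , drop = FALSE]
  levels <- unique(meta[[group]])
  coh <- list()
  conn_all <- list()
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    cols <- sid[meta[[group]] == lv]
    sub <- abund[c("taxon_id", cols)]
    cc <- null_corrected_correlations(
      sub, n_iter = n_iter,
      seed = derive_seed(seed, paste0("cohesion_group_", lv)),
      null = null, method = method)
    conn <- connectedness(cc)
    ch <- cohesion(sub, conn)
    ch[[group]] <- lv
    conn[[group]] <- lv
    coh[[i]] <- ch
    conn_all[[i]] <- conn
  }
  list(cohesion = dplyr::bind_rows(coh),
       connectedness = dplyr::bind_rows(conn_all))
}
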