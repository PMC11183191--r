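#' All-pairs abundance correlations with p and BH q values
#'
#' Computes the full taxon-by-taxon correlation matrix across samples
#' (Spearman by default, the rank-based choice for compositional OTU
#' tables; Pearson available), two-sided p-values from the t
#' approximation with n - 2 degrees of freedom, and Benjamini-Hochberg
#' q-values over the upper triangle. Taxa with zero variance are flagged
#' and assigned r = 0, p = 1 against all partners.
#'
#' @param abund wide abundance tibble (`taxon_id` + one column per
#'   sample); relative abundances in typical use.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return an object of class `cooccur_cor`: list with symmetric
#'   matrices `r`, `p`, `q`, the `method`, `n_samples`, and the ids of
#'   `zero_variance` taxa. Use [tidy()] for a long pair table.
#' @export
#' @examples
#' b <- simulate_dataset(sim_config(n_taxa = 12, reps_per_level = 3,
#'                                  seq_depth = 1000))
#' cc <- pairwise_correlation(to_relative_abundance(b$counts))
#' head(tidy(cc))
pairwise_correlation <- function(abund, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- abund_matrix(abund)
  n <- ncol(m)
  if (n < 4) {
    ngn_abort("need at least 4 samples for pairwise correlation",
              "ngn_validate_error")
  }
  sds <- apply(m, 1, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  r <- suppressWarnings(stats::cor(t(m), method = method))
  r[flat, ] <- 0
  r[, flat] <- 0
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  rt <- pmin(pmax(r, -1), 1)
  tstat <- rt * sqrt((n - 2) / pmax(1 - rt^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rt) >= 1] <- 0
  p[flat, ] <- 1
  p[, flat] <- 1
  diag(p) <- 1
  ut <- upper.tri(r)
  q <- matrix(1, nrow(r), ncol(r), dimnames = dimnames(r))
  q[ut] <- adjust_fdr(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(r = r, p = p, q = q, method = method, n_samples = n,
                 zero_variance = rownames(m)[flat]),
            class = "cooccur_cor")
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in [0, 1], monotone in p-order.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    ngn_abort("p-values must lie in [0, 1]", "ngn_validate_error")
  }
  pmin(stats::p.adjust(p, method = "BH"), 1)
}

#' @export
print.cooccur_cor <- function(x, ...) {
  cat(sprintf("<cooccur_cor> %s, %d taxa x %d samples",
              x$method, nrow(x$r), x$n_samples))
  if (length(x$zero_variance) > 0) {
    cat(sprintf(", %d zero-variance taxa", length(x$zero_variance)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname pairwise_correlation
#' @param x a `cooccur_cor` object.
#' @param ... unused.
#' @method tidy cooccur_cor
#' @export
tidy.cooccur_cor <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    taxon_a = rownames(x$r)[idx[, 1L]],
    taxon_b = colnames(x$r)[idx[, 2L]],
    r = x$r[idx], p = x$p[idx], q = x$q[idx]
  )
}
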