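# internal helpers shared across modules

ngn_abort <- function(msg, class = "ngradnet_error", ...) {
  rlang::abort(msg, class = c(class, "ngradnet_error"), ...)
}

#' Dose transform used throughout the package
#'
#' Nitrogen application rates are spaced as doublings, so all gradient
#' regressions and generative responses are linear in `log2(N + 1)`.
#'
#' @param n_rate numeric vector of N application rates (g N m^-2 y^-1).
#' @return numeric vector, `log2(n_rate + 1)`.
#' @export
#' @examples
#' n_dose(c(0, 1, 2, 4, 8, 16, 32, 64))
n_dose <- function(n_rate) {
  if (any(n_rate < 0)) ngn_abort("N rates must be non-negative")
  log2(n_rate + 1)
}

# Deterministic per-stage seed derived from one master seed, so adding a
# stage never perturbs the draws of earlier stages. Kept below 2^31.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 1009)
  as.integer((abs(master) * 48271 + h) %% 2147483587 + 1)
}

# Convert a wide abundance tibble (taxon_id + one column per sample) to a
# taxa x samples numeric matrix. Single orientation everywhere.
abund_matrix <- function(tbl, id_col = "taxon_id") {
  if (!is.data.frame(tbl)) ngn_abort("expected a data frame of abundances")
  if (!id_col %in% names(tbl)) {
    ngn_abort(sprintf("missing column: %s", id_col), "ngn_parse_error")
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    ngn_abort(sprintf("duplicate taxon id: %s",
                      ids[duplicated(ids)][1L]), "ngn_parse_error")
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (!is.numeric(m)) ngn_abort("abundance columns must be numeric",
                                "ngn_parse_error")
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col = "taxon_id") {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

sample_ids <- function(counts, id_col = "taxon_id") {
  setdiff(names(counts), id_col)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# scale() that returns zeros for a constant column instead of NaN
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
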