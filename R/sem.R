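#' Specify a piecewise structural equation model
#'
#' A piecewise SEM is a directed acyclic graph of regressions: each
#' endogenous variable is modeled by OLS on its parents, and global fit
#' is judged by testing the d-separation claims of the DAG (Fisher's C).
#'
#' @param paths character vector of path strings, one `"parent -> child"`
#'   per element (or several separated by newlines/semicolons).
#' @return an object of class `sem_spec`: list with `vars` (in
#'   deterministic topological order), `paths` (tibble: parent, child),
#'   and `exogenous`.
#' @export
#' @examples
#' sem_spec(c("a -> b", "b -> c"))
sem_spec <- function(paths) {
  raw <- unlist(strsplit(paths, "[;\n]"))
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) ngn_abort("no paths given", "ngn_config_error")
  parsed <- lapply(raw, function(s) {
    parts <- trimws(strsplit(s, "->", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(!nzchar(parts))) {
      ngn_abort(sprintf("cannot parse path: %s", s), "ngn_config_error")
    }
    parts
  })
  paths_tbl <- tibble(
    parent = vapply(parsed, `[[`, character(1), 1L),
    child = vapply(parsed, `[[`, character(1), 2L)
  )
  paths_tbl <- dplyr::distinct(paths_tbl)
  if (any(paths_tbl$parent == paths_tbl$child)) {
    ngn_abort("self-loop in path list", "ngn_config_error")
  }
  vars <- unique(c(paths_tbl$parent, paths_tbl$child))
  order <- topo_order(vars, paths_tbl)
  structure(list(vars = order,
                 paths = paths_tbl,
                 exogenous = setdiff(order, unique(paths_tbl$child))),
            class = "sem_spec")
}

# Kahn's algorithm with ties broken by first-mention order -> deterministic
topo_order <- function(vars, paths_tbl) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (ch in paths_tbl$child) indeg[ch] <- indeg[ch] + 1L
  out <- character(0)
  ready <- vars[indeg[vars] == 0]
  indeg_left <- indeg
  while (length(ready) > 0) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    kids <- paths_tbl$child[paths_tbl$parent == v]
    for (k in kids) {
      indeg_left[k] <- indeg_left[k] - 1L
      if (indeg_left[k] == 0L) {
        ready <- c(ready, k)
        ready <- ready[order(match(ready, vars))]
      }
    }
  }
  if (length(out) != length(vars)) {
    ngn_abort("path graph is cyclic", "ngn_config_error")
  }
  out
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("<sem_spec> %d variables, %d paths\n", length(x$vars),
              nrow(x$paths)))
  cat(paste0("  ", x$paths$parent, " -> ", x$paths$child, collapse = "\n"),
      "\n")
  invisible(x)
}

parents_of <- function(spec, v) spec$paths$parent[spec$paths$child == v]

#' The d-separation basis set of a DAG
#'
#' For every non-adjacent variable pair (deduplicated, the earlier
#' variable in topological order first) the basis set claims the pair
#' independent conditional on the union of both variables' parents.
#' Ordering is deterministic across runs.
#'
#' @param spec a [sem_spec()].
#' @return a tibble with columns `lhs` (earlier), `rhs` (later), and
#'   `conditioning` (comma-joined parent set, possibly empty).
#' @export
#' @examples
#' basis_set(sem_spec(c("a -> b", "b -> c")))
basis_set <- function(spec) {
  if (!inherits(spec, "sem_spec")) {
    ngn_abort("spec must come from sem_spec()", "ngn_validate_error")
  }
  vars <- spec$vars
  adj <- paste(spec$paths$parent, spec$paths$child)
  out <- list()
  k <- 0L
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      a <- vars[i]
      b <- vars[j]
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      cond <- sort(unique(setdiff(c(parents_of(spec, a),
                                    parents_of(spec, b)), c(a, b))))
      k <- k + 1L
      out[[k]] <- tibble(lhs = a, rhs = b,
                         conditioning = paste(cond, collapse = ","))
    }
  }
  if (k == 0L) {
    return(tibble(lhs = character(), rhs = character(),
                  conditioning = character()))
  }
  dplyr::bind_rows(out)
}

#' Fisher's C from independence-claim p-values
#'
#' C = -2 * sum(log p) over the k d-separation claims, compared to a
#' chi-square distribution with 2k degrees of freedom; the global
#' p-value is the upper tail. An empty claim set (saturated model)
#' yields C = 0, p = 1. A claim p of exactly 0 is surfaced as an error
#' rather than an infinite statistic.
#'
#' @param p numeric vector of claim p-values in (0, 1].
#' @return a one-row tibble: `fisher_c`, `df`, `p_value`, `k`.
#' @export
#' @examples
#' fishers_c(c(0.5, 0.5))
fishers_c <- function(p) {
  if (length(p) == 0) {
    return(tibble(fisher_c = 0, df = 0L, p_value = 1, k = 0L))
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    ngn_abort("claim p-values must lie in [0, 1]", "ngn_validate_error")
  }
  if (any(p == 0)) {
    ngn_abort("degenerate independence claim with p = 0",
              "ngn_validate_error")
  }
  cc <- -2 * sum(log(p))
  df <- 2L * length(p)
  tibble(fisher_c = cc, df = df,
         p_value = stats::pchisq(cc, df = df, lower.tail = FALSE),
         k = length(p))
}

#' Fit a piecewise structural equation model
#'
#' Fits one OLS per endogenous variable on its parents, reports
#' standardized path coefficients with p-values and per-model R², tests
#' every d-separation claim of [basis_set()] (OLS of the later variable
#' on the earlier plus the conditioning set; the p-value of the earlier
#' variable's coefficient), and summarizes global fit with Fisher's C.
#' Rows with a missing value in any SEM variable are dropped with a
#' record (complete-case analysis).
#'
#' @param data sample-level data frame containing every SEM variable.
#' @param spec a [sem_spec()]; defaults to [default_sem_spec()].
#' @return an object of class `psem_fit`: list with `paths`, `r2`,
#'   `claims`, `fit` (Fisher's C row), `n_used`, `n_dropped`, `spec`.
#'   [tidy()] returns the path table, [glance()] the global fit.
#' @export
fit_piecewise_sem <- function(data, spec = default_sem_spec()) {
  if (!inherits(spec, "sem_spec")) {
    ngn_abort("spec must come from sem_spec()", "ngn_validate_error")
  }
  miss <- setdiff(spec$vars, names(data))
  if (length(miss) > 0) {
    ngn_abort(sprintf("missing column: %s", miss[1L]), "ngn_validate_error")
  }
  d <- data[spec$vars]
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  endo <- setdiff(spec$vars, spec$exogenous)
  paths <- list()
  r2 <- list()
  for (v in endo) {
    pa <- parents_of(spec, v)
    fit <- tryCatch(ols_fit(d, v, pa), error = function(e) {
      ngn_abort(sprintf("component model for %s failed: %s", v,
                        conditionMessage(e)), "ngn_rank_error")
    })
    td <- tidy.ols_fit(fit)
    td <- td[td$term != "(Intercept)", , drop = FALSE]
    paths[[v]] <- tibble(parent = td$term, child = v,
                         estimate = td$estimate,
                         std_estimate = td$std_estimate,
                         std_error = td$std_error,
                         p_value = td$p_value)
    r2[[v]] <- tibble(variable = v,
                      r_squared = glance.ols_fit(fit)$r_squared)
  }
  claims <- basis_set(spec)
  claim_p <- numeric(nrow(claims))
  if (nrow(claims) > 0) {
    for (i in seq_len(nrow(claims))) {
      cond <- strsplit(claims$conditioning[i], ",", fixed = TRUE)[[1]]
      cond <- cond[nzchar(cond)]
      fit <- ols_fit(d, claims$rhs[i], c(claims$lhs[i], cond))
      td <- tidy.ols_fit(fit)
      claim_p[i] <- td$p_value[td$term == claims$lhs[i]]
    }
  }
  claims$p_value <- claim_p
  structure(list(
    paths = dplyr::bind_rows(paths),
    r2 = dplyr::bind_rows(r2),
    claims = claims,
    fit = fishers_c(claims$p_value),
    n_used = nrow(d),
    n_dropped = sum(!ok),
    spec = spec
  ), class = "psem_fit")
}

#' Default SEM graph for the nitrogen-gradient analysis
#'
#' N dose drives the soil environment (DIN up, pH down) and plant
#' richness; DIN and pH drive the community r/K-strategy axis; the
#' strategy axis drives bacterial richness and total cohesion; richness
#' and plant richness are given their own (tested) paths into cohesion.
#'
#' @return a [sem_spec()].
#' @export
default_sem_spec <- function() {
  sem_spec(c(
    "n_dose -> din",
    "n_dose -> ph",
    "n_dose -> plant_richness",
    "din -> rk_pc1",
    "ph -> rk_pc1",
    "rk_pc1 -> richness",
    "rk_pc1 -> total_cohesion",
    "richness -> total_cohesion",
    "plant_richness -> total_cohesion"
  ))
}

#' @export
print.psem_fit <- function(x, ...) {
  cat(sprintf("<psem_fit> %d paths, %d claims, n = %d",
              nrow(x$paths), nrow(x$claims), x$n_used))
  if (x$n_dropped > 0) cat(sprintf(" (%d rows dropped)", x$n_dropped))
  cat(sprintf("\n  Fisher's C = %.3f, df = %d, p = %.3f\n",
              x$fit$fisher_c, x$fit$df, x$fit$p_value))
  invisible(x)
}

#' @rdname fit_piecewise_sem
#' @param x a `psem_fit` object.
#' @param ... unused.
#' @method tidy psem_fit
#' @export
tidy.psem_fit <- function(x, ...) x$paths

#' @rdname fit_piecewise_sem
#' @method glance psem_fit
#' @export
glance.psem_fit <- function(x, ...) {
  tibble(fisher_c = x$fit$fisher_c, df = x$fit$df,
         p_value = x$fit$p_value, n_claims = x$fit$k,
         n = x$n_used, n_dropped = x$n_dropped)
}
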