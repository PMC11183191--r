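#' Ordinary least squares with standardized coefficients
#'
#' Thin wrapper around [stats::lm()] that additionally reports
#' standardized coefficients (b * sd(x) / sd(y)) and errors, with the
#' offending columns named, on rank deficiency.
#'
#' @param data a data frame of complete cases.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns.
#' @return an object of class `ols_fit` wrapping the `lm` fit; use
#'   [tidy()] / [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
#' glance(ols_fit(d, "y", "x"))
ols_fit <- function(data, response, predictors) {
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    ngn_abort(sprintf("missing column: %s", miss[1L]), "ngn_validate_error")
  }
  d <- data[cols]
  if (any(!stats::complete.cases(d))) {
    ngn_abort("ols_fit expects complete cases; drop or impute first",
              "ngn_validate_error")
  }
  n <- nrow(d)
  if (n <= length(predictors) + 1) {
    ngn_abort("not enough observations for the requested model",
              "ngn_validate_error")
  }
  fit <- stats::lm(stats::reformulate(predictors, response), data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    ngn_abort(sprintf("collinear predictors: %s",
                      paste(bad, collapse = ", ")), "ngn_rank_error")
  }
  sdy <- stats::sd(d[[response]])
  std <- vapply(predictors, function(p) {
    if (sdy == 0) return(0)
    unname(coef(fit)[[p]]) * stats::sd(d[[p]]) / sdy
  }, numeric(1))
  structure(list(fit = fit, response = response, predictors = predictors,
                 std_estimate = std, n = n),
            class = "ols_fit")
}

#' @rdname ols_fit
#' @param x an `ols_fit` object.
#' @param ... unused.
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
  out$std_estimate <- unname(c(NA_real_, x$std_estimate)[
    match(out$term, c("(Intercept)", x$predictors))])
  out
}

#' @rdname ols_fit
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  sm <- summary(x$fit)
  r2 <- sm$r.squared
  if (!is.finite(r2) || stats::sd(x$fit$model[[1L]]) == 0) r2 <- 0
  tibble(r_squared = r2,
         adj_r_squared = sm$adj.r.squared,
         df_residual = x$fit$df.residual,
         n = x$n)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %s ~ %s (n = %d, R^2 = %.3f)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n,
              summary(x$fit)$r.squared))
  invisible(x)
}

#' Linear trend of a per-sample quantity along the N gradient
#'
#' OLS of the value on the dose `log2(N + 1)`. Requires at least three
#' distinct N levels. Rows with a missing value are dropped.
#'
#' @param data a data frame with the value and N-rate columns.
#' @param value name of the response column.
#' @param n_rate name of the N application rate column (default
#'   `"n_rate"`).
#' @return an `ols_fit` whose single predictor is named `n_dose`.
#' @export
#' @examples
#' d <- tibble::tibble(n_rate = rep(c(0, 4, 16, 64), each = 3))
#' d$y <- 1 + 0.5 * n_dose(d$n_rate)
#' tidy(gradient_trend(d, "y"))
gradient_trend <- function(data, value, n_rate = "n_rate") {
  miss <- setdiff(c(value, n_rate), names(data))
  if (length(miss) > 0) {
    ngn_abort(sprintf("missing column: %s", miss[1L]), "ngn_validate_error")
  }
  d <- tibble(y = data[[value]], n_dose = n_dose(data[[n_rate]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$n_dose)) < 3) {
    ngn_abort("need at least 3 distinct N levels for a gradient trend",
              "ngn_validate_error")
  }
  fit <- ols_fit(d, "y", "n_dose")
  fit$response <- value
  fit
}

# slope row of a gradient trend as a one-line tibble
trend_row <- function(fit) {
  td <- tidy.ols_fit(fit)
  gl <- glance.ols_fit(fit)
  row <- td[td$term == "n_dose", ]
  tibble(response = fit$response, slope = row$estimate,
         std_estimate = row$std_estimate, p_value = row$p_value,
         r_squared = gl$r_squared, n = gl$n)
}

#' Partial correlation of two variables given controls
#'
#' Residualizes x and y on the controls by OLS and reports the Pearson
#' correlation of the residuals with a t-test on
#' n - (number of controls) - 2 degrees of freedom. With no controls
#' this is the plain Pearson correlation.
#'
#' @param data a data frame.
#' @param x,y names of the two variable columns.
#' @param controls character vector of control columns (may be empty).
#' @return a one-row tibble: `x`, `y`, `controls`, `r_partial`, `df`,
#'   `p_value`, `n`.
#' @export
partial_correlation <- function(data, x, y, controls = character()) {
  cols <- c(x, y, controls)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    ngn_abort(sprintf("missing column: %s", miss[1L]), "ngn_validate_error")
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(controls) + 2) {
    ngn_abort("not enough observations for the partial correlation",
              "ngn_validate_error")
  }
  resid_on <- function(v) {
    if (length(controls) == 0) return(d[[v]] - mean(d[[v]]))
    fit <- stats::lm(stats::reformulate(controls, v), data = d)
    if (any(is.na(coef(fit)))) {
      ngn_abort(sprintf("controls collinear with %s", v), "ngn_rank_error")
    }
    r <- stats::resid(fit)
    if (stats::sd(r) < .Machine$double.eps^0.5 * max(stats::sd(d[[v]]), 1)) {
      ngn_abort(sprintf("controls collinear with %s", v), "ngn_rank_error")
    }
    r
  }
  rx <- resid_on(x)
  ry <- resid_on(y)
  r <- stats::cor(rx, ry)
  df <- n - length(controls) - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  if (abs(r) >= 1) p <- 0
  tibble(x = x, y = y,
         controls = paste(controls, collapse = ","),
         r_partial = r, df = df, p_value = p, n = n)
}
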