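#' Ordinary least-squares regression with full diagnostics
#'
#' Fits `response ~ predictors` with an intercept on a cohort table and
#' returns the coefficient table together with R-squared, adjusted
#' R-squared and the overall F-test — the quantities the stiffness/force
#' determinant tables are built from.
#'
#' @param table Data.frame of per-animal measurements.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return A `regression_result`: `response`, `predictors`, `coefficients`
#'   (matrix with estimates, SEs, t, p), `r_squared`, `adj_r_squared`,
#'   `f_p_value`, `n`, `p` (number of predictors).
#' @export
fit_ols <- function(table, response, predictors) {
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(table[cols])) stop("missing cells in analyzed columns.", call. = FALSE)
  n <- nrow(table)
  p <- length(predictors)
  if (n <= p + 1L) stop("need n > p + 1 observations.", call. = FALSE)

  X <- as.matrix(cbind(`(Intercept)` = 1, table[predictors]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = table)
  # noiseless designed cohorts fit perfectly; that is a valid input here
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  structure(list(response = response, predictors = predictors,
                 coefficients = sm$coefficients,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_p_value = unname(f_p), n = n, p = p),
            class = "regression_result")
}

#' Adjusted R-squared (Wherry/Ezekiel)
#'
#' \deqn{\bar{R}^2 = 1 - (1 - R^2)\frac{n - 1}{n - p - 1}}
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("need n > p + 1.", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Stiffness/force determinant table of adjusted R-squared values
#'
#' One simple regression of each response on each single predictor, plus
#' the multiple-regression pairs used in the variance-partition argument:
#' for the stiffness responses, fibrosis combined with de-tyrosinated
#' tubulin and with the DT/alpha ratio; for peak force, fibrosis combined
#' with each stiffness direction and with both. Significance stars mark an
#' overall-regression F-test p <= 0.05 (the a priori threshold);
#' per-coefficient t-tests remain available through [fit_ols()].
#'
#' @param table A cohort table (see [generate_cohort()] for the column
#'   contract).
#' @param alpha Significance threshold for the star column.
#' @return A data.frame with `response`, `predictors`, `adj_r2`,
#'   `f_p_value`, `significant`.
#' @export
determinant_table <- function(table, alpha = 0.05) {
  single <- c("fibrosis", "alpha_tubulin", "beta_tubulin", "dt_tubulin",
              "dt_alpha_ratio")
  specs <- list()
  for (resp in c("transverse_stiffness", "longitudinal_stiffness")) {
    for (pr in single) specs[[length(specs) + 1L]] <- list(resp, pr)
    specs[[length(specs) + 1L]] <- list(resp, c("fibrosis", "dt_tubulin"))
    specs[[length(specs) + 1L]] <- list(resp, c("fibrosis", "dt_alpha_ratio"))
  }
  specs[[length(specs) + 1L]] <- list("peak_force", "fibrosis")
  specs[[length(specs) + 1L]] <- list("peak_force", c("fibrosis", "transverse_stiffness"))
  specs[[length(specs) + 1L]] <- list("peak_force", c("fibrosis", "longitudinal_stiffness"))
  specs[[length(specs) + 1L]] <- list("peak_force",
                                      c("fibrosis", "longitudinal_stiffness",
                                        "transverse_stiffness"))
  rows <- lapply(specs, function(sp) {
    fit <- fit_ols(table, sp[[1L]], sp[[2L]])
    data.frame(response = sp[[1L]],
               predictors = paste(sp[[2L]], collapse = "+"),
               adj_r2 = fit$adj_r_squared,
               f_p_value = fit$f_p_value,
               significant = fit$f_p_value <= alpha)
  })
  do.call(rbind, rows)
}

#' Adjusted R-squared gain from adding a predictor
#'
#' The variance-partition contrast: how much adjusted R-squared a candidate
#' predictor adds over a base model. Near-zero or negative gain means the
#' candidate carries no variance beyond the base set.
#'
#' @param table Cohort table.
#' @param response Response column.
#' @param base_predictors Character vector, the base model.
#' @param added_predictor Column to add.
#' @return List: `delta_adj_r2`, `base_adj_r2`, `full_adj_r2`.
#' @export
variance_gain <- function(table, response, base_predictors, added_predictor) {
  base <- fit_ols(table, response, base_predictors)
  full <- fit_ols(table, response, c(base_predictors, added_predictor))
  list(delta_adj_r2 = full$adj_r_squared - base$adj_r_squared,
       base_adj_r2 = base$adj_r_squared,
       full_adj_r2 = full$adj_r_squared)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("  R^2 = %.4f, adj R^2 = %.4f, F-test p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$f_p_value))
  invisible(x)
}
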