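#' Breath-frequency exclusion filter
#'
#' Single-pass quality filter for minute-resolution plethysmography logs:
#' the mean and SD of breath frequency are computed once over all minutes,
#' and minutes whose frequency falls strictly outside one SD of the mean
#' are excluded (breath-holding, head burying or hyperventilation leave
#' the band). Minutes exactly on the boundary are retained. The filter is
#' deliberately not iterated: re-trimming on the kept subset would shrink
#' the data without bound.
#'
#' @param log A breath log data.frame with at least a numeric `f` column
#'   (breaths/min), one row per minute.
#' @param sd_type `"sample"` (n-1 divisor, default) or `"population"` (n);
#'   the choice is echoed in the result.
#' @return A `breath_filter` list: `keep` (logical per minute), `mean_f`,
#'   `sd_f`, `n_excluded`, `excluded_minutes` (1-based row indices),
#'   `sd_type`.
#' @export
filter_breath_frequency <- function(log, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  f <- log$f
  if (is.null(f) || !is.numeric(f)) stop("log must have a numeric `f` column.",
                                         call. = FALSE)
  n <- length(f)
  if (n < 3L) stop("need at least 3 minutes to filter.", call. = FALSE)
  m <- mean(f)
  s <- stats::sd(f)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  keep <- abs(f - m) <= s
  structure(list(keep = keep, mean_f = m, sd_f = s,
                 n_excluded = sum(!keep),
                 excluded_minutes = which(!keep), sd_type = sd_type),
            class = "breath_filter")
}

#' Summarize respiratory variables over kept minutes
#'
#' Mean and SEM of each respiratory variable (`f`, `Tv`, `Mv`, `PIF`,
#' `PEF`, `Ti`, `Te`) over the minutes retained by the frequency filter —
#' one respiratory-function table row per animal.
#'
#' @param log A breath log data.frame.
#' @param filter A [filter_breath_frequency()] result; `NULL` summarizes
#'   all minutes.
#' @return A data.frame with one row per variable: `variable`, `mean`,
#'   `sem`, `n_minutes`; `attr(, "single_minute")` is TRUE when only one
#'   minute survived (SEM reported as 0 by convention).
#' @export
summarize_respiration <- function(log, filter = NULL) {
  keep <- if (is.null(filter)) rep(TRUE, nrow(log)) else filter$keep
  if (!any(keep)) stop("all minutes excluded; nothing to summarize.", call. = FALSE)
  vars <- intersect(c("f", "Tv", "Mv", "PIF", "PEF", "Ti", "Te"), names(log))
  kept <- log[keep, vars, drop = FALSE]
  n <- nrow(kept)
  out <- data.frame(
    variable = vars,
    mean = vapply(kept, mean, numeric(1)),
    sem = if (n > 1L) vapply(kept, function(v) stats::sd(v) / sqrt(n), numeric(1))
          else rep(0, length(vars)),
    n_minutes = n, row.names = NULL)
  attr(out, "single_minute") <- n == 1L
  out
}

#' Flag minutes whose minute ventilation is inconsistent with f x Tv
#'
#' Minute ventilation should be the product of breath frequency and tidal
#' volume up to averaging jitter; rows violating
#' `|Mv - f * Tv| / Mv > tol` indicate corrupted or mis-merged records.
#'
#' @param log A breath log data.frame with `f`, `Tv`, `Mv` columns.
#' @param tol Relative tolerance (default 0.05).
#' @return Logical vector, TRUE for inconsistent minutes.
#' @export
check_mv_consistency <- function(log, tol = 0.05) {
  stopifnot(all(c("f", "Tv", "Mv") %in% names(log)))
  abs(log$Mv - log$f * log$Tv) / log$Mv > tol
}
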