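#' Evaluate an expression under a local random seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' random state afterwards, so seeded generators never perturb global
#' simulations running around them.
#'
#' @param seed Integer seed. Mandatory: generators in this package never
#'   draw from ambient global RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer; generators require an explicit seed.",
         call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_positive <- function(..., .what = NULL) {
  vals <- list(...)
  nms <- if (is.null(.what)) sapply(substitute(list(...))[-1], deparse) else .what
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be a positive finite number.", nms[[i]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Wrap phase angles into (-pi, pi]
#' @param phi Numeric array of phase values (rad).
#' @return Array of the same shape, each value wrapped into (-pi, pi].
#' @keywords internal
wrap_phase <- function(phi) {
  # pi - ((pi - phi) mod 2pi) maps exactly onto (-pi, pi], with 0 -> 0
  pi - ((pi - phi) %% (2 * pi))
}
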