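# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding (round-half-even); the report
#' percentages and per-source removal rates follow the half-up convention
#' instead, so 0.085 prints as 0.09 at two decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  # pre-round far below the half boundary to absorb representation error
  floor(round(x * p, 9) + 0.5) / p
}

# Locale-independent string sort (C collation via radix method).
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("rxlexr_data_error", "error")))
}
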