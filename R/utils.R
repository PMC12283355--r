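#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Classed conditions so the CLI can map failures to exit codes:
# config error -> 2, data error -> 3, numerical failure -> 4.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pgstrial_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pgstrial_data_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("pgstrial_numeric_error", "error")))
}

#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows from a single user seed. Stages and
#' replicate loops draw child seeds through this one documented scheme so a
#' pipeline run is reproducible while its stages stay independent.
#' The result is always a positive integer below 2^31.
#'
#' @param seed parent integer seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
#' @examples
#' split_seed(1, 0:3)
split_seed <- function(seed, index) {
  if (!is.numeric(seed) || anyNA(seed)) stop_config("seed must be a number")
  # multiplicative hash mod a Mersenne prime keeps streams well separated
  as.integer((abs(seed) * 48271 + index * 1000003) %% 2147483647 + 1)
}

#' Standardize a numeric vector to mean 0, sd 1
#'
#' Mirrors the convention that polygenic scores are standardized in the whole
#' study population before any analysis. Refuses zero-variance input rather
#' than silently returning NaN.
#'
#' @param x numeric vector.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop_config("standardize() expects a numeric vector")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_data("cannot standardize a zero-variance vector")
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)
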