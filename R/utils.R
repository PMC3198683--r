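#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All stochastic stages draw their seed from one root seed so that any stage
#' can be re-run in isolation and reproduce its output. The derivation is a
#' small deterministic hash of the stage name folded into the root seed; the
#' result always fits a 32-bit integer.
#'
#' @param seed integer root seed.
#' @param stage character stage name (e.g. `"cohort"`, `"gsea"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 1009L + (h %% 99991L)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_param("%s must lie in [0, 1]", what)
  }
  invisible(p)
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) stop_param("%s must be positive", what)
  invisible(x)
}

#' Round half-up to a given number of digits
#'
#' Incidence percentages are reported as integers rounded half-up (so 12.5
#' becomes 13), matching the usual clinical-report convention rather than R's
#' banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

geometric_mean <- function(x) exp(mean(log(x)))
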