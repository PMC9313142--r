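## Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a root seed
#'
#' Each stochastic component (phantom background noise, cohort lesion draws,
#' PSA draws, survival draws, bootstrap resampling, ...) seeds its own RNG
#' stream from the root seed plus a fixed stream index, so sub-stages are
#' reproducible independently of the order in which they run.
#'
#' @param seed integer root seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stream) == 1)
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(stream) * 104729 + 1) %%
               2147483629)
}

## stop() with call suppressed; keeps error messages clean for pipeline users
abort <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

## percent formatted at 2 dp for reports; full precision is kept internally
format_percent <- function(x) sprintf("%.2f%%", x)

msg_info <- function(verbose, ...) {
  if (isTRUE(verbose)) message("INFO ", ...)
}
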