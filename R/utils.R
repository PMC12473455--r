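# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_numeric_vector <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || !is.null(dim(x)))
    stopf("`%s` must be a numeric vector", name)
  invisible(x)
}

#' Derive a per-stage seed from a global seed
#'
#' Counter-based fan-out so that each pipeline stage (and each repetition
#' inside a stage) gets its own reproducible stream without seed collisions.
#' Kept below 2^31 - 1 so the result is a valid R integer seed.
#'
#' @param seed Global integer seed.
#' @param counter Non-negative stage/repetition counter.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 100003) %%
               2147483647)
}
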