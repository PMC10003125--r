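#' Derive a child seed from a master seed
#'
#' Each pipeline stage draws from its own child stream so that stages are
#' independently reproducible: re-running only the phenotype stage under the
#' same master seed reproduces the same phenotypes regardless of how many
#' draws earlier stages consumed. The scheme is a fixed affine map into the
#' 31-bit positive integer range.
#'
#' @param seed master seed (single non-negative integer).
#' @param stage stage index (single non-negative integer), one per named
#'   stage of the pipeline.
#' @return an integer seed usable with [set.seed()].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, length(stage) == 1L,
            is.finite(seed), is.finite(stage), seed >= 0, stage >= 0)
  m <- 2147483647 # 2^31 - 1
  as.integer((as.double(seed) * 10007 + as.double(stage)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
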