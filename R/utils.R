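#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so library code does not perturb the caller's stream.
#' A `NULL` seed evaluates `code` against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage-specific seed from a pipeline seed
#'
#' Deterministic polynomial hash of the stage name folded into the master
#' seed, kept below 2^31 so the result is a valid R integer seed.  Stage
#' reruns therefore see the same sub-stream regardless of execution order.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 31 + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
pkg_version_string <- function() {
  paste0("microdivr ", as.character(utils::packageVersion("microdivr")))
}
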