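# Internal helpers shared across modules.

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Deterministic, stage-keyed seed derivation so independent stages of a
#' pipeline never share an RNG stream. Kept below 2^31 - 1.
#'
#' @param seed parent integer seed
#' @param stage character stage name
#' @param index optional replicate index
#' @return integer seed
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.double(seed) * 48271 + h * 7919 + as.double(index) * 104729) %% 2147483629
  as.integer(val) + 1L
}

# stop() with a classed condition so callers can test on error class
gfb_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gfblupkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
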