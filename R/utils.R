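# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are deterministic
#' given their `seed` argument without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stream of child seeds from a master seed
#'
#' Used so that independent stages (bootstrap replicates, rewiring
#' replicates, jackknife iterations) get decorrelated but reproducible
#' seeds. Kept below 2^31 - 1.
#' @noRd
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_coab <- function(..., class = "coabnet_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
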