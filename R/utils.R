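# Internal helpers shared across modules.

# DNAbin byte codes for the four unambiguous bases (a, c, g, t).
.ACGT_CODES <- as.raw(c(136L, 40L, 72L, 24L))

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous RNG state, so
#' library code never clobbers the caller's random stream. A `NULL` seed
#' evaluates `code` under the ambient stream; this is how the top-level
#' driver threads one master seed through all nested stochastic steps.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Logical mask of unambiguous A/C/G/T positions in a raw DNAbin vector.
.acgt_mask <- function(row) {
  row == .ACGT_CODES[1L] | row == .ACGT_CODES[2L] |
    row == .ACGT_CODES[3L] | row == .ACGT_CODES[4L]
}

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
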