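#' @import data.table
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

# SAM flag bits used throughout
FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_READ1 <- 0x40L
FLAG_READ2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Deterministic scoped RNG
#'
#' Runs `expr` under a fixed seed with the generator kinds pinned, restoring
#' the caller's RNG state afterwards. All stochastic operations in the
#' package route through this so that a seed fully determines every output.
#'
#' @param seed integer seed (< 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
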