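#' @useDynLib dtxmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @import Biostrings
#' @importMethodsFrom IRanges findOverlaps reduce gaps width start end
#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Sequences are handled as DNA
# (T, not U) throughout; RNA input is converted at the boundary.

as_dna <- function(x) toupper(chartr("Uu", "Tt", x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Derive a per-stage RNG seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage draws from its own
#' substream so that changing one stage's internals never perturbs another's
#' randomness.
#'
#' @param seed master integer seed.
#' @param label stage label (character).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h * 30269) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
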