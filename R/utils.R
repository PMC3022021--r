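#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so simulator calls do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic counter scheme: stage `k` of a run with master seed `s`
#' draws from seed `(s * 101 + k) mod (2^31 - 1)`.
#'
#' @param seed master seed.
#' @param k stage counter (small integer).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 101 + k) %% (2^31 - 1))
}

# round half away from zero, as printed tables conventionally do
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
}

gc_fraction <- function(x) {
  if (nchar(x) == 0L) return(NA_real_)
  v <- strsplit(x, NULL)[[1]]
  sum(v == "G" | v == "C") / length(v)
}

split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
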