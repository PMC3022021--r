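# Shared codon bookkeeping for the simulator, NG86 and CAI (bacterial
# genetic code, translation table 11).

genetic_code11 <- function() {
  gc <- .pangcn_cache$gc11
  if (is.null(gc)) {
    gc <- Biostrings::getGeneticCode("11")
    .pangcn_cache$gc11 <- gc
  }
  gc
}

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sense_codons <- function() {
  gc <- genetic_code11()
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- genetic_code11()
  names(gc)[gc == "*"]
}

codon_aa <- function(codon) unname(genetic_code11()[codon])

# synonymous families: named list aa -> codons
codon_families <- function() {
  gc <- genetic_code11()
  sense <- names(gc)[gc != "*"]
  split(sense, unname(gc[sense]))
}

#' Codon usage table with a tunable synonymous bias
#'
#' Builds the exact sampling distribution the ancestor simulator draws
#' coding sequences from. Within each synonymous family one codon is
#' "preferred" (the alphabetically first codon ending in G or C, mimicking
#' the GC3-rich usage of lactic acid bacteria); `bias_strength` linearly
#' interpolates between uniform usage within the family (0) and exclusive
#' use of the preferred codon (1). Amino acids are drawn uniformly.
#'
#' @param bias_strength numeric in \[0, 1\].
#' @return data.frame with columns `codon`, `aa`, `preferred`,
#'   `p_within_family` (conditional on the amino acid) and `prob`
#'   (joint sampling probability over the 61 sense codons).
#' @export
codon_usage_table <- function(bias_strength = 0.5) {
  stopifnot(bias_strength >= 0, bias_strength <= 1)
  fams <- codon_families()
  rows <- lapply(names(fams), function(aa) {
    cods <- sort(fams[[aa]])
    gc3 <- substring(cods, 3, 3) %in% c("G", "C")
    pref <- if (any(gc3)) cods[gc3][1] else cods[1]
    k <- length(cods)
    w <- (1 - bias_strength) / k + bias_strength * (cods == pref)
    data.frame(codon = cods, aa = aa, preferred = cods == pref,
               p_within_family = w, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_aa <- length(fams)
  tab$prob <- tab$p_within_family / n_aa
  rownames(tab) <- NULL
  tab
}
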