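#' Genome summary statistics
#'
#' Computes the usual bacterial genome-table quantities: chromosome length,
#' overall GC, CDS counts split into intact and pseudo (truncated), total
#' and mean CDS length, GC inside coding sequences, GC3 (every third
#' coding base, intact CDSs only), coding fraction
#' and stable-RNA (rRNA + tRNA) fraction.
#'
#' Pseudogenes count toward the CDS total, total CDS length and the mean
#' CDS length, but are excluded from GC3, which needs an intact reading
#' frame. Percentages are reported to 2 decimals, half-up.
#'
#' @param g a [genome].
#' @return an object of class `genome_stats` (a named list).
#' @export
genome_stats <- function(g) {
  stopifnot(inherits(g, "genome"))
  len <- nchar(g$seq)
  if (len == 0L) stop("empty genome")
  f <- g$features
  cds <- f[f$type == "CDS", , drop = FALSE]
  rna <- f[f$type %in% c("rRNA", "tRNA"), , drop = FALSE]
  cds_bp <- sum(cds$end - cds$start + 1L)
  intact <- cds[!cds$pseudo, , drop = FALSE]

  coding_concat <- if (nrow(intact)) {
    paste(vapply(intact$locus_tag, function(t) extract_cds(g, t), character(1)),
          collapse = "")
  } else ""
  gc_cds <- if (nzchar(coding_concat)) gc_fraction(coding_concat) else NA_real_
  gc3 <- if (nrow(intact)) {
    # every third base of each intact coding sequence
    thirds <- unlist(lapply(intact$locus_tag, function(t) {
      s <- extract_cds(g, t)
      n <- nchar(s) %/% 3L
      substring(s, 3L * seq_len(n), 3L * seq_len(n))
    }))
    if (length(thirds)) mean(thirds %in% c("G", "C")) else NA_real_
  } else NA_real_

  structure(list(
    length_bp = len,
    gc_percent = round_half_up(100 * gc_fraction(g$seq), 2),
    n_cds_total = nrow(cds),
    n_cds_intact = sum(!cds$pseudo),
    n_cds_pseudo = sum(cds$pseudo),
    total_cds_bp = cds_bp,
    mean_cds_len_bp = if (nrow(cds)) as.integer(round_half_up(cds_bp / nrow(cds))) else NA_integer_,
    gc_in_cds_percent = round_half_up(100 * gc_cds, 2),
    gc3_percent = round_half_up(100 * gc3, 2),
    coding_fraction = cds_bp / len,
    stable_rna_fraction = sum(rna$end - rna$start + 1L) / len
  ), class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Genome statistics\n",
    "  length:        %s bp\n",
    "  GC:            %.2f %%\n",
    "  CDS:           %d (intact %d, pseudo %d)\n",
    "  mean CDS len:  %d bp\n",
    "  GC in CDS:     %.2f %%   GC3: %.2f %%\n",
    "  coding:        %.1f %%   stable RNA: %.2f %%\n"),
    format(x$length_bp, big.mark = ","), x$gc_percent,
    x$n_cds_total, x$n_cds_intact, x$n_cds_pseudo,
    x$mean_cds_len_bp, x$gc_in_cds_percent, x$gc3_percent,
    100 * x$coding_fraction, 100 * x$stable_rna_fraction))
  invisible(x)
}
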