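#' Detect large duplicated chromosomal segments
#'
#' Maximal-exact-match style repeat detection: exact k-mer anchors shared
#' between two loci (on either strand) are chained by collinearity and
#' merged chains are reported as duplicated segment pairs with an
#' anchor-based identity estimate. Self matches on the main diagonal are
#' excluded. This plays the role whole-genome aligners (e.g. MUMmer) play
#' in chromosome dot-plots.
#'
#' @param g a [genome] (or a plain DNA character scalar).
#' @param min_len minimum reported segment length in bp (>= 1000).
#' @param min_identity minimum anchor-based identity percent.
#' @param k anchor k-mer size.
#' @param max_gap maximum anchor-to-anchor gap within a chain, bp.
#' @param max_occ k-mers occurring more often than this are skipped
#'   (low-complexity guard).
#' @return data.frame with columns `start1`, `end1`, `start2`, `end2`,
#'   `orientation` ("direct"/"inverted"), `length_bp`, `identity_percent`,
#'   one row per segment pair, sorted by `start1`. Coordinates 1-based
#'   closed; pair 1 is always the leftmost copy.
#' @export
find_duplicated_segments <- function(g, min_len = 1000L, min_identity = 90,
                                     k = 20L, max_gap = 500L, max_occ = 12L) {
  seq <- if (inherits(g, "genome")) g$seq else toupper(g)
  if (min_len < 1000L) stop("min_len must be >= 1000")
  n <- nchar(seq)
  if (n < 2L * k) return(empty_segments())
  pos <- seq_len(n - k + 1L)
  fw <- substring(seq, pos, pos + k - 1L)

  pairs <- NULL  # matrix cols: p1, p2, inverted(0/1)

  # direct repeats: duplicated forward k-mers
  dup_keys <- unique(fw[duplicated(fw)])
  if (length(dup_keys)) {
    hit <- which(fw %in% dup_keys)
    grp <- split(hit, fw[hit])
    for (ps in grp) {
      if (length(ps) > max_occ) next
      cmb <- utils::combn(sort(ps), 2L)
      pairs <- rbind(pairs, cbind(cmb[1L, ], cmb[2L, ], 0L))
    }
  }

  # inverted repeats: forward k-mer equals a reverse-complement k-mer
  rc <- revcomp(seq)
  rv <- substring(rc, pos, pos + k - 1L)
  # rv[j] covers forward interval [n - (j + k - 1) + 1, n - j + 1]
  common <- intersect(fw, rv)
  # drop palindromic anchors pairing a position with itself
  if (length(common)) {
    fidx <- split(which(fw %in% common), fw[which(fw %in% common)])
    ridx <- split(which(rv %in% common), rv[which(rv %in% common)])
    for (key in names(fidx)) {
      pi <- fidx[[key]]; pj <- ridx[[key]]
      if (length(pi) * length(pj) > max_occ^2) next
      for (i in pi) for (j in pj) {
        jf <- n - (j + k - 1L) + 1L   # forward start of the rc anchor
        a <- min(i, jf); b <- max(i, jf)
        if (abs(i - jf) < k) next     # overlapping palindrome core
        pairs <- rbind(pairs, cbind(a, b, 1L))
      }
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_segments())
  pairs <- unique(pairs)

  out <- empty_segments()
  for (inv in c(0L, 1L)) {
    pp <- pairs[pairs[, 3L] == inv, , drop = FALSE]
    if (!nrow(pp)) next
    # chain key: diagonal (direct) or anti-diagonal (inverted)
    key <- if (inv == 0L) pp[, 2L] - pp[, 1L] else pp[, 1L] + pp[, 2L]
    ord <- order(key, pp[, 1L])
    pp <- pp[ord, , drop = FALSE]; key <- key[ord]
    brk <- c(TRUE, abs(diff(key)) > 30L | diff(pp[, 1L]) > max_gap)
    chain_id <- cumsum(brk)
    for (cid in unique(chain_id)) {
      cc <- pp[chain_id == cid, , drop = FALSE]
      s1 <- min(cc[, 1L]); e1 <- max(cc[, 1L]) + k - 1L
      s2 <- min(cc[, 2L]); e2 <- max(cc[, 2L]) + k - 1L
      len <- e1 - s1 + 1L
      if (len < min_len) next
      if (s2 <= e1 && inv == 0L && s1 == s2) next  # degenerate self chain
      # identity: fraction of span 1 covered by exact anchors
      cov <- IRanges::reduce(IRanges::IRanges(cc[, 1L], cc[, 1L] + k - 1L))
      ident <- 100 * sum(IRanges::width(cov)) / len
      if (ident < min_identity) next
      out <- rbind(out, data.frame(
        start1 = s1, end1 = e1, start2 = s2, end2 = e2,
        orientation = if (inv == 0L) "direct" else "inverted",
        length_bp = len, identity_percent = round_half_up(ident, 2),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(out)) {
    out <- out[order(out$start1, out$start2), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_segments <- function() {
  data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
             end2 = integer(), orientation = character(),
             length_bp = integer(), identity_percent = numeric(),
             stringsAsFactors = FALSE)
}

#' Write duplicated segments as a BED-like TSV
#' @param segments result of [find_duplicated_segments].
#' @param path output path.
#' @param chrom chromosome name column value.
#' @return invisibly, `path`.
#' @export
write_segments <- function(segments, path, chrom = "chr") {
  df <- cbind(chrom = chrom, segments)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
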