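#' Construct a genome object
#'
#' A genome is a single (by default circular) bacterial chromosome plus an
#' ordered table of typed features. Coordinates are 1-based closed, on the
#' forward strand, matching the GFF3 convention used on disk.
#'
#' @param id strain identifier (also the sequence record id).
#' @param seq chromosome sequence, a character scalar over A,C,G,T,N.
#' @param features data.frame with columns `locus_tag`, `type` (one of
#'   CDS, rRNA, tRNA, other), `start`, `end`, `strand` ("+"/"-"),
#'   `pseudo` (logical), `product`, `ec` (comma-separated EC numbers,
#'   "" if none). Extra columns are preserved.
#' @param is_circular logical flag.
#' @return an object of class `genome`.
#' @export
genome <- function(id, seq, features = empty_features(), is_circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("locus_tag", "type", "start", "end", "strand", "pseudo", "product", "ec")
  miss <- setdiff(needed, names(features))
  for (m in miss) {
    features[[m]] <- switch(m,
      pseudo = logical(nrow(features)),
      start = , end = integer(nrow(features)),
      character(nrow(features)))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$pseudo <- as.logical(features$pseudo)
  features$product[is.na(features$product)] <- ""
  features$ec[is.na(features$ec)] <- ""
  if (nrow(features)) {
    if (anyDuplicated(features$locus_tag))
      stop("duplicate locus tags: ", paste(unique(
        features$locus_tag[duplicated(features$locus_tag)]), collapse = ", "))
    if (any(features$start < 1L) || any(features$end > nchar(seq)))
      stop("feature coordinates outside [1, genome length]")
    if (any(features$start > features$end))
      stop("feature with start > end (origin-wrapping features are not emitted)")
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!all(features$type %in% c("CDS", "rRNA", "tRNA", "other")))
      stop("feature type must be CDS, rRNA, tRNA or other")
    features <- features[order(features$start, features$end, features$locus_tag), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, seq = seq, features = features,
                 is_circular = isTRUE(is_circular)),
            class = "genome")
}

empty_features <- function() {
  data.frame(locus_tag = character(), type = character(),
             start = integer(), end = integer(), strand = character(),
             pseudo = logical(), product = character(), ec = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.genome <- function(x, ...) {
  ft <- table(factor(x$features$type, levels = c("CDS", "rRNA", "tRNA", "other")))
  cat(sprintf("<genome> %s: %s bp (%s), %d features (CDS %d, rRNA %d, tRNA %d)\n",
              x$id, format(nchar(x$seq), big.mark = ","),
              if (x$is_circular) "circular" else "linear",
              nrow(x$features), ft[["CDS"]], ft[["rRNA"]], ft[["tRNA"]]))
  invisible(x)
}

#' Read a genome from FASTA + GFF3 or from a GenBank flat file
#'
#' @param path FASTA file (gff3 dialect) or GenBank flat file (genbank
#'   dialect).
#' @param annotation GFF3 file; required for the gff3 dialect, ignored for
#'   genbank.
#' @param dialect "auto" (by extension), "gff3" or "genbank".
#' @return a [genome] object. Only CDS, rRNA and tRNA features are kept.
#'   The GFF3 `pseudo=true` attribute and the GenBank `/pseudo` qualifier
#'   set the pseudo flag.
#' @export
read_genome <- function(path, annotation = NULL,
                        dialect = c("auto", "gff3", "genbank")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  if (dialect == "genbank") return(read_genbank(path))
  if (is.null(annotation)) stop("gff3 dialect needs an annotation file")
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("FASTA must contain exactly one chromosome record, found ", length(seqs))
  id <- sub("\\s.*$", "", names(seqs)[1])
  gr <- rtracklayer::import(annotation, format = "gff3")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == id &
             as.character(S4Vectors::mcols(gr)$type) %in% c("CDS", "rRNA", "tRNA")]
  if (length(gr) == 0L && length(rtracklayer::import(annotation, format = "gff3")) > 0L)
    stop("annotation does not reference sequence id '", id, "'")
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (nm %in% names(mc)) {
      v <- mc[[nm]]
      if (inherits(v, "CharacterList") || is.list(v))
        v <- vapply(v, function(e) paste(e, collapse = ","), character(1))
      as.character(v)
    } else rep(NA_character_, length(gr))
  }
  lt <- getcol("locus_tag")
  if (all(is.na(lt))) lt <- getcol("ID")
  feats <- data.frame(
    locus_tag = lt,
    type = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    pseudo = tolower(getcol("pseudo")) %in% "true",
    product = getcol("product"),
    ec = getcol("ec_number"),
    stringsAsFactors = FALSE)
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  if (any(feats$end > nchar(as.character(seqs[[1]]))))
    stop("feature out of sequence bounds in ", annotation)
  genome(id, as.character(seqs[[1]]), feats)
}

#' Write a genome as FASTA + GFF3
#'
#' Emits 1-based closed GFF3 with `ID`, `locus_tag`, `product`,
#' `pseudo=true` and `ec_number` attributes, so that
#' `read_genome(fasta, gff3)` round-trips the object.
#'
#' @param g a [genome].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(g, fasta_path, gff3_path) {
  stopifnot(inherits(g, "genome"))
  dna <- Biostrings::DNAStringSet(setNames(g$seq, g$id))
  Biostrings::writeXStringSet(dna, fasta_path)
  f <- g$features
  if (nrow(f)) {
    gr <- GenomicRanges::GRanges(
      g$id, IRanges::IRanges(f$start, f$end), strand = f$strand)
    S4Vectors::mcols(gr)$source <- "pangcn"
    S4Vectors::mcols(gr)$type <- f$type
    S4Vectors::mcols(gr)$ID <- f$locus_tag
    S4Vectors::mcols(gr)$locus_tag <- f$locus_tag
    S4Vectors::mcols(gr)$pseudo <- ifelse(f$pseudo, "true", NA_character_)
    S4Vectors::mcols(gr)$product <- ifelse(nzchar(f$product), f$product, NA_character_)
    S4Vectors::mcols(gr)$ec_number <- ifelse(nzchar(f$ec), f$ec, NA_character_)
    suppressWarnings(rtracklayer::export(gr, gff3_path, format = "gff3"))
  } else {
    writeLines("##gff-version 3", gff3_path)
  }
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Extract the coding sequence of a feature
#'
#' Minus-strand features are reverse complemented so the returned string
#' reads 5' to 3' in the coding sense.
#'
#' @param g a [genome].
#' @param locus_tag feature to extract.
#' @return DNA string.
#' @export
extract_cds <- function(g, locus_tag) {
  stopifnot(inherits(g, "genome"))
  i <- match(locus_tag, g$features$locus_tag)
  if (is.na(i)) stop("no feature with locus tag '", locus_tag, "'")
  s <- substring(g$seq, g$features$start[i], g$features$end[i])
  if (g$features$strand[i] == "-") s <- revcomp(s) else s
}

#' Translate a CDS with the bacterial genetic code (table 11)
#'
#' The terminal stop codon is stripped. An internal stop in a sequence not
#' flagged pseudo raises an error; codons containing non-ACGT bases
#' translate as `X`.
#'
#' @param dna coding-sense DNA string, length divisible by 3 (unless
#'   `pseudo`).
#' @param pseudo if TRUE, translate the longest open reading frame instead
#'   of requiring an intact frame (frameshifted pseudogenes).
#' @return protein string (possibly empty for a short pseudogene).
#' @export
translate_cds <- function(dna, pseudo = FALSE) {
  if (pseudo) return(longest_orf_protein(dna))
  if (nchar(dna) %% 3L != 0L)
    stop("CDS length not divisible by 3; use pseudo = TRUE for pseudogenes")
  aa <- translate_codons(split_codons(toupper(dna)))
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE)) stop("internal stop codon in non-pseudo CDS")
  aa
}

# plain lookup translation; codons containing non-ACGT bases give X
translate_codons <- function(cods) {
  gc <- genetic_code11()
  aa <- unname(gc[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# longest stretch of sense codons in any of the three forward frames,
# used to let INDEL pseudogenes take part in protein-level comparisons
longest_orf_protein <- function(dna, min_codons = 1L) {
  best <- ""
  dna <- toupper(dna)
  for (off in 0:2) {
    s <- substring(dna, off + 1L, nchar(dna))
    s <- substring(s, 1L, 3L * (nchar(s) %/% 3L))
    if (nchar(s) < 3L) next
    aa <- translate_codons(split_codons(s))
    for (piece in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      if (nchar(piece) > nchar(best)) best <- piece
    }
  }
  if (nchar(best) >= min_codons) best else ""
}

#' Translated proteome of a genome
#'
#' Non-pseudo CDSs are translated through table 11; pseudogenes contribute
#' their longest open reading frame if it reaches `min_pseudo_codons`
#' (shorter ones are dropped).
#'
#' @param g a [genome].
#' @param min_pseudo_codons minimum ORF length for pseudogene inclusion.
#' @return named character vector of protein sequences.
#' @export
proteome <- function(g, min_pseudo_codons = 50L) {
  f <- g$features[g$features$type == "CDS", , drop = FALSE]
  if (!nrow(f)) return(setNames(character(0), character(0)))
  cds <- Biostrings::DNAStringSet(substring(g$seq, f$start, f$end))
  minus <- f$strand == "-"
  if (any(minus)) cds[minus] <- Biostrings::reverseComplement(cds[minus])
  out <- character(nrow(f))
  intact <- !f$pseudo
  if (any(intact)) {
    aa <- as.character(suppressWarnings(Biostrings::translate(
      cds[intact], genetic.code = genetic_code11(), if.fuzzy.codon = "X")))
    aa <- sub("\\*$", "", aa)
    if (any(grepl("*", aa, fixed = TRUE)))
      stop("internal stop codon in non-pseudo CDS of ", g$id)
    out[intact] <- aa
  }
  for (i in which(f$pseudo))
    out[i] <- longest_orf_protein(as.character(cds[[i]]),
                                  min_codons = min_pseudo_codons)
  keep <- nzchar(out)
  setNames(out[keep], f$locus_tag[keep])
}
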