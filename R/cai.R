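#' Relative adaptiveness of codons from a reference gene set
#'
#' Sharp & Li style weights: codon counts are pooled over the reference
#' CDSs; within each synonymous family the weight is the count divided by
#' the family's maximum count, with zero counts replaced by 0.5 before
#' normalization so that rare codons keep a finite penalty.
#'
#' @param reference_cds character vector of coding-sense CDSs
#'   (>= 10 genes recommended), or a [genome] plus `reference_keyword`.
#' @param reference_keyword if `reference_cds` is a genome, CDSs whose
#'   product matches this string (fixed, case-insensitive) form the
#'   reference set. Default "ribosomal protein".
#' @return object of class `codon_weights`: named numeric vector over the
#'   61 sense codons with attribute `reference` describing the set.
#' @export
relative_adaptiveness <- function(reference_cds,
                                  reference_keyword = "ribosomal protein") {
  if (inherits(reference_cds, "genome")) {
    g <- reference_cds
    f <- g$features
    sel <- f$type == "CDS" & !f$pseudo &
      grepl(reference_keyword, f$product, ignore.case = TRUE, fixed = FALSE)
    if (!any(sel)) stop("no CDS product matches '", reference_keyword, "'")
    reference_cds <- vapply(f$locus_tag[sel], function(t) extract_cds(g, t),
                            character(1))
    desc <- sprintf("%d CDSs matching '%s' in %s", sum(sel),
                    reference_keyword, g$id)
  } else {
    desc <- sprintf("%d reference CDSs", length(reference_cds))
  }
  if (length(reference_cds) < 1L) stop("empty reference set")
  counts <- table(factor(unlist(lapply(reference_cds, split_codons)),
                         levels = all_codons()))
  fams <- codon_families()
  w <- setNames(numeric(0), character(0))
  for (aa in names(fams)) {
    cods <- fams[[aa]]
    cnt <- as.numeric(counts[cods])
    if (all(cnt == 0)) {
      w[cods] <- 1  # unobserved family: no information, all weights 1
      next
    }
    cnt[cnt == 0] <- 0.5
    w[cods] <- cnt / max(cnt)
  }
  structure(w[sense_codons()], class = "codon_weights", reference = desc)
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative-adaptiveness weights of the gene's
#' codons; ATG (Met), TGG (Trp) and stop codons carry no usage
#' information and are excluded from the average.
#'
#' @param cds coding-sense nucleotide CDS.
#' @param weights a `codon_weights` vector from [relative_adaptiveness],
#'   or any named numeric vector over codons.
#' @return list with `cai` and `n_codons_used`.
#' @export
cai <- function(cds, weights) {
  cods <- split_codons(cds)
  excl <- c("ATG", "TGG", stop_codons())
  cods <- cods[!cods %in% excl & cods %in% names(weights)]
  if (!length(cods)) stop("no codons usable for CAI in this CDS")
  lw <- log(weights[cods])
  list(cai = exp(mean(lw)), n_codons_used = length(cods))
}

#' CAI of every intact CDS in a genome
#'
#' @param g a [genome].
#' @param weights from [relative_adaptiveness]; by default computed from
#'   the genome's own ribosomal-protein CDSs.
#' @return data.frame: locus_tag, product, cai, n_codons_used, sorted by
#'   decreasing CAI.
#' @export
cai_table <- function(g, weights = NULL) {
  if (is.null(weights)) weights <- relative_adaptiveness(g)
  f <- g$features
  sel <- which(f$type == "CDS" & !f$pseudo)
  rows <- lapply(sel, function(i) {
    r <- cai(extract_cds(g, f$locus_tag[i]), weights)
    data.frame(locus_tag = f$locus_tag[i], product = f$product[i],
               cai = r$cai, n_codons_used = r$n_codons_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cai), ]
  rownames(out) <- NULL
  out
}
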