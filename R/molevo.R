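#' Codon-aware alignment of two coding sequences
#'
#' The two CDSs are translated, globally aligned at the protein level
#' (Needleman-Wunsch, BLOSUM62, affine gaps) and the alignment is
#' back-threaded to codons. Gap columns are dropped; terminal stop codons
#' are excluded.
#'
#' @param cds_a,cds_b coding-sense nucleotide CDSs (translatable, length
#'   divisible by 3).
#' @param criteria a [homology_criteria] supplying matrix and gap
#'   penalties.
#' @return object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (character vectors of paired codons), `n_codons`, and
#'   `gapped` (TRUE if the protein alignment contained gap columns).
#' @export
codon_align <- function(cds_a, cds_b, criteria = homology_criteria()) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  if (!nzchar(pa) || !nzchar(pb)) stop("untranslatable CDS")
  if (nchar(cds_a) == nchar(cds_b)) {
    # equal-length CDSs pair codon by codon; no protein alignment needed
    return(structure(list(codons_a = split_codons(cds_a)[seq_len(nchar(pa))],
                          codons_b = split_codons(cds_b)[seq_len(nchar(pb))],
                          n_codons = nchar(pa), gapped = FALSE),
                     class = "codon_alignment"))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = subst_matrix(criteria$matrix),
    gapOpening = criteria$gap_open, gapExtension = criteria$gap_extend,
    type = "global")
  if (as.numeric(Biostrings::score(al)) <= 0 && nchar(pa) > 5 && nchar(pb) > 5)
    warning("protein alignment has non-positive score; sequences may be unrelated")
  sa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ca <- split_codons(cds_a)[seq_len(nchar(pa))]
  cb <- split_codons(cds_b)[seq_len(nchar(pb))]
  ia <- 0L; ib <- 0L
  keep_a <- integer(0); keep_b <- integer(0)
  gapped <- FALSE
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) { gapped <- TRUE; next }
    keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
  }
  structure(list(codons_a = ca[keep_a], codons_b = cb[keep_b],
                 n_codons = length(keep_a), gapped = gapped),
            class = "codon_alignment")
}

# ---- NG86 lookup tables ---------------------------------------------------

# Synonymous site count of a codon: over the three positions, the
# fraction of the three possible single-base changes that are synonymous.
# Changes creating a stop codon count as nonsynonymous opportunity.
ng86_site_table <- function() {
  tab <- .pangcn_cache$ng86_sites
  if (!is.null(tab)) return(tab)
  gc <- genetic_code11()
  bases <- c("A", "C", "G", "T")
  sense <- sense_codons()
  s <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    tot <- 0
    for (pos in 1:3) {
      oldb <- substring(cod, pos, pos)
      for (nb in setdiff(bases, oldb)) {
        new <- cod
        substring(new, pos, pos) <- nb
        if (gc[[new]] != "*" && gc[[new]] == gc[[cod]]) tot <- tot + 1
      }
    }
    s[cod] <- tot / 3
  }
  .pangcn_cache$ng86_sites <- s
  s
}

# Average syn/nonsyn difference counts between codon pairs over all
# shortest mutation paths; paths passing through a stop codon are
# excluded from the average (when every path is blocked, all paths are
# used as a fallback).
ng86_path_counts <- function(codon_a, codon_b) {
  gc <- genetic_code11()
  diffs <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  nd <- length(diffs)
  if (nd == 0L) return(c(nd = 0, sd = 0))
  perms <- if (nd == 1L) list(diffs) else {
    if (nd == 2L) list(diffs, rev(diffs)) else {
      p <- list()
      for (i in 1:3) for (j in 1:3) if (i != j)
        p[[length(p) + 1L]] <- c(diffs[i], diffs[j], diffs[setdiff(1:3, c(i, j))])
      p
    }
  }
  count_path <- function(ord) {
    cur <- codon_a
    syn <- 0; non <- 0
    for (pos in ord) {
      nxt <- cur
      substring(nxt, pos, pos) <- substring(codon_b, pos, pos)
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(non, syn)
  }
  res <- lapply(perms, count_path)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # all paths pass through stops: fall back to counting through them
    count_any <- function(ord) {
      cur <- codon_a; syn <- 0; non <- 0
      for (pos in ord) {
        nxt <- cur
        substring(nxt, pos, pos) <- substring(codon_b, pos, pos)
        if (gc[[nxt]] != "*" && gc[[nxt]] == gc[[cur]]) syn <- syn + 1
        else non <- non + 1
        cur <- nxt
      }
      c(non, syn)
    }
    res <- lapply(perms, count_any)
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(nd = mean(m[, 1]), sd = mean(m[, 2]))
}

# 61 x 61 lookup of averaged path counts, built once
ng86_pair_tables <- function() {
  tabs <- .pangcn_cache$ng86_pairs
  if (!is.null(tabs)) return(tabs)
  sense <- sense_codons()
  n <- length(sense)
  ndm <- matrix(0, n, n, dimnames = list(sense, sense))
  sdm <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cnt <- ng86_path_counts(sense[i], sense[j])
    ndm[i, j] <- cnt[["nd"]]; sdm[i, j] <- cnt[["sd"]]
  }
  tabs <- list(nd = ndm, sd = sdm)
  .pangcn_cache$ng86_pairs <- tabs
  tabs
}

#' Nei-Gojobori (1986) dN/dS for a codon alignment
#'
#' Counting estimator: expected synonymous (S) and nonsynonymous (N)
#' sites are per-codon fractions of single-base changes, averaged over
#' the two sequences; observed differences are averaged over all
#' stop-free shortest mutation paths between each codon pair; the
#' proportions pN = Nd/N and pS = Sd/S receive the Jukes-Cantor
#' multiple-hit correction d = -(3/4) log(1 - 4p/3).
#'
#' @param ca a `codon_alignment` from [codon_align], or a list with
#'   `codons_a` and `codons_b`.
#' @return object of class `dnds`: list with `N`, `S`, `Nd`, `Sd`, `pN`,
#'   `pS`, `dN`, `dS`, `omega` and `flags` (character vector; may contain
#'   `"omega_undefined"` when dS = 0 and `"saturated"` when a proportion
#'   reaches 3/4 so the correction is undefined).
#' @export
ng86_dnds <- function(ca) {
  a <- ca$codons_a; b <- ca$codons_b
  stopifnot(length(a) == length(b), length(a) >= 1L)
  sense <- sense_codons()
  keep <- a %in% sense & b %in% sense
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no comparable sense codons in alignment")
  st <- ng86_site_table()
  S <- (sum(st[a]) + sum(st[b])) / 2
  N <- 3 * length(a) - S
  pt <- ng86_pair_tables()
  Nd <- sum(pt$nd[cbind(a, b)])
  Sd <- sum(pt$sd[cbind(a, b)])
  pN <- Nd / N
  pS <- Sd / S
  flags <- character(0)
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN); dS <- jc(pS)
  if (is.na(dN) || is.na(dS)) flags <- c(flags, "saturated")
  omega <- NA_real_
  if (!is.na(dN) && !is.na(dS)) {
    if (dS == 0) flags <- c(flags, "omega_undefined") else omega <- dN / dS
  }
  structure(list(n_codons = length(a), N = N, S = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                 flags = flags),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf(
    "NG86: %d codons | N=%.2f S=%.2f | Nd=%.2f Sd=%.2f | dN=%s dS=%s omega=%s%s\n",
    x$n_codons, x$N, x$S, x$Nd, x$Sd,
    formatC(x$dN, digits = 4, format = "f"),
    formatC(x$dS, digits = 4, format = "f"),
    if (is.na(x$omega)) "undef" else formatC(x$omega, digits = 3, format = "f"),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' dN/dS of many CDS pairs
#'
#' @param pairs data.frame with columns `tag_a`, `tag_b`.
#' @param genome_a,genome_b [genome] objects the tags refer to.
#' @param criteria alignment criteria for [codon_align].
#' @return data.frame: tags plus N, S, Nd, Sd, dN, dS, omega, flags.
#' @export
dnds_pairs <- function(pairs, genome_a, genome_b,
                       criteria = homology_criteria()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fa <- genome_a$features; fb <- genome_b$features
    pa <- fa$pseudo[match(pairs$tag_a[i], fa$locus_tag)]
    pb <- fb$pseudo[match(pairs$tag_b[i], fb$locus_tag)]
    if (isTRUE(pa) || isTRUE(pb)) return(NULL)
    r <- tryCatch(
      ng86_dnds(codon_align(extract_cds(genome_a, pairs$tag_a[i]),
                            extract_cds(genome_b, pairs$tag_b[i]), criteria)),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(tag_a = pairs$tag_a[i], tag_b = pairs$tag_b[i],
               n_codons = r$n_codons, N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
               dN = r$dN, dS = r$dS, omega = r$omega,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(tag_a = character(), tag_b = character(),
                      n_codons = integer(), N = numeric(), S = numeric(),
                      Nd = numeric(), Sd = numeric(), dN = numeric(),
                      dS = numeric(), omega = numeric(), flags = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Per-category evolutionary rate summary
#'
#' Arithmetic means of dN, dS and omega per label (undefined values
#' excluded), with a two-sided Mann-Whitney U test of each label's omega
#' values against the complement.
#'
#' @param results data.frame from [dnds_pairs] (needs `dN`, `dS`,
#'   `omega`).
#' @param labels character vector of category labels, one per row.
#' @return data.frame per label: n, mean_dN, mean_dS, mean_omega,
#'   p_value.
#' @export
category_rates <- function(results, labels) {
  stopifnot(nrow(results) == length(labels))
  labs <- unique(labels)
  rows <- lapply(labs, function(L) {
    inL <- labels == L
    if (!any(is.finite(results$dN[inL]))) {
      warning("label '", L, "' has no defined rates; excluded")
      return(NULL)
    }
    om_in <- results$omega[inL & !is.na(results$omega)]
    om_out <- results$omega[!inL & !is.na(results$omega)]
    p <- if (length(om_in) && length(om_out)) {
      suppressWarnings(wilcox.test(om_in, om_out, exact = FALSE)$p.value)
    } else NA_real_
    data.frame(label = L, n = sum(inL),
               mean_dN = mean(results$dN[inL], na.rm = TRUE),
               mean_dS = mean(results$dS[inL], na.rm = TRUE),
               mean_omega = if (length(om_in)) mean(om_in) else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
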