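#' Classify the nucleotide relationship of an ortholog pair
#'
#' `identical` if the CDSs are equal; otherwise a codon-aware alignment
#' is made: with equal lengths and no gaps, the pair is
#' `synonymous_only` when every substituted codon encodes the same amino
#' acid and `amino_acid_changing` otherwise; any alignment gap or length
#' difference yields `indel`.
#'
#' @param cds_a,cds_b coding-sense nucleotide CDSs.
#' @param criteria alignment parameters for [codon_align].
#' @return one of "identical", "synonymous_only", "amino_acid_changing",
#'   "indel".
#' @export
classify_ortholog_pair <- function(cds_a, cds_b,
                                   criteria = homology_criteria()) {
  if (identical(toupper(cds_a), toupper(cds_b))) return("identical")
  if (nchar(cds_a) != nchar(cds_b)) return("indel")
  ca <- codon_align(cds_a, cds_b, criteria)
  if (ca$gapped) return("indel")
  diff <- ca$codons_a != ca$codons_b
  if (!any(diff)) {
    # differences confined to the terminal stop codon
    return("synonymous_only")
  }
  gc <- genetic_code11()
  if (all(gc[ca$codons_a[diff]] == gc[ca$codons_b[diff]]))
    "synonymous_only" else "amino_acid_changing"
}

#' Three-way pan-genome partition
#'
#' Core families are locus-tag triples consistent across the three
#' pairwise reciprocal-best-hit maps (a-b, a-c and b-c all present and
#' mutually agreeing). Inconsistent triangles are resolved conservatively
#' by dropping the weakest-scoring edge. Genes in a surviving pair but in
#' no core triple are pairwise shared; unpaired genes are strain
#' specific, subdivided into unique versus duplicated (member of a
#' within-strain paralog family).
#'
#' @param g1,g2,g3 [genome] objects.
#' @param rbh_12,rbh_13,rbh_23 reciprocal-best-hit tables from
#'   [reciprocal_best_hits] computed under one criteria set (tag_a from
#'   the first genome of each pair).
#' @param criteria criteria used for the paralog-family subdivision.
#' @param paralogs optional precomputed list of paralog family lists
#'   (names g1/g2/g3) to avoid recomputation.
#' @return object of class `pan_partition`: list with `core`
#'   (data.frame tag_1/tag_2/tag_3), `pairwise` (list of data.frames
#'   `g1_g2`, `g1_g3`, `g2_g3` of non-core pairs), `specific` (list per
#'   genome: data.frame tag/duplicated), and `counts` (named list of
#'   Venn sector sizes).
#' @export
three_way_partition <- function(g1, g2, g3, rbh_12, rbh_13, rbh_23,
                                criteria = homology_criteria(),
                                paralogs = NULL) {
  ids <- c(g1$id, g2$id, g3$id)
  if (anyDuplicated(ids)) stop("genomes must have distinct ids")
  tags1 <- g1$features$locus_tag[g1$features$type == "CDS"]
  tags2 <- g2$features$locus_tag[g2$features$type == "CDS"]
  tags3 <- g3$features$locus_tag[g3$features$type == "CDS"]
  chk <- function(rbh, ta, tb, nm) {
    if (nrow(rbh) && (!all(rbh$tag_a %in% ta) || !all(rbh$tag_b %in% tb)))
      stop("RBH table ", nm, " does not match the supplied genomes")
  }
  chk(rbh_12, tags1, tags2, "rbh_12")
  chk(rbh_13, tags1, tags3, "rbh_13")
  chk(rbh_23, tags2, tags3, "rbh_23")

  m12 <- setNames(rbh_12$tag_b, rbh_12$tag_a)
  m13 <- setNames(rbh_13$tag_b, rbh_13$tag_a)
  m23 <- setNames(rbh_23$tag_b, rbh_23$tag_a)
  s12 <- setNames(rbh_12$score, rbh_12$tag_a)
  s13 <- setNames(rbh_13$score, rbh_13$tag_a)
  s23 <- setNames(rbh_23$score, rbh_23$tag_a)

  core <- data.frame(tag_1 = character(), tag_2 = character(),
                     tag_3 = character(), stringsAsFactors = FALSE)
  drop12 <- character(0); drop13 <- character(0); drop23 <- character(0)
  for (a in names(m12)) {
    b <- m12[[a]]
    cc <- m13[a]; cc2 <- m23[b]
    if (!is.na(cc) && !is.na(cc2) && cc == cc2) {
      core <- rbind(core, data.frame(tag_1 = a, tag_2 = b, tag_3 = unname(cc),
                                     stringsAsFactors = FALSE))
    } else if (!is.na(cc) && !is.na(cc2) && cc != cc2) {
      # inconsistent triangle: drop the weakest of the three edges
      sc <- c(ab = s12[[a]], ac = s13[[a]], bc = s23[[b]])
      weakest <- names(sc)[which.min(sc)]
      if (weakest == "ab") drop12 <- c(drop12, a)
      else if (weakest == "ac") drop13 <- c(drop13, a)
      else drop23 <- c(drop23, b)
    }
  }
  pair12 <- rbh_12[!rbh_12$tag_a %in% c(core$tag_1, drop12), , drop = FALSE]
  pair13 <- rbh_13[!rbh_13$tag_a %in% c(core$tag_1, drop13), , drop = FALSE]
  pair23 <- rbh_23[!rbh_23$tag_a %in% c(core$tag_2, drop23), , drop = FALSE]
  pair12 <- pair12[!pair12$tag_b %in% core$tag_2, , drop = FALSE]
  pair13 <- pair13[!pair13$tag_b %in% core$tag_3, , drop = FALSE]
  pair23 <- pair23[!pair23$tag_b %in% core$tag_3, , drop = FALSE]

  paired1 <- unique(c(core$tag_1, pair12$tag_a, pair13$tag_a))
  paired2 <- unique(c(core$tag_2, pair12$tag_b, pair23$tag_a))
  paired3 <- unique(c(core$tag_3, pair13$tag_b, pair23$tag_b))

  if (is.null(paralogs))
    paralogs <- list(paralog_families(g1, criteria),
                     paralog_families(g2, criteria),
                     paralog_families(g3, criteria))
  in_family <- function(tags, fams) tags %in% unlist(fams)
  spec <- list()
  for (k in 1:3) {
    tags <- list(tags1, tags2, tags3)[[k]]
    paired <- list(paired1, paired2, paired3)[[k]]
    st <- setdiff(tags, paired)
    spec[[ids[k]]] <- data.frame(
      tag = st, duplicated = in_family(st, paralogs[[k]]),
      stringsAsFactors = FALSE)
  }

  counts <- list(core = nrow(core),
                 shared_12 = nrow(pair12), shared_13 = nrow(pair13),
                 shared_23 = nrow(pair23),
                 specific = setNames(vapply(spec, nrow, integer(1)), ids))
  structure(list(core = core,
                 pairwise = list(g1_g2 = pair12, g1_g3 = pair13,
                                 g2_g3 = pair23),
                 specific = spec, ids = ids, counts = counts),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf("Pan-genome partition of %s / %s / %s\n",
              x$ids[1], x$ids[2], x$ids[3]))
  cat(sprintf("  core families:   %d\n", x$counts$core))
  cat(sprintf("  pairwise shared: %d (1-2), %d (1-3), %d (2-3)\n",
              x$counts$shared_12, x$counts$shared_13, x$counts$shared_23))
  cat(sprintf("  strain-specific: %s\n",
              paste(sprintf("%s=%d", names(x$counts$specific),
                            x$counts$specific), collapse = ", ")))
  invisible(x)
}

#' Variant classes of the ortholog pairs of a partition
#'
#' @param partition a `pan_partition`.
#' @param genomes named list of the three [genome] objects (names = ids).
#' @return data.frame: strain_a, strain_b, tag_a, tag_b, variant_class
#'   for every core and pairwise ortholog pair.
#' @export
partition_variant_classes <- function(partition, genomes) {
  ids <- partition$ids
  mk <- function(sa, sb, ta, tb) {
    n <- length(ta)
    data.frame(strain_a = rep(sa, n), strain_b = rep(sb, n),
               tag_a = ta, tag_b = tb, stringsAsFactors = FALSE)
  }
  pairs <- rbind(
    mk(ids[1], ids[2], partition$core$tag_1, partition$core$tag_2),
    mk(ids[1], ids[3], partition$core$tag_1, partition$core$tag_3),
    mk(ids[2], ids[3], partition$core$tag_2, partition$core$tag_3),
    mk(ids[1], ids[2], partition$pairwise$g1_g2$tag_a,
       partition$pairwise$g1_g2$tag_b),
    mk(ids[1], ids[3], partition$pairwise$g1_g3$tag_a,
       partition$pairwise$g1_g3$tag_b),
    mk(ids[2], ids[3], partition$pairwise$g2_g3$tag_a,
       partition$pairwise$g2_g3$tag_b))
  cls <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- genomes[[pairs$strain_a[i]]]; gb <- genomes[[pairs$strain_b[i]]]
    fa <- ga$features; fb <- gb$features
    pa <- fa$pseudo[match(pairs$tag_a[i], fa$locus_tag)]
    pb <- fb$pseudo[match(pairs$tag_b[i], fb$locus_tag)]
    if (isTRUE(pa) || isTRUE(pb)) { cls[i] <- "indel"; next }
    cls[i] <- tryCatch(
      classify_ortholog_pair(extract_cds(ga, pairs$tag_a[i]),
                             extract_cds(gb, pairs$tag_b[i])),
      error = function(e) "indel")
  }
  pairs$variant_class <- cls
  pairs
}

#' Read a pathway definition (ordered steps of alternative EC numbers)
#'
#' The packaged lysine biosynthesis pathway (L-aspartate to L-lysine,
#' nine enzymatic steps, with the acetyl / succinyl transferase
#' alternatives at step five) ships as
#' `system.file("extdata", "lysine_pathway.tsv", package = "pangcn")`.
#'
#' @param path TSV with columns `step`, `gene`, `ec` (alternatives
#'   separated by `|`).
#' @return object of class `pathway_definition`.
#' @export
read_pathway <- function(path = system.file("extdata", "lysine_pathway.tsv",
                                            package = "pangcn")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("step", "gene", "ec") %in% names(df)))
  if (!nrow(df)) stop("empty pathway definition")
  ecs <- strsplit(df$ec, "|", fixed = TRUE)
  ok <- vapply(unlist(ecs), function(e)
    grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", e), logical(1))
  if (!all(ok)) stop("malformed EC number(s): ",
                     paste(unlist(ecs)[!ok], collapse = ", "))
  structure(list(name = attr(df, "name") %||% "pathway",
                 steps = setNames(ecs, df$gene)),
            class = "pathway_definition")
}

#' Pathway presence matrix across genomes
#'
#' A step is present in a genome iff any feature carries an EC number in
#' the step's alternative set; completeness is the number of present
#' steps.
#'
#' @param genomes named list of [genome] objects.
#' @param pathway a `pathway_definition` from [read_pathway].
#' @return list with `matrix` (logical, strains x steps) and
#'   `completeness` (named integer vector).
#' @export
pathway_presence <- function(genomes, pathway = read_pathway()) {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (!length(pathway$steps)) stop("empty pathway")
  ids <- vapply(genomes, function(g) g$id, character(1))
  m <- matrix(FALSE, length(genomes), length(pathway$steps),
              dimnames = list(ids, names(pathway$steps)))
  for (i in seq_along(genomes)) {
    ecs <- unlist(strsplit(genomes[[i]]$features$ec, ","))
    ecs <- ecs[nzchar(ecs)]
    for (j in seq_along(pathway$steps))
      m[i, j] <- any(pathway$steps[[j]] %in% ecs)
  }
  list(matrix = m, completeness = rowSums(m))
}
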