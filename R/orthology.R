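#' Homology acceptance criteria
#'
#' Thresholds a pairwise protein alignment must pass to count as a
#' homology hit: minimum percent identity over aligned columns and
#' minimum coverage of the shorter protein, under a named substitution
#' matrix with affine gap penalties. The 40% / 0.7 defaults are a common
#' best-bidirectional-hit standard; all values are configurable.
#'
#' @param min_identity_percent minimum identity over aligned columns.
#' @param min_coverage minimum aligned fraction of the shorter protein.
#' @param matrix substitution matrix name (from Biostrings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return a `homology_criteria` list.
#' @export
homology_criteria <- function(min_identity_percent = 40, min_coverage = 0.7,
                              matrix = "BLOSUM62", gap_open = 11,
                              gap_extend = 1) {
  stopifnot(min_identity_percent >= 0, min_identity_percent <= 100,
            min_coverage >= 0, min_coverage <= 1,
            gap_open >= 0, gap_extend >= 0)
  structure(list(min_identity_percent = min_identity_percent,
                 min_coverage = min_coverage, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "homology_criteria")
}

subst_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  m <- .pangcn_cache[[key]]
  if (is.null(m)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    .pangcn_cache[[key]] <- m
  }
  m
}

#' Align two proteins (Smith-Waterman, affine gaps)
#'
#' Local alignment under the criteria's substitution matrix and gap
#' penalties. Identity is computed over aligned columns, coverage as the
#' aligned span over each protein's length.
#'
#' @param a,b protein strings.
#' @param criteria a [homology_criteria] (matrix and gap penalties used;
#'   thresholds are not applied here).
#' @param type "local" (default) or "global".
#' @return list with `score`, `identity_percent`, `aligned_cols`,
#'   `coverage_query`, `coverage_target`.
#' @export
align_proteins <- function(a, b, criteria = homology_criteria(),
                           type = "local") {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = subst_matrix(criteria$matrix),
    gapOpening = criteria$gap_open, gapExtension = criteria$gap_extend,
    type = type)
  cols <- Biostrings::nchar(al)
  list(score = as.numeric(Biostrings::score(al)),
       identity_percent = if (cols > 0) Biostrings::pid(al) else 0,
       aligned_cols = cols,
       coverage_query = (Biostrings::width(Biostrings::pattern(al))) / nchar(a),
       coverage_target = (Biostrings::width(Biostrings::subject(al))) / nchar(b))
}

# ---- k-mer prefiltered hit search ----------------------------------------

protein_kmers <- function(x, k = 5L) {
  n <- nchar(x)
  if (n < k) return(x)
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# For each query protein, candidate targets ranked by shared-kmer count.
kmer_candidates <- function(query, target, k = 5L, top_n = 5L) {
  tk <- lapply(target, protein_kmers, k = k)
  index <- split(rep(seq_along(target), lengths(tk)), unlist(tk))
  lapply(query, function(q) {
    qk <- protein_kmers(q, k)
    hits <- unlist(index[qk], use.names = FALSE)
    if (is.null(hits) || !length(hits)) return(integer(0))
    tab <- sort(table(hits), decreasing = TRUE)
    as.integer(names(tab))[seq_len(min(top_n, length(tab)))]
  })
}

# Align each query against its candidate targets (one batched
# pairwiseAlignment call over all query/candidate pairs); returns a
# data.frame of hits passing the criteria.
protein_hits <- function(query, target, criteria = homology_criteria(),
                         prefilter = TRUE, top_n = 5L, keep_all = FALSE) {
  empty <- data.frame(tag_q = character(), tag_t = character(),
                      score = numeric(), identity = numeric(),
                      coverage_q = numeric(), coverage_t = numeric(),
                      t_start = integer(), t_end = integer(),
                      stringsAsFactors = FALSE)
  if (!length(query) || !length(target)) return(empty)
  stopifnot(!is.null(names(query)), !is.null(names(target)))
  cand <- if (prefilter) kmer_candidates(query, target, top_n = top_n)
          else rep(list(seq_along(target)), length(query))
  qi <- rep(seq_along(query), lengths(cand))
  ti <- unlist(cand, use.names = FALSE)
  if (!length(qi)) return(empty)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(target[ti]),
    Biostrings::AAStringSet(query[qi]),
    substitutionMatrix = subst_matrix(criteria$matrix),
    gapOpening = criteria$gap_open, gapExtension = criteria$gap_extend,
    type = "local")
  cols <- Biostrings::nchar(al)
  ident <- ifelse(cols > 0, suppressWarnings(Biostrings::pid(al)), 0)
  qlen <- nchar(query)[qi]; tlen <- nchar(target)[ti]
  cov_q <- Biostrings::width(Biostrings::subject(al)) / qlen
  cov_t <- Biostrings::width(Biostrings::pattern(al)) / tlen
  cov_short <- ifelse(qlen <= tlen, cov_q, cov_t)
  ok <- !is.na(ident) & ident >= criteria$min_identity_percent &
    cov_short >= criteria$min_coverage
  if (keep_all) ok <- rep(TRUE, length(ok))
  if (!any(ok)) return(empty)
  data.frame(
    tag_q = names(query)[qi][ok], tag_t = names(target)[ti][ok],
    score = as.numeric(Biostrings::score(al))[ok],
    identity = ident[ok], coverage_q = cov_q[ok], coverage_t = cov_t[ok],
    t_start = Biostrings::start(Biostrings::pattern(al))[ok],
    t_end = Biostrings::end(Biostrings::pattern(al))[ok],
    stringsAsFactors = FALSE)
}

#' Best protein hit of every query gene in a target genome
#'
#' For each query protein, the highest-scoring target protein passing the
#' criteria; ties are broken by higher identity, then lexicographic
#' target tag. Pseudogenes take part through their longest open reading
#' frame (>= 50 codons).
#'
#' @param genome_q,genome_t [genome] objects (or named protein vectors).
#' @param criteria a [homology_criteria].
#' @param prefilter use the shared k-mer prefilter (exact search when
#'   FALSE).
#' @param top_n candidates per query to align under the prefilter.
#' @return named character vector mapping query tags to target tags;
#'   queries without a passing hit are absent.
#' @export
best_hits <- function(genome_q, genome_t, criteria = homology_criteria(),
                      prefilter = TRUE, top_n = 5L) {
  pq <- if (inherits(genome_q, "genome")) proteome(genome_q) else genome_q
  pt <- if (inherits(genome_t, "genome")) proteome(genome_t) else genome_t
  hits <- protein_hits(pq, pt, criteria, prefilter = prefilter, top_n = top_n)
  if (!nrow(hits)) return(setNames(character(0), character(0)))
  hits <- hits[order(hits$tag_q, -hits$score, -hits$identity, hits$tag_t), ]
  best <- hits[!duplicated(hits$tag_q), ]
  setNames(best$tag_t, best$tag_q)
}

#' Reciprocal-best-hit ortholog pairs between two genomes
#'
#' A pair (a, b) is kept iff a's best hit in genome 2 is b and b's best
#' hit in genome 1 is a, the operational ortholog definition of
#' best-bidirectional-hit comparative genomics.
#'
#' @param g1,g2 [genome] objects (or named protein vectors).
#' @param criteria a [homology_criteria].
#' @param prefilter,top_n passed to [best_hits].
#' @return data.frame with columns `tag_a`, `tag_b`, `score`, `identity`,
#'   `coverage_a`, `coverage_b`, sorted by `tag_a`.
#' @export
reciprocal_best_hits <- function(g1, g2, criteria = homology_criteria(),
                                 prefilter = TRUE, top_n = 5L) {
  p1 <- if (inherits(g1, "genome")) proteome(g1) else g1
  p2 <- if (inherits(g2, "genome")) proteome(g2) else g2
  h12 <- protein_hits(p1, p2, criteria, prefilter = prefilter, top_n = top_n)
  empty <- data.frame(tag_a = character(), tag_b = character(),
                      score = numeric(), identity = numeric(),
                      coverage_a = numeric(), coverage_b = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(h12)) return(empty)
  h12 <- h12[order(h12$tag_q, -h12$score, -h12$identity, h12$tag_t), ]
  b12 <- h12[!duplicated(h12$tag_q), ]
  b21 <- best_hits(p2, p1, criteria, prefilter = prefilter, top_n = top_n)
  keep <- !is.na(b21[b12$tag_t]) & b21[b12$tag_t] == b12$tag_q
  keep[is.na(keep)] <- FALSE
  out <- data.frame(tag_a = b12$tag_q[keep], tag_b = b12$tag_t[keep],
                    score = b12$score[keep], identity = b12$identity[keep],
                    coverage_a = b12$coverage_q[keep],
                    coverage_b = b12$coverage_t[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_a), ]
  rownames(out) <- NULL
  out
}

#' Within-genome paralog families
#'
#' Single-linkage clustering of within-genome protein hits passing the
#' criteria (self hits excluded); only families of two or more members
#' are reported.
#'
#' @param g a [genome] (or named protein vector).
#' @param criteria a [homology_criteria].
#' @param prefilter,top_n passed to the hit search.
#' @return list of character vectors of locus tags (each a family,
#'   sorted), ordered by first member.
#' @export
paralog_families <- function(g, criteria = homology_criteria(),
                             prefilter = TRUE, top_n = 8L) {
  p <- if (inherits(g, "genome")) proteome(g) else g
  if (length(p) < 2L) return(list())
  hits <- protein_hits(p, p, criteria, prefilter = prefilter, top_n = top_n)
  hits <- hits[hits$tag_q != hits$tag_t, , drop = FALSE]
  if (!nrow(hits)) return(list())
  tags <- names(p)
  parent <- seq_along(tags)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(hits))) {
    i <- find(match(hits$tag_q[r], tags)); j <- find(match(hits$tag_t[r], tags))
    if (i != j) parent[j] <- i
  }
  roots <- vapply(seq_along(tags), find, integer(1))
  fams <- split(tags, roots)
  fams <- fams[lengths(fams) >= 2L]
  fams <- lapply(fams, sort)
  fams[order(vapply(fams, `[`, character(1), 1L))]
}

#' Write an ortholog table as TSV
#' @param pairs data.frame from [reciprocal_best_hits].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_orthologs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
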