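#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns where either sequence has a gap or an ambiguous base are
#' removed pairwise; p is the mismatch fraction over the remaining
#' columns and d = -(3/4) log(1 - 4p/3).
#'
#' @param aligned_a,aligned_b equal-length aligned DNA strings.
#' @return numeric distance.
#' @export
jc_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length")
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable columns")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75) stop("p = ", round(p, 3), " >= 3/4: JC distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix for a set of aligned sequences
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- jc_distance(seqs[[i]], seqs[[j]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch-length estimates
#' are clamped to zero and flagged.
#'
#' @param d symmetric numeric matrix with labeled rows/columns, or a
#'   `dist`.
#' @return an `ape::phylo` tree (unrooted); attribute
#'   `negative_branches` gives the number of clamped edges.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  tr <- ape::nj(stats::as.dist(d))
  neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_branches") <- neg
  tr
}

#' Bootstrap support for the splits of a tree
#'
#' Generic resampling harness: `resampler(i)` must return the input for
#' replicate i and `builder(x)` must turn it into an `ape::phylo`;
#' support is the percentage of replicate trees containing each internal
#' split of the reference tree.
#'
#' @param tree reference `phylo`.
#' @param resampler function(i) producing replicate input.
#' @param builder function(x) producing a replicate tree.
#' @param n number of replicates.
#' @param seed RNG seed (resampler draws happen under it).
#' @return the tree with `node.label` set to supports (0-100, rounded to
#'   1 decimal); attribute `replicates` holds the replicate trees.
#' @export
bootstrap_support <- function(tree, resampler, builder, n = 100L, seed = 1L) {
  stopifnot(n >= 1L)
  reps <- with_seed(seed, lapply(seq_len(n), function(i) builder(resampler(i))))
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  supports <- round(100 * cnt / n, 1)
  tree$node.label <- as.character(supports)
  attr(tree, "replicates") <- reps
  attr(tree, "supports") <- supports
  tree
}

#' Write / read Newick
#'
#' Thin wrappers around ape's Newick I/O so trees round-trip with
#' support labels and 6-significant-digit branch lengths.
#'
#' @param tree a `phylo`.
#' @param path file path (optional for [write_newick]; when missing the
#'   Newick string is returned).
#' @return [write_newick]: the Newick string, invisibly if written to a
#'   file. [read_newick]: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  tree$edge.length <- signif(tree$edge.length, 6)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) {
    ape::read.tree(path)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("malformed Newick input")
  unquote <- function(x) gsub("^'(.*)'$", "\\1", x)
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}

# unrooted split set of a tree as canonical strings, for topology
# comparison in tests and recovery rates
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  out <- character(0)
  for (p in bp) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) < 2L || length(other) < 2L) next
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

#' Do two trees share the same unrooted topology?
#' @param t1,t2 `phylo` objects over the same tip set.
#' @return TRUE/FALSE.
#' @export
same_topology <- function(t1, t2) {
  setequal(sort(t1$tip.label), sort(t2$tip.label)) &&
    setequal(tree_splits(t1), tree_splits(t2))
}
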