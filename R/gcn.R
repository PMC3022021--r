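#' Genome-context-network parameters
#'
#' Edge rules for the three evidence channels and the network distance.
#'
#' @param max_hamming profile channel: maximum Hamming distance between
#'   two genes' presence/absence vectors (computed on informative
#'   vectors, i.e. neither all-zero nor all-one).
#' @param profile_rule "hamming" or "mi" (mutual information >= `min_mi`
#'   nats).
#' @param min_mi threshold for the mutual-information rule.
#' @param window neighbor channel: maximum separation, in genes along
#'   the (circular) panel genome, between the two genes' homologs.
#' @param min_support neighbor channel: minimum number of panel genomes
#'   in which the adjacency is observed.
#' @param max_fusion_overlap fusion channel: maximum allowed overlap
#'   between the two alignment footprints on the panel protein, as a
#'   fraction of either footprint.
#' @param restrict_distance if TRUE the network distance is computed only
#'   over edges whose endpoints are ortholog-mapped in both strains; by
#'   default unmappable edges count as disagreements, so gene-content
#'   differences contribute signal.
#' @param criteria a [homology_criteria] for strain-vs-panel mapping.
#' @return a `gcn_params` list.
#' @export
gcn_params <- function(max_hamming = 1L, profile_rule = c("hamming", "mi"),
                       min_mi = 0.3, window = 3L, min_support = 2L,
                       max_fusion_overlap = 0.1, restrict_distance = FALSE,
                       criteria = homology_criteria()) {
  structure(list(max_hamming = as.integer(max_hamming),
                 profile_rule = match.arg(profile_rule), min_mi = min_mi,
                 window = as.integer(window),
                 min_support = as.integer(min_support),
                 max_fusion_overlap = max_fusion_overlap,
                 restrict_distance = isTRUE(restrict_distance),
                 criteria = criteria),
            class = "gcn_params")
}

#' Homology evidence of one strain against a reference panel
#'
#' Maps every strain protein onto each panel genome (best hit under the
#' criteria) and records, per panel genome: presence, the position of the
#' hit gene in the panel genome's circular gene order, and candidate
#' fusion pairs (panel proteins matched by two strain genes on
#' essentially disjoint segments).
#'
#' @param strain a [genome].
#' @param panel named list of [genome] objects (>= 3).
#' @param params a [gcn_params].
#' @return a `gcn_evidence` object used by [build_gcn] and panel
#'   bootstrap.
#' @export
gcn_evidence <- function(strain, panel, params = gcn_params()) {
  if (length(panel) < 3L) stop("reference panel needs >= 3 genomes")
  if (anyDuplicated(names(panel))) stop("panel ids must be unique")
  prot <- proteome(strain)
  tags <- names(prot)
  np <- length(panel)
  presence <- matrix(FALSE, length(tags), np, dimnames = list(tags, names(panel)))
  hit_pos <- matrix(NA_integer_, length(tags), np,
                    dimnames = list(tags, names(panel)))
  panel_sizes <- integer(np)
  fusion_pairs <- vector("list", np)
  for (i in seq_len(np)) {
    pg <- panel[[i]]
    pprot <- proteome(pg)
    # circular gene order of the panel genome (all features, by start)
    cds <- pg$features[pg$features$type == "CDS", ]
    ord <- setNames(rank(cds$start, ties.method = "first"), cds$locus_tag)
    panel_sizes[i] <- nrow(cds)
    hits <- protein_hits(prot, pprot, params$criteria)
    fusion_pairs[[i]] <- matrix(character(0), ncol = 2)
    if (nrow(hits)) {
      hits <- hits[order(hits$tag_q, -hits$score, -hits$identity, hits$tag_t), ]
      best <- hits[!duplicated(hits$tag_q), ]
      presence[best$tag_q, i] <- TRUE
      hit_pos[best$tag_q, i] <- unname(ord[best$tag_t])
      # fusion: one panel protein, >= 2 strain genes, disjoint footprints
      multi <- names(which(table(best$tag_t) >= 2L))
      fp <- list()
      for (tt in multi) {
        sub <- best[best$tag_t == tt, ]
        for (u in seq_len(nrow(sub) - 1L)) for (v in (u + 1L):nrow(sub)) {
          ov <- min(sub$t_end[u], sub$t_end[v]) -
            max(sub$t_start[u], sub$t_start[v]) + 1L
          len_u <- sub$t_end[u] - sub$t_start[u] + 1L
          len_v <- sub$t_end[v] - sub$t_start[v] + 1L
          if (ov <= params$max_fusion_overlap * min(len_u, len_v))
            fp[[length(fp) + 1L]] <- sort(c(sub$tag_q[u], sub$tag_q[v]))
        }
      }
      if (length(fp))
        fusion_pairs[[i]] <- do.call(rbind, fp)
    }
  }
  structure(list(tags = tags, presence = presence, hit_pos = hit_pos,
                 panel_sizes = panel_sizes, fusion_pairs = fusion_pairs,
                 strain_id = strain$id),
            class = "gcn_evidence")
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Phylogenetic-profile edges
#' @param evidence a `gcn_evidence` (its `presence` matrix is the
#'   profile).
#' @param params a [gcn_params].
#' @param panel_idx panel genome indices to use (supports bootstrap
#'   resampling with replacement); default all.
#' @return character vector of canonical edge keys.
#' @export
profile_edges <- function(evidence, params = gcn_params(), panel_idx = NULL) {
  m <- evidence$presence
  if (!is.null(panel_idx)) m <- m[, panel_idx, drop = FALSE]
  rs <- rowSums(m)
  inf <- rs > 0L & rs < ncol(m)   # informative vectors only
  m <- m[inf, , drop = FALSE]
  if (nrow(m) < 2L) return(character(0))
  x <- 1 * m
  if (params$profile_rule == "hamming") {
    ham <- tcrossprod(x, 1 - x)
    ham <- ham + t(ham)
    sel <- which(ham <= params$max_hamming & upper.tri(ham), arr.ind = TRUE)
  } else {
    n <- ncol(x)
    mi <- matrix(0, nrow(x), nrow(x))
    for (i in seq_len(nrow(x) - 1L)) for (j in (i + 1L):nrow(x)) {
      mi[i, j] <- mutual_information(x[i, ], x[j, ])
    }
    sel <- which(mi >= params$min_mi & upper.tri(mi), arr.ind = TRUE)
  }
  if (!nrow(sel)) return(character(0))
  edge_key(rownames(m)[sel[, 1]], rownames(m)[sel[, 2]])
}

mutual_information <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (va in 0:1) for (vb in 0:1) {
    p <- sum(a == va & b == vb) / n
    if (p > 0) mi <- mi + p * log(p / ((sum(a == va) / n) * (sum(b == vb) / n)))
  }
  mi
}

#' Gene-neighbor edges
#'
#' Edge between two strain genes iff their homologs lie within `window`
#' genes of each other (circular order) in at least `min_support` panel
#' genomes.
#'
#' @inheritParams profile_edges
#' @return character vector of canonical edge keys.
#' @export
neighbor_edges <- function(evidence, params = gcn_params(), panel_idx = NULL) {
  idx <- panel_idx %||% seq_along(evidence$panel_sizes)
  support <- new.env(parent = emptyenv())
  for (i in idx) {
    pos <- evidence$hit_pos[, i]
    mapped <- which(!is.na(pos))
    if (length(mapped) < 2L) next
    n <- evidence$panel_sizes[i]
    o <- mapped[order(pos[mapped])]
    keys <- character(0)
    for (u in seq_along(o)) for (v in seq_len(length(o) - u)) {
      d <- pos[o[u + v]] - pos[o[u]]
      d <- min(d, n - d)   # circular separation
      if (d > params$window) {
        if (pos[o[u + v]] - pos[o[u]] > params$window) break
        next
      }
      if (d == 0L) next
      keys <- c(keys, edge_key(evidence$tags[o[u]], evidence$tags[o[u + v]]))
    }
    # wrap-around pairs near the origin
    tailn <- which(pos[o] > n - params$window)
    headn <- which(pos[o] <= params$window)
    for (u in tailn) for (v in headn) {
      d <- pos[o[v]] + n - pos[o[u]]
      if (d >= 1L && d <= params$window)
        keys <- c(keys, edge_key(evidence$tags[o[u]], evidence$tags[o[v]]))
    }
    for (k in unique(keys))
      assign(k, (support[[k]] %||% 0L) + 1L, envir = support)
  }
  keys <- ls(support)
  keys[vapply(keys, function(k) support[[k]] >= params$min_support, logical(1))]
}

#' Gene-fusion edges
#' @inheritParams profile_edges
#' @return character vector of canonical edge keys.
#' @export
fusion_edges <- function(evidence, params = gcn_params(), panel_idx = NULL) {
  idx <- panel_idx %||% seq_along(evidence$panel_sizes)
  keys <- character(0)
  for (i in idx) {
    fp <- evidence$fusion_pairs[[i]]
    if (length(fp) && nrow(fp))
      keys <- c(keys, edge_key(fp[, 1], fp[, 2]))
  }
  unique(keys)
}

#' Build a genome context network
#'
#' Union of the profile, neighbor and fusion edge sets with channel
#' labels retained.
#'
#' @param strain a [genome], or a precomputed `gcn_evidence`.
#' @param panel named list of panel genomes (ignored when `strain` is
#'   already evidence).
#' @param params a [gcn_params].
#' @param panel_idx optional panel resampling indices.
#' @return object of class `context_network`: list with `nodes` (strain
#'   locus tags), `edges` (data.frame tag_a, tag_b, channels) and the
#'   originating `evidence`.
#' @export
build_gcn <- function(strain, panel = NULL, params = gcn_params(),
                      panel_idx = NULL) {
  ev <- if (inherits(strain, "gcn_evidence")) strain
        else gcn_evidence(strain, panel, params)
  ch <- list(profile = profile_edges(ev, params, panel_idx),
             neighbor = neighbor_edges(ev, params, panel_idx),
             fusion = fusion_edges(ev, params, panel_idx))
  keys <- unique(unlist(ch))
  labels <- vapply(keys, function(k)
    paste(names(ch)[vapply(ch, function(e) k %in% e, logical(1))],
          collapse = ","), character(1))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    tag_a = vapply(parts, `[`, character(1), 1L),
    tag_b = vapply(parts, `[`, character(1), 2L),
    channels = unname(labels), stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$tag_a, edges$tag_b), ]
  rownames(edges) <- NULL
  structure(list(nodes = ev$tags, edges = edges, evidence = ev,
                 strain_id = ev$strain_id),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat(sprintf("<context_network> %s: %d nodes, %d edges (%s)\n",
              x$strain_id, length(x$nodes), nrow(x$edges),
              paste(names(table(x$edges$channels)), collapse = "; ")))
  invisible(x)
}

#' Distance between two genome context networks
#'
#' Edges of network a are translated into network b's tag space through
#' the ortholog map; the distance is 1 minus the Jaccard index of the
#' two edge sets. By default edges with an unmapped endpoint stay in the
#' union as automatic disagreements, so differences in gene content --
#' the phylogenetically informative part of the signal -- contribute to
#' the distance; with `params$restrict_distance` they are discarded
#' first (both conventions are available). Two empty edge sets give
#' distance 0.
#'
#' @param net_a,net_b `context_network` objects.
#' @param ortholog_map named character vector, tags of a to tags of b
#'   (e.g. from [reciprocal_best_hits]).
#' @param params a [gcn_params].
#' @return numeric in \[0, 1\].
#' @export
network_distance <- function(net_a, net_b, ortholog_map,
                             params = gcn_params()) {
  if (!length(ortholog_map)) stop("empty ortholog map: distance undefined")
  ea <- net_a$edges; eb <- net_b$edges
  ka <- character(0)
  if (nrow(ea)) {
    ma <- ortholog_map[ea$tag_a]; mb <- ortholog_map[ea$tag_b]
    mapped <- !is.na(ma) & !is.na(mb)
    ka <- c(edge_key(ma[mapped], mb[mapped]),
            if (!params$restrict_distance && any(!mapped))
              paste0("a!", edge_key(ea$tag_a[!mapped], ea$tag_b[!mapped])))
  }
  kb <- character(0)
  if (nrow(eb)) {
    if (params$restrict_distance) {
      inmap <- eb$tag_a %in% ortholog_map & eb$tag_b %in% ortholog_map
      kb <- edge_key(eb$tag_a[inmap], eb$tag_b[inmap])
    } else {
      kb <- edge_key(eb$tag_a, eb$tag_b)
    }
  }
  ka <- unique(ka); kb <- unique(kb)
  un <- union(ka, kb)
  if (!length(un)) return(0)
  1 - length(intersect(ka, kb)) / length(un)
}

#' Genome-context-network phylogeny
#'
#' Builds the context network of every strain against the panel,
#' computes all pairwise network distances, and infers a
#' neighbor-joining tree. Bootstrap resamples the panel genomes with
#' replacement (the panel is the stochastic evidence base), rebuilds
#' networks, distances and trees, and reports split frequencies.
#'
#' @param strains named list of [genome] objects (>= 3; include an
#'   outgroup for a rootable topology).
#' @param panel named list of panel genomes.
#' @param params a [gcn_params].
#' @param n_bootstrap bootstrap replicates (0 to skip).
#' @param seed RNG seed for the bootstrap resampling.
#' @return list with `tree` (`phylo`, node labels = supports),
#'   `distances` (matrix), `networks` (list of `context_network`).
#' @export
gcn_tree <- function(strains, panel, params = gcn_params(),
                     n_bootstrap = 100L, seed = 1L) {
  if (length(strains) < 3L) stop("need at least 3 strains")
  ids <- names(strains)
  if (is.null(ids) || anyDuplicated(ids)) stop("strains must be uniquely named")
  nets <- lapply(strains, build_gcn, panel = panel, params = params)
  prots <- lapply(strains, proteome)
  maps <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    rbh <- reciprocal_best_hits(prots[[i]], prots[[j]], params$criteria)
    maps[[paste(ids[i], ids[j])]] <- setNames(rbh$tag_b, rbh$tag_a)
  }
  dist_from <- function(networks) {
    d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      d[i, j] <- d[j, i] <- network_distance(
        networks[[i]], networks[[j]], maps[[paste(ids[i], ids[j])]], params)
    }
    d
  }
  d <- dist_from(nets)
  tree <- neighbor_joining(d)
  if (n_bootstrap > 0L) {
    np <- length(panel)
    evs <- lapply(nets, function(nn) nn$evidence)
    tree <- bootstrap_support(
      tree,
      resampler = function(i) sample.int(np, np, replace = TRUE),
      builder = function(idx) {
        reps <- lapply(evs, build_gcn, params = params, panel_idx = idx)
        neighbor_joining(dist_from(reps))
      },
      n = n_bootstrap, seed = seed)
  }
  list(tree = tree, distances = d, networks = nets)
}

#' Write a context network as an edge-list TSV
#' @param net a `context_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
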