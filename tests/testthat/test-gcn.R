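# hand-built evidence objects for channel-rule unit tests
mk_evidence <- function(presence, hit_pos = NULL, panel_sizes = NULL,
                        fusion = NULL) {
  np <- ncol(presence)
  structure(list(
    tags = rownames(presence),
    presence = presence,
    hit_pos = hit_pos %||% matrix(NA_integer_, nrow(presence), np,
                                  dimnames = dimnames(presence)),
    panel_sizes = panel_sizes %||% rep(10L, np),
    fusion_pairs = fusion %||% rep(list(matrix(character(0), ncol = 2)), np),
    strain_id = "T"), class = "gcn_evidence")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("profile edges connect matching informative vectors only", {
  m <- rbind(g1 = c(TRUE, TRUE, FALSE, FALSE),
             g2 = c(TRUE, TRUE, FALSE, FALSE),   # identical to g1
             g3 = c(FALSE, FALSE, TRUE, TRUE),   # complementary to g1
             g4 = c(TRUE, TRUE, TRUE, TRUE),     # uninformative (all one)
             g5 = c(TRUE, TRUE, TRUE, FALSE))    # hamming 1 from g1
  e <- profile_edges(mk_evidence(m))
  pairs <- sort(gsub("\r", "-", e))
  expect_true("g1-g2" %in% pairs)
  expect_true("g1-g5" %in% pairs)
  expect_false(any(grepl("g3", pairs) & grepl("g1", pairs)))
  expect_false(any(grepl("g4", pairs)))
})

test_that("planted co-occurrence is recovered across random profiles", {
  hits <- 0L
  for (seed in 1:20) {
    m <- withr::with_seed(seed, {
      x <- matrix(runif(20 * 8) < 0.5, 20, 8,
                  dimnames = list(sprintf("g%02d", 1:20), NULL))
      x["g01", ] <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE)
      x["g02", ] <- x["g01", ]  # planted co-occurring pair
      x
    })
    e <- profile_edges(mk_evidence(m))
    if (any(e == pangcn:::edge_key("g01", "g02"))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("neighbor edges require window proximity and panel support", {
  pos <- cbind(p1 = c(a = 5L, b = 6L, c = 50L),
               p2 = c(a = 20L, b = 22L, c = 90L),
               p3 = c(a = 7L, b = NA, c = 8L))
  pres <- !is.na(pos)
  ev <- mk_evidence(pres, hit_pos = pos, panel_sizes = c(100L, 100L, 100L))
  e <- neighbor_edges(ev, gcn_params(window = 3L, min_support = 2L))
  expect_equal(e, pangcn:::edge_key("a", "b"))
  # support threshold: requiring 3 genomes removes the edge
  e3 <- neighbor_edges(ev, gcn_params(window = 3L, min_support = 3L))
  expect_length(e3, 0L)
  # circular wrap-around counts as adjacency
  posw <- cbind(p1 = c(a = 99L, b = 2L), p2 = c(a = 99L, b = 2L),
                p3 = c(a = NA, b = 2L))
  evw <- mk_evidence(!is.na(posw), hit_pos = posw,
                     panel_sizes = c(100L, 100L, 100L))
  ew <- neighbor_edges(evw, gcn_params(window = 3L, min_support = 2L))
  expect_equal(ew, pangcn:::edge_key("a", "b"))
})

test_that("neighbor support equals a brute-force adjacency scan", {
  ev <- withr::with_seed(17, {
    np <- 5L
    pos <- matrix(sample(c(NA, 1:30), 12 * np, replace = TRUE), 12, np,
                  dimnames = list(sprintf("g%02d", 1:12), NULL))
    mk_evidence(!is.na(pos), hit_pos = pos, panel_sizes = rep(30L, np))
  })
  prm <- gcn_params(window = 2L, min_support = 2L)
  got <- sort(neighbor_edges(ev, prm))
  # oracle: enumerate all gene pairs and panel genomes directly
  want <- character(0)
  tags <- ev$tags
  for (i in 1:11) for (j in (i + 1):12) {
    sup <- 0L
    for (k in 1:5) {
      pi <- ev$hit_pos[i, k]; pj <- ev$hit_pos[j, k]
      if (is.na(pi) || is.na(pj) || pi == pj) next
      dd <- min(abs(pi - pj), 30L - abs(pi - pj))
      if (dd <= 2L) sup <- sup + 1L
    }
    if (sup >= 2L) want <- c(want, pangcn:::edge_key(tags[i], tags[j]))
  }
  expect_equal(got, sort(want))
})

test_that("fusion evidence requires near-disjoint footprints", {
  half1 <- random_cds(80, seed = 61)
  half2 <- random_cds(80, seed = 62)
  strain <- genome_from_cds("S", c(half1, half2))
  # panel protein = fusion of the two strain proteins
  fused <- paste0(substring(half1, 1, nchar(half1) - 3),
                  substring(half2, 4, nchar(half2)))
  p_fuse <- genome_from_cds("PF", fused)
  filler <- lapply(1:2, function(i) genome_from_cds(paste0("PX", i),
                                                    random_cds(80, seed = 70 + i)))
  panel <- c(list(PF = p_fuse), setNames(filler, c("PX1", "PX2")))
  ev <- gcn_evidence(strain, panel)
  e <- fusion_edges(ev)
  expect_equal(e, pangcn:::edge_key("S_001", "S_002"))
  # heavily overlapping footprints are rejected by the 10% rule
  body <- random_cds(160, seed = 75)
  segA <- paste0(substring(body, 1, 288), "TAA")          # codons 1-96
  segB <- paste0("ATG", substring(body, 220, nchar(body)))  # codons 74-160
  strain2 <- genome_from_cds("S2", c(segA, segB))
  panel2 <- c(list(PB = genome_from_cds("PB", body)), panel["PX1"], panel["PX2"])
  ev2 <- gcn_evidence(strain2, panel2)
  expect_length(fusion_edges(ev2), 0L)
})

test_that("the context network is the labeled union of its channels", {
  tr <- tiny_triplet()
  panel <- .fixtures$panel %||% (.fixtures$panel <- make_panel(tr, n_panel = 5,
                                                               seed = 404))
  net <- build_gcn(tr$B, panel)
  expect_setequal(net$nodes, names(proteome(tr$B)))
  prm <- gcn_params()
  np <- length(profile_edges(net$evidence, prm))
  nn <- length(neighbor_edges(net$evidence, prm))
  nf <- length(fusion_edges(net$evidence, prm))
  expect_lte(nrow(net$edges), np + nn + nf)
  expect_gte(nrow(net$edges), max(np, nn, nf))
  # deterministic under fixed inputs
  net2 <- build_gcn(tr$B, panel)
  expect_identical(net$edges, net2$edges)
  # unrelated panel genomes provide no evidence: edgeless network
  rnd <- lapply(1:3, function(i)
    genome_from_cds(paste0("R", i),
                    vapply(1:6, function(j) random_cds(90, seed = 500 + 10 * i + j),
                           character(1))))
  names(rnd) <- paste0("R", 1:3)
  net0 <- build_gcn(tr$B, rnd)
  expect_equal(nrow(net0$edges), 0L)
  expect_setequal(net0$nodes, names(proteome(tr$B)))
})

test_that("network distance does explicit set arithmetic", {
  mknet <- function(id, edges) {
    structure(list(nodes = unique(c(edges)), strain_id = id,
                   edges = data.frame(tag_a = edges[, 1], tag_b = edges[, 2],
                                      channels = "profile",
                                      stringsAsFactors = FALSE)),
              class = "context_network")
  }
  # six-node fixture: a maps 1:1 onto b except node a6/b6 missing from map
  na <- mknet("a", rbind(c("a1", "a2"), c("a2", "a3"), c("a4", "a5"),
                         c("a5", "a6")))
  nb <- mknet("b", rbind(c("b1", "b2"), c("b3", "b4"), c("b4", "b5")))
  map <- c(a1 = "b1", a2 = "b2", a3 = "b3", a4 = "b4", a5 = "b5")
  # translated a-edges: {b1b2, b2b3, b4b5} + untranslatable {a5a6}
  # b-edges: {b1b2, b3b4, b4b5}; intersection 2, union 5
  expect_equal(network_distance(na, nb, map), 1 - 2 / 5)
  # restricted variant discards the unmapped edge: intersection 2, union 4
  expect_equal(network_distance(na, nb, map,
                                gcn_params(restrict_distance = TRUE)),
               1 - 2 / 4)
  # identity map on itself: distance zero
  ident <- setNames(c("a1", "a2", "a3", "a4", "a5", "a6"),
                    c("a1", "a2", "a3", "a4", "a5", "a6"))
  expect_equal(network_distance(na, na, ident), 0)
  # disjoint edge sets at distance one
  nc <- mknet("c", rbind(c("b1", "b3"), c("b2", "b5")))
  expect_equal(network_distance(na, nc, map), 1)
  expect_error(network_distance(na, nb, character(0)), "empty")
})

test_that("network distance is symmetric under map inversion", {
  tr <- tiny_triplet()
  panel <- .fixtures$panel %||% (.fixtures$panel <- make_panel(tr, n_panel = 5,
                                                               seed = 404))
  nb <- build_gcn(tr$B, panel)
  nc <- build_gcn(tr$C, panel)
  rbc <- tiny_rbh()$BC
  m_bc <- setNames(rbc$tag_b, rbc$tag_a)
  m_cb <- setNames(rbc$tag_a, rbc$tag_b)
  expect_equal(network_distance(nb, nc, m_bc),
               network_distance(nc, nb, m_cb))
  expect_equal(network_distance(nb, nb,
                                setNames(nb$nodes, nb$nodes)), 0)
})

test_that("the GCN tree separates the shared-history pair from the outgroup", {
  tr <- tiny_triplet()
  panel <- .fixtures$panel %||% (.fixtures$panel <- make_panel(tr, n_panel = 5,
                                                               seed = 404))
  res <- gcn_tree(list(A = tr$A, B = tr$B, C = tr$C, ANC = tr$ancestor),
                  panel, n_bootstrap = 20, seed = 12)
  expect_true(same_topology(res$tree, read_newick(text = "((B,C),(A,ANC));")))
  expect_equal(res$distances, t(res$distances))
  expect_true(all(diag(res$distances) == 0))
  sup <- attr(res$tree, "supports")
  expect_true(all(sup >= 0 & sup <= 100))
  # resampling under the same seed reproduces the supports
  res2 <- gcn_tree(list(A = tr$A, B = tr$B, C = tr$C, ANC = tr$ancestor),
                   panel, n_bootstrap = 20, seed = 12)
  expect_identical(attr(res2$tree, "supports"), sup)
})
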