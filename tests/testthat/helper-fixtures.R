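# Shared simulated fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

tiny_params <- function(seed = 3L, ...) {
  sim_params(n_genes = 50L, mean_gene_len_codons = 120L,
             planted_duplication_len_bp = 5000L,
             unique_central_len_bp = 2500L, seed = seed, ...)
}

tiny_triplet <- function() {
  if (is.null(.fixtures$triplet)) .fixtures$triplet <- make_triplet(tiny_params())
  .fixtures$triplet
}

tiny_ancestor <- function() {
  if (is.null(.fixtures$anc))
    .fixtures$anc <- simulate_ancestor(tiny_params(seed = 8L))
  .fixtures$anc
}

tiny_rbh <- function() {
  if (is.null(.fixtures$rbh)) {
    tr <- tiny_triplet()
    .fixtures$rbh <- list(AB = reciprocal_best_hits(tr$A, tr$B),
                          AC = reciprocal_best_hits(tr$A, tr$C),
                          BC = reciprocal_best_hits(tr$B, tr$C))
  }
  .fixtures$rbh
}

# build a genome from explicit coding sequences (plus-strand, spaced)
genome_from_cds <- function(id, cds, products = NULL, ecs = NULL,
                            spacer = 30L, pseudo = NULL) {
  n <- length(cds)
  products <- products %||% rep("hypothetical protein", n)
  ecs <- ecs %||% rep("", n)
  pseudo <- pseudo %||% rep(FALSE, n)
  sp <- paste(rep("ACGT", ceiling(spacer / 4)), collapse = "")
  seq <- ""
  feats <- NULL
  pos <- 1L
  for (i in seq_len(n)) {
    seq <- paste0(seq, sp)
    pos <- nchar(seq) + 1L
    seq <- paste0(seq, cds[i])
    feats <- rbind(feats, data.frame(
      locus_tag = sprintf("%s_%03d", id, i), type = "CDS",
      start = pos, end = nchar(seq), strand = "+", pseudo = pseudo[i],
      product = products[i], ec = ecs[i], stringsAsFactors = FALSE))
  }
  seq <- paste0(seq, sp)
  genome(id, seq, feats)
}

random_cds <- function(n_codons, seed = NULL) {
  draw <- function() {
    body <- sample(setdiff(names(Biostrings::getGeneticCode("11")),
                           c("TAA", "TAG", "TGA")), n_codons - 2L,
                   replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_protein <- function(n, seed = NULL) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  draw <- function() paste(sample(aas, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
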