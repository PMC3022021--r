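test_that("codon usage table is a proper distribution with the stated bias", {
  u0 <- codon_usage_table(0)
  expect_equal(sum(u0$prob), 1)
  # bias 0: uniform within each synonymous family
  for (aa in unique(u0$aa)) {
    w <- u0$p_within_family[u0$aa == aa]
    expect_equal(w, rep(1 / length(w), length(w)))
  }
  u9 <- codon_usage_table(0.9)
  agg <- tapply(u9$p_within_family, u9$aa, max)
  expect_true(all(agg >= 0.9))
})

test_that("unbiased ancestors use synonymous codons uniformly", {
  p <- sim_params(n_genes = 60L, mean_gene_len_codons = 150L,
                  codon_bias_strength = 0, seed = 21L)
  g <- simulate_ancestor(p)$genome
  f <- g$features[g$features$type == "CDS", ]
  cods <- unlist(lapply(f$locus_tag, function(t) {
    s <- extract_cds(g, t)
    split_codons(s)[2:(nchar(s) / 3 - 1)]  # body codons only
  }))
  counts <- table(cods)
  fams <- split(names(Biostrings::getGeneticCode("11")),
                Biostrings::getGeneticCode("11"))
  fams <- fams[names(fams) != "*"]
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    n <- sum(counts[fam], na.rm = TRUE)
    if (n < 50) next
    p0 <- 1 / length(fam)
    sigma <- sqrt(n * p0 * (1 - p0))
    for (cod in fam) {
      obs <- if (cod %in% names(counts)) counts[[cod]] else 0
      expect_lt(abs(obs - n * p0), 5 * sigma + 1)
    }
  }
})

test_that("gene count and mean length track the requested parameters", {
  p <- sim_params(n_genes = 50L, mean_gene_len_codons = 300L, seed = 31L)
  g <- simulate_ancestor(p)$genome
  cds <- g$features[g$features$type == "CDS", ]
  expect_equal(nrow(cds), 50L)
  expect_lt(abs(mean(cds$end - cds$start + 1) - 900) / 900, 0.10)
})

test_that("same seed gives byte-identical FASTA and GFF3", {
  p <- tiny_params(seed = 77L)
  d <- tempfile(); dir.create(d)
  for (run in 1:2) {
    g <- simulate_ancestor(p)$genome
    write_genome(g, file.path(d, sprintf("r%d.fa", run)),
                 file.path(d, sprintf("r%d.gff3", run)))
  }
  expect_identical(readLines(file.path(d, "r1.fa")),
                   readLines(file.path(d, "r2.fa")))
  g1 <- readLines(file.path(d, "r1.gff3")); g2 <- readLines(file.path(d, "r2.gff3"))
  # the date header line may differ; compare feature lines
  expect_identical(grep("^#", g1, value = TRUE, invert = TRUE),
                   grep("^#", g2, value = TRUE, invert = TRUE))
})

test_that("zero rates leave the descendant identical to the ancestor", {
  p <- tiny_params(seed = 5L, loss_rate = 0, dup_rate = 0, snp_per_site = 0,
                   pseudogenization_rate = 0)
  anc <- simulate_ancestor(p)$genome
  d <- evolve_strain(anc, p, seed = 9L, id = "D")
  expect_identical(d$genome$seq, anc$seq)
  expect_equal(nrow(d$genome$features), nrow(anc$features))
  tr <- d$truth
  expect_true(all(!is.na(tr$descendant_tag)))
  expect_true(all(tr$events == ""))
  expect_equal(sum(tr$n_syn) + sum(tr$n_nonsyn), 0)
})

test_that("gene losses follow the requested binomial rate", {
  p <- sim_params(n_genes = 500L, mean_gene_len_codons = 60L,
                  loss_rate = 0.1, dup_rate = 0, snp_per_site = 0,
                  pseudogenization_rate = 0, seed = 13L)
  anc <- simulate_ancestor(p)$genome
  d <- evolve_strain(anc, p, seed = 17L, id = "D")
  lost <- sum(grepl("lost", d$truth$events))
  expect_gte(lost, 30L)  # 50 +/- 4 binomial sigmas
  expect_lte(lost, 70L)
})

test_that("event draws are reproducible and duplications are recorded", {
  p <- tiny_params(seed = 41L, dup_rate = 0.15)
  anc <- simulate_ancestor(p)$genome
  d1 <- evolve_strain(anc, p, seed = 43L, id = "D")
  d2 <- evolve_strain(anc, p, seed = 43L, id = "D")
  expect_identical(d1$genome$seq, d2$genome$seq)
  expect_identical(d1$truth, d2$truth)
  copies <- d1$truth[grepl("dup_copy", d1$truth$events), ]
  expect_gt(nrow(copies), 0L)
  # each copy shares its ancestor gene with a primary descendant
  for (atag in copies$ancestor_tag) {
    expect_gte(sum(d1$truth$ancestor_tag == atag, na.rm = TRUE), 2L)
  }
})

test_that("pseudogenization deletes one base and flags the gene", {
  p <- tiny_params(seed = 51L, pseudogenization_rate = 0.3, snp_per_site = 0,
                   loss_rate = 0, dup_rate = 0)
  anc <- simulate_ancestor(p)$genome
  d <- evolve_strain(anc, p, seed = 53L, id = "D")
  ps <- d$truth[grepl("indel_pseudo", d$truth$events), ]
  expect_gt(nrow(ps), 0L)
  f <- d$genome$features
  for (i in seq_len(nrow(ps))) {
    row <- f[f$locus_tag == ps$descendant_tag[i], ]
    anc_row <- anc$features[anc$features$locus_tag == ps$ancestor_tag[i], ]
    expect_true(row$pseudo)
    expect_equal(row$end - row$start + 1L,
                 anc_row$end - anc_row$start + 1L - 1L)
  }
})

test_that("the triplet carries the planted structure", {
  tr <- tiny_triplet()
  n_cds <- function(g) sum(g$features$type == "CDS" & !g$features$pseudo)
  expect_gt(n_cds(tr$A), n_cds(tr$B))
  expect_gt(n_cds(tr$A), n_cds(tr$C))
  # central-region genes are present in A, absent from B and C
  a_anc <- tr$truth$A$ancestor_tag[!is.na(tr$truth$A$descendant_tag)]
  b_anc <- tr$truth$B$ancestor_tag[!is.na(tr$truth$B$descendant_tag)]
  c_anc <- tr$truth$C$ancestor_tag[!is.na(tr$truth$C$descendant_tag)]
  expect_gte(sum(tr$central_tags %in% a_anc), length(tr$central_tags) - 1L)
  expect_length(intersect(tr$central_tags, b_anc), 0L)
  expect_length(intersect(tr$central_tags, c_anc), 0L)
  # the flanking duplication is recoverable from A's chromosome
  seg <- find_duplicated_segments(tr$A, min_len = 3000)
  expect_gte(nrow(seg), 1L)
  expect_true(any(seg$orientation == "inverted" & seg$length_bp > 4500))
  # determinism
  tr2 <- make_triplet(tiny_params())
  expect_identical(tr2$A$seq, tr$A$seq)
  expect_identical(tr2$truth$B, tr$truth$B)
})

test_that("the lysine pathway contrast is planted as designed", {
  tr <- tiny_triplet()
  pw <- pathway_presence(list(tr$A, tr$ancestor), read_pathway())
  expect_equal(unname(pw$completeness), c(9, 9))
  pw_bc <- pathway_presence(list(tr$B, tr$C), read_pathway())
  expect_true(all(pw_bc$completeness <= 3))
})
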