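test_that("codon alignment pairs codons and drops gap columns", {
  cds <- random_cds(50, seed = 2)
  ca <- codon_align(cds, cds)
  expect_equal(ca$n_codons, 49L)  # terminal stop dropped
  expect_false(ca$gapped)
  expect_identical(ca$codons_a, ca$codons_b)
  # one inserted codon in b drops exactly one column
  ins <- paste0(substring(cds, 1, 60), "GAA", substring(cds, 61, nchar(cds)))
  ca2 <- codon_align(cds, ins)
  expect_true(ca2$gapped)
  expect_equal(ca2$n_codons, 49L)
  # back-threaded codons translate to the aligned residues
  gc <- Biostrings::getGeneticCode("11")
  expect_identical(unname(gc[ca2$codons_a]), unname(gc[ca2$codons_b]))
})

test_that("NG86 site and difference counts match the enumeration oracle on spot checks", {
  code <- Biostrings::getGeneticCode("11")
  # single synonymous third-position change
  r <- ng86_dnds(list(codons_a = "TTT", codons_b = "TTC"))
  expect_equal(r$Sd, 1); expect_equal(r$Nd, 0)
  expect_equal(r$S, oracle_syn_sites("TTT", code) / 2 +
                 oracle_syn_sites("TTC", code) / 2)
  # identical sequences: no divergence, omega undefined
  r0 <- ng86_dnds(list(codons_a = c("ATG", "GCT"), codons_b = c("ATG", "GCT")))
  expect_equal(r0$Nd + r0$Sd, 0)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_true("omega_undefined" %in% r0$flags)
  # two-difference codon pair averages over both mutation orders
  want <- oracle_pair_counts("TTT", "GTC", code)
  r2 <- ng86_dnds(list(codons_a = "TTT", codons_b = "GTC"))
  expect_equal(r2$Nd, unname(want["non"]))
  expect_equal(r2$Sd, unname(want["syn"]))
})

test_that("site counts conserve N + S = 3 * n_codons", {
  sense <- setdiff(names(Biostrings::getGeneticCode("11")),
                   c("TAA", "TAG", "TGA"))
  for (i in 1:25) {
    n <- sample(10:200, 1)
    ca <- withr::with_seed(1000 + i, list(
      codons_a = sample(sense, n, replace = TRUE),
      codons_b = sample(sense, n, replace = TRUE)))
    r <- ng86_dnds(ca)
    expect_equal(r$N + r$S, 3 * n, tolerance = 1e-9)
  }
})

test_that("saturated proportions are flagged rather than corrected", {
  # force pS towards saturation with highly divergent synonymous codons
  ca <- list(codons_a = rep("TCT", 50), codons_b = rep("AGC", 50))
  r <- ng86_dnds(ca)
  expect_true(is.na(r$omega) || r$omega >= 0)
  expect_true(length(r$flags) > 0)
})

test_that("category rate summaries aggregate per-pair results", {
  cds <- vapply(1:10, function(i) random_cds(80, seed = 1100 + i),
                character(1))
  g1 <- genome_from_cds("X", cds)
  g2 <- genome_from_cds("Y", cds)
  pairs <- data.frame(tag_a = g1$features$locus_tag,
                      tag_b = g2$features$locus_tag,
                      stringsAsFactors = FALSE)
  res <- dnds_pairs(pairs, g1, g2)
  cr <- category_rates(res, rep("same", nrow(res)))
  expect_equal(cr$mean_dN, 0)
  expect_equal(cr$mean_dS, 0)
  # two-label case: means equal per-pair means (accounting identity)
  p <- sim_params(n_genes = 40L, mean_gene_len_codons = 100L, loss_rate = 0,
                  dup_rate = 0, pseudogenization_rate = 0,
                  snp_per_site = 0.01, omega_true = 0.3, seed = 91L)
  anc <- simulate_ancestor(p)$genome
  d <- evolve_strain(anc, p, seed = 93L, id = "D")
  tr <- d$truth[!is.na(d$truth$descendant_tag), ]
  res2 <- dnds_pairs(data.frame(tag_a = tr$ancestor_tag,
                                tag_b = tr$descendant_tag), anc, d$genome)
  labs <- rep(c("u", "v"), length.out = nrow(res2))
  cr2 <- category_rates(res2, labs)
  for (L in c("u", "v")) {
    expect_equal(cr2$mean_dN[cr2$label == L],
                 mean(res2$dN[labs == L], na.rm = TRUE))
  }
})

test_that("rate categories under different selection separate significantly", {
  sim_set <- function(om, seed) {
    p <- sim_params(n_genes = 50L, mean_gene_len_codons = 150L, loss_rate = 0,
                    dup_rate = 0, pseudogenization_rate = 0,
                    snp_per_site = 0.02, omega_true = om, seed = seed)
    anc <- simulate_ancestor(p)$genome
    d <- evolve_strain(anc, p, seed = seed + 1L, id = "D")
    tr <- d$truth[!is.na(d$truth$descendant_tag), ]
    dnds_pairs(data.frame(tag_a = tr$ancestor_tag,
                          tag_b = tr$descendant_tag), anc, d$genome)
  }
  lo <- sim_set(0.1, 201L)
  hi <- sim_set(0.8, 301L)
  res <- rbind(lo, hi)
  cr <- category_rates(res, rep(c("constrained", "relaxed"),
                                c(nrow(lo), nrow(hi))))
  expect_lt(cr$p_value[cr$label == "constrained"], 0.01)
  expect_lt(cr$mean_omega[cr$label == "constrained"],
            cr$mean_omega[cr$label == "relaxed"])
})

test_that("relative adaptiveness follows the Sharp & Li conventions", {
  # a reference using only GCT for Ala: GCT gets 1, the rest 0.5/count
  ref <- paste0("ATG", paste(rep("GCT", 50), collapse = ""), "TAA")
  w <- relative_adaptiveness(ref)
  expect_equal(unname(w["GCT"]), 1)
  expect_equal(unname(w["GCC"]), 0.5 / 50)
  # unobserved families carry no information: weight 1
  expect_equal(unname(w["TTT"]), 1)
  # uniform usage gives weights near 1 everywhere
  p <- sim_params(n_genes = 80L, mean_gene_len_codons = 200L,
                  codon_bias_strength = 0, seed = 111L)
  g <- simulate_ancestor(p)$genome
  allcds <- vapply(g$features$locus_tag[g$features$type == "CDS"],
                   function(t) extract_cds(g, t), character(1))
  wu <- relative_adaptiveness(allcds)
  expect_gt(min(wu), 0.6)
  # biased usage: the top-weight codon per family is the table's mode
  pb <- sim_params(n_genes = 80L, mean_gene_len_codons = 200L,
                   codon_bias_strength = 0.8, seed = 113L)
  sb <- simulate_ancestor(pb)
  gb <- sb$genome
  cdsb <- vapply(gb$features$locus_tag[gb$features$type == "CDS"],
                 function(t) extract_cds(gb, t), character(1))
  wb <- relative_adaptiveness(cdsb)
  tab <- sb$codon_usage
  for (aa in unique(tab$aa)) {
    fam <- tab$codon[tab$aa == aa]
    if (length(fam) < 2L) next
    expect_equal(fam[which.max(wb[fam])],
                 tab$codon[tab$aa == aa][which.max(tab$prob[tab$aa == aa])])
  }
})

test_that("CAI is the geometric mean of codon weights", {
  w <- setNames(rep(1, 61), pangcn:::sense_codons())
  gene <- paste0("ATG", "GCTGCTGCT", "TAA")
  expect_equal(cai(gene, w)$cai, 1.0)
  # permuting synonymous codons with equal weights leaves CAI unchanged
  w2 <- w; w2[c("GCT", "GCC")] <- 0.4
  g1 <- paste0("ATG", "GCTGCCAAA", "TAA")
  g2 <- paste0("ATG", "GCCGCTAAA", "TAA")
  expect_equal(cai(g1, w2)$cai, cai(g2, w2)$cai)
  # Met, Trp and stop codons are excluded from the average
  g3 <- paste0("ATG", "TGGGCT", "TAA")
  expect_equal(cai(g3, w2)$n_codons_used, 1L)
  expect_error(cai("ATGTGGTAA", w), "no codons")
})

test_that("highly expressed simulated genes score the highest CAI", {
  g <- tiny_ancestor()$genome
  tab <- cai_table(g)
  top <- head(tab, 5)
  expect_gt(mean(grepl("ribosomal", top$product)), 0.5)
  ribo <- tab$cai[grepl("ribosomal", tab$product)]
  other <- tab$cai[!grepl("ribosomal", tab$product)]
  expect_gt(mean(ribo), mean(other))
})
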