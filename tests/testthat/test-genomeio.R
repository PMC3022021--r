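test_that("GFF3 coordinates are read 1-based closed with strand and pseudo", {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(">chr", paste(rep("ATGAAATAAGCC", 5), collapse = "")), fa)
  writeLines(c("##gff-version 3",
               "chr\tsim\tCDS\t1\t30\t.\t+\t.\tID=g1",
               "chr\tsim\tCDS\t40\t60\t.\t-\t.\tID=g2;pseudo=true;product=broken thing"),
             gff)
  g <- read_genome(fa, gff)
  expect_equal(nrow(g$features), 2L)
  expect_equal(g$features$start, c(1L, 40L))
  expect_equal(g$features$end, c(30L, 60L))
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$pseudo, c(FALSE, TRUE))
})

test_that("GenBank flat files round-trip, including /pseudo and /EC_number", {
  anc <- tiny_ancestor()$genome
  # give the fixture a pseudo gene and an EC so both qualifiers are hit
  g <- anc
  g$features$pseudo[3] <- TRUE
  g$features$ec[4] <- "2.7.2.4,1.1.1.1"
  path <- tempfile(fileext = ".gbk")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$features$locus_tag, g$features$locus_tag)
  expect_identical(g2$features$start, g$features$start)
  expect_identical(g2$features$end, g$features$end)
  expect_identical(g2$features$strand, g$features$strand)
  expect_identical(g2$features$pseudo, g$features$pseudo)
  expect_identical(g2$features$ec, g$features$ec)
  expect_true(g2$is_circular)
})

test_that("simulator genomes round-trip through FASTA+GFF3", {
  g <- tiny_ancestor()$genome
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, gff)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$features[, c("locus_tag", "type", "start", "end",
                                   "strand", "pseudo", "product", "ec")],
                   g$features[, c("locus_tag", "type", "start", "end",
                                  "strand", "pseudo", "product", "ec")])
})

test_that("mismatched annotation and invalid features are rejected", {
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  writeLines(c(">chr", "ACGTACGTACGT"), fa)
  writeLines(c("##gff-version 3",
               "other\tsim\tCDS\t1\t6\t.\t+\t.\tID=g1"), gff)
  expect_error(read_genome(fa, gff), "does not reference")
  writeLines(c("##gff-version 3",
               "chr\tsim\tCDS\t1\t600\t.\t+\t.\tID=g1"), gff)
  expect_error(read_genome(fa, gff), "bounds|length")
  expect_error(genome("x", "ACGT", data.frame(
    locus_tag = c("a", "a"), type = "CDS", start = 1L, end = 3L,
    strand = "+", pseudo = FALSE, product = "", ec = "")), "duplicate")
})

test_that("genome statistics match direct counts", {
  g0 <- genome("mini", "ATGC")
  s0 <- genome_stats(g0)
  expect_equal(s0$length_bp, 4L)
  expect_equal(s0$gc_percent, 50)
  expect_error(genome_stats(genome("e", "")), "empty")

  g1 <- genome_from_cds("one", "ATGGCCTAA")
  s1 <- genome_stats(g1)
  expect_equal(s1$gc3_percent, 66.67)  # third bases G, C, A
  expect_equal(s1$n_cds_total, 1L)
  expect_equal(s1$mean_cds_len_bp, 9L)

  # pseudogenes count toward totals but not GC3
  g2 <- genome_from_cds("two", c("ATGGCCTAA", "ATGGGCCCTAA"),
                        pseudo = c(FALSE, TRUE))
  s2 <- genome_stats(g2)
  expect_equal(s2$n_cds_total, 2L)
  expect_equal(s2$n_cds_intact, 1L)
  expect_equal(s2$n_cds_pseudo, 1L)
  expect_equal(s2$gc3_percent, 66.67)
  expect_equal(s2$coding_fraction, s2$total_cds_bp / s2$length_bp)
})

test_that("gc percent is invariant under reverse complement", {
  g <- tiny_ancestor()$genome
  expect_equal(genome_stats(g)$gc_percent,
               genome_stats(genome(g$id, revcomp(g$seq)))$gc_percent)
})

test_that("genome statistics agree with the simulator's bookkeeping", {
  g <- tiny_ancestor()$genome
  s <- genome_stats(g)
  f <- g$features
  expect_equal(s$n_cds_total, sum(f$type == "CDS"))
  expect_equal(s$n_cds_total, s$n_cds_intact + s$n_cds_pseudo)
  expect_equal(s$total_cds_bp,
               sum((f$end - f$start + 1)[f$type == "CDS"]))
  expect_equal(s$stable_rna_fraction,
               sum((f$end - f$start + 1)[f$type %in% c("rRNA", "tRNA")]) /
                 nchar(g$seq))
})

test_that("translation and CDS extraction follow the bacterial code", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_error(translate_cds("ATGTAAAAATAA"), "internal stop")
  expect_equal(translate_cds("ATGNNNTAA"), "MX")
  # minus-strand extraction reverse complements
  g <- genome("m", paste0("GGGG", "TTTCAT", "GGGG"),
              data.frame(locus_tag = "g1", type = "CDS", start = 5L, end = 10L,
                         strand = "-", pseudo = FALSE, product = "", ec = ""))
  expect_equal(extract_cds(g, "g1"), "ATGAAA")
  expect_equal(translate_cds(extract_cds(g, "g1")), "MK")
  # random gene agrees with the Biostrings translation oracle
  cds <- random_cds(300, seed = 11)
  expect_equal(translate_cds(cds),
               sub("\\*$", "", as.character(Biostrings::translate(
                 Biostrings::DNAString(cds),
                 genetic.code = Biostrings::getGeneticCode("11")))))
})

test_that("proteome translates pseudogenes through their longest ORF", {
  cds <- random_cds(120, seed = 5)
  broken <- paste0(substring(cds, 1, 150), substring(cds, 152, nchar(cds)))
  g <- genome_from_cds("p", c(cds, broken), pseudo = c(FALSE, TRUE))
  p <- proteome(g, min_pseudo_codons = 20L)
  expect_named(p, c("p_001", "p_002"))
  expect_equal(p[["p_001"]], translate_cds(cds))
  expect_gte(nchar(p[["p_002"]]), 20L)
})

test_that("planted duplications are found with correct orientation and length", {
  plant <- function(seed, inverted) {
    withr::with_seed(seed, {
      bases <- c("A", "C", "G", "T")
      s <- paste(sample(bases, 1e5, replace = TRUE), collapse = "")
      rep5 <- paste(sample(bases, 5000, replace = TRUE), collapse = "")
      second <- if (inverted) revcomp(rep5) else rep5
      paste0(substring(s, 1, 20000), rep5, substring(s, 20001, 60000),
             second, substring(s, 60001, 1e5))
    })
  }
  for (seed in 1:3) {
    seg <- find_duplicated_segments(genome("d", plant(seed, FALSE)),
                                    min_len = 2000)
    expect_equal(nrow(seg), 1L)
    expect_equal(seg$orientation, "direct")
    expect_lt(abs(seg$length_bp - 5000) / 5000, 0.02)
    expect_equal(seg$start1, 20001, tolerance = 25)

    segi <- find_duplicated_segments(genome("i", plant(seed + 10, TRUE)),
                                     min_len = 2000)
    expect_equal(nrow(segi), 1L)
    expect_equal(segi$orientation, "inverted")
    expect_lt(abs(segi$length_bp - 5000) / 5000, 0.02)
  }
})

test_that("random sequence contains no long duplicated segments", {
  s <- withr::with_seed(99, paste(sample(c("A", "C", "G", "T"), 1e5,
                                         replace = TRUE), collapse = ""))
  expect_equal(nrow(find_duplicated_segments(genome("r", s), min_len = 2000)),
               0L)
  expect_error(find_duplicated_segments(genome("r", s), min_len = 500),
               "min_len")
})

test_that("repeat finder recovers planted repeats across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    s <- withr::with_seed(seed, {
      bases <- c("A", "C", "G", "T")
      x <- paste(sample(bases, 4e4, replace = TRUE), collapse = "")
      r <- paste(sample(bases, 3000, replace = TRUE), collapse = "")
      paste0(substring(x, 1, 10000), r, substring(x, 10001, 30000), r,
             substring(x, 30001, 4e4))
    })
    seg <- find_duplicated_segments(genome("x", s), min_len = 2000,
                                    min_identity = 98)
    if (nrow(seg) == 1L && seg$identity_percent >= 98 &&
        abs(seg$length_bp - 3000) < 100) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
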