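#!/usr/bin/env Rscript
# Optional validation against real genomes. Needs the GenBank flat files
# of the three Lactobacillus delbrueckii subsp. bulgaricus chromosomes
# (CP000156, NC_008054, NC_008529), downloaded separately, e.g.:
#   https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=CP000156&rettype=gbwithparts&retmode=text
# Usage:
#   Rscript scripts/validation.R <dir-with-gbk-files> [out.json]
# Reports genome statistics, pan-genome Venn counts under the default
# homology criteria, and CAI of the lactate dehydrogenase genes against
# a ribosomal-protein reference set.

suppressPackageStartupMessages(library(pangcn))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: Rscript scripts/validation.R <dir> [out.json]")
dir <- args[[1]]
out <- if (length(args) > 1L) args[[2]] else "results/validation.json"
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)

find_gbk <- function(acc) {
  hits <- list.files(dir, pattern = paste0(acc, ".*\\.(gb|gbk|gbff)$"),
                     full.names = TRUE, ignore.case = TRUE)
  if (!length(hits)) stop("no GenBank flat file for ", acc, " under ", dir)
  hits[[1]]
}

g2038 <- read_genbank(find_gbk("CP000156"))
g11842 <- read_genbank(find_gbk("NC_008054"))
gbaa <- read_genbank(find_gbk("NC_008529"))

res <- list()
st <- genome_stats(g2038)
res$stats_2038 <- unclass(st)

message("pan-genome partition (this aligns ~1800x1800 proteomes; be patient)")
crit <- homology_criteria()
rab <- reciprocal_best_hits(g2038, g11842, crit)
rac <- reciprocal_best_hits(g2038, gbaa, crit)
rbc <- reciprocal_best_hits(g11842, gbaa, crit)
part <- three_way_partition(g2038, g11842, gbaa, rab, rac, rbc, crit)
res$venn <- part$counts

w <- relative_adaptiveness(g2038, "ribosomal protein")
for (tag in c("LBU0066", "LBU0084", "LBU0059")) {
  f <- g2038$features
  if (tag %in% f$locus_tag && !f$pseudo[match(tag, f$locus_tag)])
    res[[paste0("cai_", tag)]] <- cai(extract_cds(g2038, tag), w)$cai
}

jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", out)
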