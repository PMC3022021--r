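#' Configuration for an end-to-end pipeline run
#'
#' A single master seed is fanned out deterministically to every
#' stochastic stage (see [derive_seed]), so two runs with the same
#' configuration produce identical outputs and checksums.
#'
#' @param outdir output directory (created if needed).
#' @param sim a [sim_params] describing the simulated strain triplet
#'   (the default is a desk-scale genome so a demo run stays fast).
#' @param criteria a [homology_criteria].
#' @param gcn a [gcn_params].
#' @param n_panel reference-panel size.
#' @param n_bootstrap bootstrap replicates for the context-network tree.
#' @param n_dnds_pairs how many core ortholog pairs enter the dN/dS
#'   table (0 = all).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(outdir = tempfile("pangcn_run_"),
                       sim = sim_params(n_genes = 60L,
                                        mean_gene_len_codons = 120L,
                                        planted_duplication_len_bp = 5000L,
                                        unique_central_len_bp = 3000L),
                       criteria = homology_criteria(),
                       gcn = gcn_params(criteria = criteria),
                       n_panel = 6L, n_bootstrap = 50L,
                       n_dnds_pairs = 30L, seed = 1L) {
  structure(list(outdir = outdir, sim = sim, criteria = criteria, gcn = gcn,
                 n_panel = as.integer(n_panel),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_dnds_pairs = as.integer(n_dnds_pairs),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a simulated strain triplet
#'
#' simulate -> genome statistics -> orthology -> pan-genome partition and
#' variant classes -> dN/dS -> CAI -> context-network phylogeny ->
#' 16S-marker neighbor-joining tree. All stage outputs are written under
#' `config$outdir` together with a checksummed manifest and a JSON
#' report; a stage failure aborts with the stage named, keeping partial
#' outputs.
#'
#' @param config a [run_config].
#' @param quiet suppress progress messages.
#' @return the report, invisibly (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s] start", name)
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] done (%.1fs)", name, as.numeric(Sys.time() - t0, units = "secs"))
    r
  }
  outfile <- function(...) file.path(config$outdir, sprintf(...))
  manifest <- list()
  note <- function(path, producer) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), md5 = unname(tools::md5sum(path)),
      stage = producer, stringsAsFactors = FALSE)
  }

  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)
  trip <- stage("simulate", make_triplet(sim))
  strains <- list(A = trip$A, B = trip$B, C = trip$C)
  for (nm in names(strains)) {
    write_genome(strains[[nm]], outfile("%s.fasta", nm), outfile("%s.gff3", nm))
    note(outfile("%s.fasta", nm), "simulate"); note(outfile("%s.gff3", nm), "simulate")
    write_truth(trip$truth[[nm]], outfile("truth_%s.tsv", nm))
    note(outfile("truth_%s.tsv", nm), "simulate")
  }

  stats <- stage("stats", lapply(c(strains, list(ANC = trip$ancestor)),
                                 genome_stats))

  rbh <- stage("orthology", list(
    AB = reciprocal_best_hits(trip$A, trip$B, config$criteria),
    AC = reciprocal_best_hits(trip$A, trip$C, config$criteria),
    BC = reciprocal_best_hits(trip$B, trip$C, config$criteria)))
  for (nm in names(rbh)) {
    write_orthologs(rbh[[nm]], outfile("rbh_%s.tsv", nm))
    note(outfile("rbh_%s.tsv", nm), "orthology")
  }

  part <- stage("pangenome", three_way_partition(
    trip$A, trip$B, trip$C, rbh$AB, rbh$AC, rbh$BC, config$criteria))
  classes <- stage("classify", partition_variant_classes(part, strains))
  utils::write.table(classes, outfile("variant_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("variant_classes.tsv"), "classify")

  pathway <- stage("pathway", pathway_presence(
    c(strains, list(ANC = trip$ancestor)), read_pathway()))
  utils::write.table(cbind(strain = rownames(pathway$matrix),
                           as.data.frame(pathway$matrix)),
                     outfile("pathway_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("pathway_matrix.tsv"), "pathway")

  dnds <- stage("dnds", {
    pairs <- rbh$AB[, c("tag_a", "tag_b")]
    if (config$n_dnds_pairs > 0L && nrow(pairs) > config$n_dnds_pairs)
      pairs <- pairs[with_seed(derive_seed(config$seed, 2L),
                               sample.int(nrow(pairs), config$n_dnds_pairs)), ]
    dnds_pairs(pairs, trip$A, trip$B, config$criteria)
  })
  utils::write.table(dnds, outfile("dnds_AB.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(outfile("dnds_AB.tsv"), "dnds")

  cai_tabs <- stage("cai", lapply(strains, cai_table))
  utils::write.table(cai_tabs$A, outfile("cai_A.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("cai_A.tsv"), "cai")

  gcn_res <- stage("gcn", {
    panel <- make_panel(trip, n_panel = config$n_panel,
                        seed = derive_seed(config$seed, 3L))
    gcn_tree(c(strains, list(ANC = trip$ancestor)), panel, config$gcn,
             n_bootstrap = config$n_bootstrap,
             seed = derive_seed(config$seed, 4L))
  })
  write_newick(gcn_res$tree, outfile("gcn_tree.nwk"))
  note(outfile("gcn_tree.nwk"), "gcn")
  utils::write.table(gcn_res$distances, outfile("gcn_distances.tsv"),
                     sep = "\t", quote = FALSE)
  note(outfile("gcn_distances.tsv"), "gcn")

  marker_tree <- stage("marker_tree", {
    seqs <- vapply(c(strains, list(ANC = trip$ancestor)), function(g) {
      f <- g$features
      i <- which(f$type == "rRNA" & grepl("16S", f$product))[1]
      substring(g$seq, f$start[i], f$end[i])
    }, character(1))
    neighbor_joining(jc_distance_matrix(seqs))
  })
  write_newick(marker_tree, outfile("marker_tree.nwk"))
  note(outfile("marker_tree.nwk"), "marker_tree")

  class_counts <- table(classes$variant_class)
  report <- list(
    seed = config$seed,
    genome_stats = lapply(stats, unclass),
    venn = part$counts,
    variant_classes = as.list(setNames(as.integer(class_counts),
                                       names(class_counts))),
    pathway_completeness = as.list(pathway$completeness),
    mean_omega_AB = mean(dnds$omega, na.rm = TRUE),
    top_cai_A = if (nrow(cai_tabs$A)) cai_tabs$A[1, c("locus_tag", "cai")],
    gcn_tree = write_newick(gcn_res$tree),
    marker_tree = write_newick(marker_tree),
    params = list(criteria = unclass(config$criteria),
                  gcn = unclass(config$gcn)[setdiff(names(config$gcn), "criteria")],
                  sim = unclass(sim)))
  jsonlite::write_json(report, outfile("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note(outfile("report.json"), "report")
  man <- do.call(rbind, manifest)
  utils::write.table(man, outfile("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  say("pipeline complete: %s", config$outdir)
  invisible(report)
}
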