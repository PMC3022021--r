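# Self-contained validation experiments: each runs the simulator with
# known ground truth, applies the estimator under test, and reports the
# recovery. Used by the test suite and by scripts/acceptance.R.

#' dN/dS parameter-recovery experiment
#'
#' Simulates gene sets under a known target omega, estimates omega with
#' the NG86 counting estimator pooled over genes (summed site and
#' difference counts), and reports the per-seed estimates.
#'
#' @param omega_true target dN/dS enforced by the mutation engine.
#' @param n_genes genes per replicate.
#' @param len_codons codons per gene.
#' @param snp_per_site per-site divergence between ancestor and
#'   descendant.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @return numeric vector of pooled omega estimates, one per seed.
#' @export
omega_recovery_experiment <- function(omega_true, n_genes = 50L,
                                      len_codons = 300L,
                                      snp_per_site = 0.01,
                                      n_seeds = 20L, seed = 1L) {
  vapply(seq_len(n_seeds), function(s) {
    p <- sim_params(n_genes = n_genes, mean_gene_len_codons = len_codons,
                    intergenic_mean_bp = 20L,
                    loss_rate = 0, dup_rate = 0, pseudogenization_rate = 0,
                    snp_per_site = snp_per_site, omega_true = omega_true,
                    seed = derive_seed(seed, s))
    anc <- simulate_ancestor(p)$genome
    des <- evolve_strain(anc, p, derive_seed(seed, 10000L + s), id = "D")
    tr <- des$truth[!is.na(des$truth$descendant_tag), ]
    ca <- character(0); cb <- character(0)
    for (i in seq_len(nrow(tr))) {
      al <- codon_align(extract_cds(anc, tr$ancestor_tag[i]),
                        extract_cds(des$genome, tr$descendant_tag[i]))
      ca <- c(ca, al$codons_a); cb <- c(cb, al$codons_b)
    }
    pooled <- ng86_dnds(list(codons_a = ca, codons_b = cb))
    pooled$omega
  }, numeric(1))
}

#' Neighbor-joining additivity experiment
#'
#' Draws random trees, computes their exact (additive) leaf-to-leaf
#' distance matrices, and checks that neighbor joining recovers the
#' generating topology.
#'
#' @param n_matrices number of random trees.
#' @param taxa_range range of tip counts to draw from.
#' @param seed master seed.
#' @return fraction of exactly recovered topologies (0-1).
#' @export
nj_recovery_experiment <- function(n_matrices = 100L, taxa_range = 4:10,
                                   seed = 1L) {
  ok <- with_seed(seed, vapply(seq_len(n_matrices), function(i) {
    n <- sample(taxa_range, 1L)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    est <- neighbor_joining(d)
    same_topology(est, tr)
  }, logical(1)))
  mean(ok)
}

#' Genome-context-network topology-recovery experiment
#'
#' For each seed, simulates a strain triplet plus ancestor outgroup and a
#' reference panel, builds the context-network phylogeny with panel
#' bootstrap, and records whether the ground-truth topology
#' ((B,C),(A,ancestor)) is recovered and how strongly the (B,C) split is
#' supported.
#'
#' @param n_seeds replicates.
#' @param params triplet [sim_params] (desk-scale default).
#' @param n_panel panel size.
#' @param n_bootstrap bootstrap replicates per seed.
#' @param seed master seed.
#' @return data.frame with per-seed columns `correct` (logical) and
#'   `bc_support` (percent of bootstrap trees containing the (B,C)
#'   split).
#' @export
gcn_recovery_experiment <- function(n_seeds = 20L,
                                    params = sim_params(
                                      n_genes = 50L,
                                      mean_gene_len_codons = 120L,
                                      planted_duplication_len_bp = 5000L,
                                      unique_central_len_bp = 2500L),
                                    n_panel = 6L, n_bootstrap = 50L,
                                    seed = 1L) {
  truth <- read_newick(text = "((B,C),(A,ANC));")
  rows <- lapply(seq_len(n_seeds), function(s) {
    p <- params
    p$seed <- derive_seed(seed, s)
    trip <- make_triplet(p)
    panel <- make_panel(trip, n_panel = n_panel,
                        seed = derive_seed(seed, 2000L + s))
    res <- gcn_tree(list(A = trip$A, B = trip$B, C = trip$C,
                         ANC = trip$ancestor),
                    panel, n_bootstrap = n_bootstrap,
                    seed = derive_seed(seed, 4000L + s))
    reps <- attr(res$tree, "replicates")
    tips <- sort(res$tree$tip.label)
    side <- sort(c("B", "C")); other <- sort(setdiff(tips, side))
    bc_key <- min(paste(side, collapse = ","), paste(other, collapse = ","))
    bc <- if (length(reps)) {
      100 * mean(vapply(reps, function(tr) bc_key %in% tree_splits(tr),
                        logical(1)))
    } else NA_real_
    data.frame(correct = same_topology(res$tree, truth), bc_support = bc)
  })
  do.call(rbind, rows)
}

#' Pan-genome truth-recovery experiment
#'
#' Simulates a triplet at low divergence under clean single-copy
#' conditions (no pseudogenization, no tandem duplication -- with
#' within-strain copies the choice of ortholog copy is not identifiable
#' at the locus-tag level, so copy-bearing families are excluded from
#' this measurement and duplication handling is validated separately),
#' partitions the pan-genome from reciprocal best hits, and scores the
#' inferred core families against the event-log truth: an inferred core
#' triple is correct iff its three tags trace to one ancestor gene.
#'
#' @param params triplet [sim_params].
#' @param criteria a [homology_criteria].
#' @return list with `precision`, `recall` (core families, 0-1),
#'   `n_core_true`, `n_core_est`, and the partition object.
#' @export
pangenome_recovery_experiment <- function(params = sim_params(
                                            n_genes = 120L,
                                            mean_gene_len_codons = 150L,
                                            planted_duplication_len_bp = 5000L,
                                            unique_central_len_bp = 2500L,
                                            pseudogenization_rate = 0,
                                            dup_rate = 0),
                                          criteria = homology_criteria()) {
  trip <- make_triplet(params)
  rAB <- reciprocal_best_hits(trip$A, trip$B, criteria)
  rAC <- reciprocal_best_hits(trip$A, trip$C, criteria)
  rBC <- reciprocal_best_hits(trip$B, trip$C, criteria)
  part <- three_way_partition(trip$A, trip$B, trip$C, rAB, rAC, rBC, criteria)
  anc_of <- function(truth) {
    tr <- truth[!is.na(truth$descendant_tag), ]
    setNames(tr$ancestor_tag, tr$descendant_tag)
  }
  mA <- anc_of(trip$truth$A); mB <- anc_of(trip$truth$B); mC <- anc_of(trip$truth$C)
  present <- function(truth) unique(truth$ancestor_tag[
    !is.na(truth$descendant_tag) & !is.na(truth$ancestor_tag)])
  core_true <- Reduce(intersect, list(present(trip$truth$A),
                                      present(trip$truth$B),
                                      present(trip$truth$C)))
  a1 <- mA[part$core$tag_1]; a2 <- mB[part$core$tag_2]; a3 <- mC[part$core$tag_3]
  correct <- !is.na(a1) & !is.na(a2) & !is.na(a3) & a1 == a2 & a1 == a3
  list(precision = if (nrow(part$core)) mean(correct) else NA_real_,
       recall = sum(correct & !duplicated(a1)) / length(core_true),
       n_core_true = length(core_true), n_core_est = nrow(part$core),
       partition = part)
}
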