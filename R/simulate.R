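#' Parameters for the synthetic pan-genome simulator
#'
#' Defaults emulate a small GC-balanced lactobacillus-like chromosome:
#' about 1,750 protein-coding genes averaging ~860 bp, ~50% genomic GC
#' with a strong synonymous preference for GC-ending codons, an rRNA
#' operon and a set of tRNAs, low per-site divergence between strains of
#' one subspecies, purifying selection (omega < 1), occasional gene loss,
#' tandem duplication and INDEL pseudogenization, and a planted
#' duplication (two 25 kb copies, the second inverted) flanking an 8.5 kb
#' strain-specific central region that carries a complete lysine
#' biosynthesis gene set.
#'
#' @param n_genes number of protein-coding genes in the ancestor.
#' @param mean_gene_len_codons mean CDS length in codons (incl. start and
#'   stop).
#' @param gc_target GC fraction of intergenic sequence.
#' @param codon_bias_strength synonymous codon bias in \[0, 1\]
#'   (see [codon_usage_table]).
#' @param intergenic_mean_bp mean intergenic spacer length.
#' @param loss_rate per-gene Bernoulli loss probability per unit branch.
#' @param dup_rate per-gene tandem duplication probability per unit branch.
#' @param snp_per_site per-site substitution probability per unit branch.
#' @param omega_true target dN/dS enforced by acceptance-rejection on
#'   proposed point mutations.
#' @param pseudogenization_rate per-gene probability of a frameshifting
#'   1-bp deletion (pseudo flag set).
#' @param gain_rate per-gene probability of gaining a fresh random gene
#'   (HGT-like); off by default.
#' @param planted_duplication_len_bp length of each planted duplicated
#'   segment.
#' @param unique_central_len_bp length of the strain-specific central
#'   region between the two copies.
#' @param branch_a,branch_shared,branch_terminal branch-length scale
#'   factors for, respectively, the short branch to strain A, the shared
#'   branch to the B/C intermediate, and the terminal B and C branches.
#'   The asymmetry (A short, B/C long and partly shared) encodes the
#'   ground-truth topology ((B,C),A).
#' @param ribosomal_fraction fraction of genes labeled as ribosomal
#'   proteins and sampled with boosted codon bias (the highly expressed
#'   reference set for CAI).
#' @param seed integer seed fixing every stochastic draw.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_genes = 1750L,
                       mean_gene_len_codons = 287L,
                       gc_target = 0.4968,
                       codon_bias_strength = 0.3,
                       intergenic_mean_bp = 150L,
                       loss_rate = 0.02,
                       dup_rate = 0.01,
                       snp_per_site = 0.005,
                       omega_true = 0.3,
                       pseudogenization_rate = 0.01,
                       gain_rate = 0,
                       planted_duplication_len_bp = 25000L,
                       unique_central_len_bp = 8500L,
                       branch_a = 0.5,
                       branch_shared = 1.5,
                       branch_terminal = 1.0,
                       ribosomal_fraction = 0.05,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            mean_gene_len_codons = as.integer(mean_gene_len_codons),
            gc_target = gc_target,
            codon_bias_strength = codon_bias_strength,
            intergenic_mean_bp = as.integer(intergenic_mean_bp),
            loss_rate = loss_rate, dup_rate = dup_rate,
            snp_per_site = snp_per_site, omega_true = omega_true,
            pseudogenization_rate = pseudogenization_rate,
            gain_rate = gain_rate,
            planted_duplication_len_bp = as.integer(planted_duplication_len_bp),
            unique_central_len_bp = as.integer(unique_central_len_bp),
            branch_a = branch_a, branch_shared = branch_shared,
            branch_terminal = branch_terminal,
            ribosomal_fraction = ribosomal_fraction,
            seed = as.integer(seed))
  rates <- c("loss_rate", "dup_rate", "snp_per_site", "pseudogenization_rate",
             "gain_rate", "gc_target", "codon_bias_strength", "ribosomal_fraction")
  for (r in rates)
    if (p[[r]] < 0 || p[[r]] > 1) stop(r, " must lie in [0, 1]")
  if (p$n_genes < 10L) stop("n_genes must be >= 10")
  if (p$omega_true <= 0) stop("omega_true must be positive")
  class(p) <- "sim_params"
  p
}

# ---- block representation -------------------------------------------------
# A genome under construction is a list of blocks:
#   gene:   list(kind="gene", tag, seq (coding sense), strand, pseudo,
#                product, ec, region)
#   rna:    list(kind="rna", tag, type ("rRNA"/"tRNA"), seq, strand)
#   spacer: list(kind="spacer", seq, region)

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

sample_gene_seq <- function(len_codons, usage) {
  n_body <- max(1L, len_codons - 2L)
  body <- sample(usage$codon, n_body, replace = TRUE, prob = usage$prob)
  stp <- sample(c("TAA", "TAG", "TGA"), 1L, prob = c(0.7, 0.15, 0.15))
  paste0("ATG", paste(body, collapse = ""), stp)
}

new_spacer <- function(p, region = "") {
  list(kind = "spacer", seq = random_dna(max(1L, rpois(1L, p$intergenic_mean_bp)),
                                         p$gc_target), region = region)
}

#' Assemble a block list into a genome object
#' @noRd
assemble_genome <- function(id, blocks, is_circular = TRUE, tag_prefix = id) {
  seqs <- character(0)
  feats <- empty_features()
  pos <- 1L
  gi <- 0L
  region_coords <- list()
  for (b in blocks) {
    s <- if (b$kind == "gene" && b$strand == "-") revcomp(b$seq) else b$seq
    w <- nchar(s)
    if (w == 0L) next
    if (b$kind %in% c("gene", "rna")) {
      gi <- gi + 1L
      tag <- sprintf("%s_%04d", tag_prefix, gi)
      feats <- rbind(feats, data.frame(
        locus_tag = tag,
        type = if (b$kind == "gene") "CDS" else b$type,
        start = pos, end = pos + w - 1L, strand = b$strand,
        pseudo = isTRUE(b$pseudo),
        product = b$product %||% "", ec = b$ec %||% "",
        stringsAsFactors = FALSE))
    }
    rg <- b$region %||% ""
    if (nzchar(rg)) {
      cur <- region_coords[[rg]] %||% c(pos, pos + w - 1L)
      region_coords[[rg]] <- c(min(cur[1], pos), max(cur[2], pos + w - 1L))
    }
    seqs <- c(seqs, s)
    pos <- pos + w
  }
  g <- genome(id, paste(seqs, collapse = ""), feats, is_circular = is_circular)
  attr(g, "regions") <- region_coords
  g
}

# Cut a genome back into blocks. Requires non-overlapping features (true
# for simulator output). Gene sequences are stored coding-sense.
decompose_genome <- function(g) {
  f <- g$features
  if (nrow(f) > 1L && any(f$start[-1L] <= f$end[-nrow(f)]))
    stop("decompose_genome requires non-overlapping features")
  blocks <- list()
  pos <- 1L
  for (i in seq_len(nrow(f))) {
    if (f$start[i] > pos)
      blocks[[length(blocks) + 1L]] <-
        list(kind = "spacer", seq = substring(g$seq, pos, f$start[i] - 1L),
             region = "")
    s <- substring(g$seq, f$start[i], f$end[i])
    if (f$strand[i] == "-") s <- revcomp(s)
    blocks[[length(blocks) + 1L]] <- if (f$type[i] == "CDS") {
      list(kind = "gene", tag = f$locus_tag[i], seq = s, strand = f$strand[i],
           pseudo = f$pseudo[i], product = f$product[i], ec = f$ec[i],
           region = "")
    } else {
      list(kind = "rna", tag = f$locus_tag[i], type = f$type[i], seq = s,
           strand = f$strand[i], pseudo = FALSE, product = f$product[i],
           ec = "", region = "")
    }
    pos <- f$end[i] + 1L
  }
  if (pos <= nchar(g$seq))
    blocks[[length(blocks) + 1L]] <-
      list(kind = "spacer", seq = substring(g$seq, pos, nchar(g$seq)), region = "")
  blocks
}

#' Simulate an ancestral bacterial genome
#'
#' Genes are drawn codon by codon from the biased codon distribution of
#' [codon_usage_table]; a fraction of genes ("ribosomal proteins") is
#' drawn with boosted bias so a highly-expressed reference set exists for
#' codon adaptation analyses. Intergenic spacers are i.i.d. at the target
#' GC. One rRNA operon (16S + 23S surrogates) and 20 tRNAs are planted.
#'
#' @param params a [sim_params] object.
#' @param id genome/strain identifier.
#' @return list with elements `genome` (a [genome]) and `codon_usage`
#'   (the exact sampling distribution for ordinary genes; the boosted
#'   table for highly expressed genes is attached as attribute
#'   `he_table`).
#' @export
simulate_ancestor <- function(params = sim_params(), id = "ANC") {
  stopifnot(inherits(params, "sim_params"))
  usage <- codon_usage_table(params$codon_bias_strength)
  he_bias <- 1 - (1 - params$codon_bias_strength)^2
  he_usage <- codon_usage_table(he_bias)
  res <- with_seed(params$seed, {
    n <- params$n_genes
    n_he <- max(5L, as.integer(round(params$ribosomal_fraction * n)))
    he_idx <- sample.int(n, min(n_he, n))
    lens <- pmax(35L, as.integer(round(rnorm(n, params$mean_gene_len_codons,
                                             0.35 * params$mean_gene_len_codons))))
    blocks <- list()
    blocks[[1L]] <- new_spacer(params)
    for (i in seq_len(n)) {
      tab <- if (i %in% he_idx) he_usage else usage
      prod <- if (i %in% he_idx)
        sprintf("50S ribosomal protein L%d", match(i, he_idx)) else
        "hypothetical protein"
      blocks[[length(blocks) + 1L]] <- list(
        kind = "gene", tag = "", seq = sample_gene_seq(lens[i], tab),
        strand = sample(c("+", "-"), 1L), pseudo = FALSE,
        product = prod, ec = "", region = "")
      blocks[[length(blocks) + 1L]] <- new_spacer(params)
    }
    # rRNA operon + tRNAs
    rna_blocks <- c(
      list(list(kind = "rna", tag = "", type = "rRNA",
                seq = random_dna(1550L, params$gc_target), strand = "+",
                pseudo = FALSE, product = "16S ribosomal RNA", region = ""),
           list(kind = "spacer", seq = random_dna(80L, params$gc_target),
                region = ""),
           list(kind = "rna", tag = "", type = "rRNA",
                seq = random_dna(2900L, params$gc_target), strand = "+",
                pseudo = FALSE, product = "23S ribosomal RNA", region = "")),
      lapply(seq_len(20L), function(i)
        list(kind = "rna", tag = "", type = "tRNA",
             seq = random_dna(76L, params$gc_target), strand = "+",
             pseudo = FALSE, product = sprintf("tRNA-%02d", i), region = "")))
    ins <- sample(seq_along(blocks), length(rna_blocks))
    for (j in order(ins, decreasing = TRUE)) {
      at <- ins[j]
      blocks <- append(blocks, list(rna_blocks[[j]],
                                    new_spacer(params)), after = at)
    }
    assemble_genome(id, blocks)
  })
  attr(usage, "he_table") <- he_usage
  attr(usage, "he_products") <- "ribosomal protein"
  list(genome = res, codon_usage = usage)
}

# ---- mutation machinery ---------------------------------------------------

# Per sense codon, the ratio of all nonsynonymous single-base changes
# (including changes to stop codons) to the nonsynonymous changes that
# reach another sense codon. The mutation engine never fixes a stop, so
# sense nonsynonymous changes are boosted by this factor to keep the
# realized rate ratio on the NG86 opportunity scale, where stop changes
# count as nonsynonymous sites.
stop_ratio_table <- function() {
  tab <- .pangcn_cache$stop_ratio
  if (!is.null(tab)) return(tab)
  gc <- genetic_code11()
  bases <- c("A", "C", "G", "T")
  sense <- sense_codons()
  tab <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    non_all <- 0L; non_sense <- 0L
    for (pos in 1:3) for (nb in setdiff(bases, substring(cod, pos, pos))) {
      new <- cod
      substring(new, pos, pos) <- nb
      if (gc[[new]] == "*") non_all <- non_all + 1L
      else if (gc[[new]] != gc[[cod]]) {
        non_all <- non_all + 1L; non_sense <- non_sense + 1L
      }
    }
    tab[cod] <- if (non_sense > 0L) non_all / non_sense else 1
  }
  .pangcn_cache$stop_ratio <- tab
  tab
}

# Point mutations on the body codons of a coding-sense gene sequence.
# Proposals are uniform over sites and alternative bases; proposals
# creating a stop codon are rejected. Acceptance probabilities are
# scaled so that the realized nonsynonymous/synonymous rate ratio equals
# omega on the NG86 opportunity scale (see stop_ratio_table): with
# a = omega * r_codon, nonsynonymous proposals are accepted with
# probability a / max(a, 1) and synonymous ones with 1 / max(a, 1).
mutate_gene <- function(seq, rate, omega) {
  cods <- split_codons(seq)
  nb <- length(cods)
  if (nb <= 2L || rate <= 0)
    return(list(seq = seq, n_syn = 0L, n_nonsyn = 0L))
  body_idx <- 2:(nb - 1L)
  nsites <- 3L * length(body_idx)
  target <- rbinom(1L, nsites, min(1, rate))
  if (target == 0L) return(list(seq = seq, n_syn = 0L, n_nonsyn = 0L))
  gc <- genetic_code11()
  sr <- stop_ratio_table()
  bases <- c("A", "C", "G", "T")
  n_syn <- 0L; n_non <- 0L
  acc <- 0L; prop <- 0L; max_prop <- 60L * target + 600L
  while (acc < target && prop < max_prop) {
    prop <- prop + 1L
    ci <- sample(body_idx, 1L)
    pos <- sample.int(3L, 1L)
    old <- cods[[ci]]
    oldb <- substring(old, pos, pos)
    newb <- sample(setdiff(bases, oldb), 1L)
    new <- old
    substring(new, pos, pos) <- newb
    if (gc[[new]] == "*") next
    syn <- gc[[new]] == gc[[old]]
    a <- omega * sr[[old]]
    p_acc <- if (syn) 1 / max(a, 1) else a / max(a, 1)
    if (runif(1L) <= p_acc) {
      cods[[ci]] <- new
      acc <- acc + 1L
      if (syn) n_syn <- n_syn + 1L else n_non <- n_non + 1L
    }
  }
  list(seq = paste(cods, collapse = ""), n_syn = n_syn, n_nonsyn = n_non)
}

mutate_neutral <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(seq)
  k <- rbinom(1L, n, min(1, rate))
  if (k == 0L) return(seq)
  sites <- sample.int(n, k)
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "")[[1]]
  for (s in sites) v[s] <- sample(setdiff(bases, v[s]), 1L)
  paste(v, collapse = "")
}

#' Evolve a descendant strain from an ancestor genome
#'
#' Per gene: Bernoulli loss, Bernoulli tandem duplication (the copy gets
#' its own locus tag and a recorded paralogy), point substitutions with
#' the realized nonsynonymous/synonymous ratio targeting `omega_true`
#' (see the mutation engine), and Bernoulli pseudogenization via a 1-bp
#' frameshifting deletion with the pseudo flag set. Intergenic and RNA
#' sequence evolves neutrally at `snp_per_site`. All rates are multiplied
#' by `scale` (a branch length in units of the parameter set).
#'
#' @param ancestor a [genome] (typically from [simulate_ancestor]).
#' @param params a [sim_params].
#' @param seed seed for this branch.
#' @param id identifier (and locus-tag prefix) for the descendant.
#' @param scale branch-length scale factor applied to all rates.
#' @param drop_tags ancestor locus tags deleted deterministically
#'   (recorded as losses), e.g. a region absent from a lineage.
#' @return list with `genome` (the descendant) and `truth`, a data.frame
#'   with columns `descendant_tag` (NA for lost genes), `ancestor_tag`,
#'   `n_syn`, `n_nonsyn` and `events` (comma-joined labels among
#'   `lost`, `duplicated`, `dup_copy`, `syn_snp`, `nonsyn_snp`,
#'   `indel_pseudo`, `gain`).
#' @export
evolve_strain <- function(ancestor, params, seed, id = "DESC", scale = 1,
                          drop_tags = character()) {
  stopifnot(inherits(ancestor, "genome"), inherits(params, "sim_params"))
  blocks <- decompose_genome(ancestor)
  usage <- codon_usage_table(params$codon_bias_strength)
  res <- with_seed(seed, {
    out <- list()
    truth_anc <- character(0); truth_ev <- character(0)
    truth_syn <- integer(0); truth_non <- integer(0)
    truth_slot <- integer(0)  # index into `out` of the gene block, NA if lost
    r_loss <- min(1, params$loss_rate * scale)
    r_dup <- min(1, params$dup_rate * scale)
    r_snp <- min(1, params$snp_per_site * scale)
    r_pse <- min(1, params$pseudogenization_rate * scale)
    r_gain <- min(1, params$gain_rate * scale)
    for (b in blocks) {
      if (b$kind == "spacer") {
        b$seq <- mutate_neutral(b$seq, r_snp)
        out[[length(out) + 1L]] <- b
        next
      }
      if (b$kind == "rna") {
        b$seq <- mutate_neutral(b$seq, r_snp)
        out[[length(out) + 1L]] <- b
        next
      }
      # gene block
      if (b$tag %in% drop_tags || runif(1L) < r_loss) {
        truth_anc <- c(truth_anc, b$tag); truth_ev <- c(truth_ev, "lost")
        truth_syn <- c(truth_syn, NA_integer_); truth_non <- c(truth_non, NA_integer_)
        truth_slot <- c(truth_slot, NA_integer_)
        next
      }
      dup <- runif(1L) < r_dup
      variants <- if (dup) c("orig", "copy") else "orig"
      for (v in variants) {
        nb <- b
        ev <- character(0)
        if (!nb$pseudo) {
          m <- mutate_gene(nb$seq, r_snp, params$omega_true)
          nb$seq <- m$seq
          if (m$n_syn > 0L) ev <- c(ev, "syn_snp")
          if (m$n_nonsyn > 0L) ev <- c(ev, "nonsyn_snp")
          n_syn <- m$n_syn; n_non <- m$n_nonsyn
        } else {
          nb$seq <- mutate_neutral(nb$seq, r_snp)
          n_syn <- NA_integer_; n_non <- NA_integer_
        }
        if (dup) ev <- c(ev, if (v == "orig") "duplicated" else "dup_copy")
        if (!nb$pseudo && runif(1L) < r_pse) {
          cut <- sample.int(nchar(nb$seq) - 4L, 1L) + 1L
          nb$seq <- paste0(substring(nb$seq, 1L, cut - 1L),
                           substring(nb$seq, cut + 1L, nchar(nb$seq)))
          nb$pseudo <- TRUE
          ev <- c(ev, "indel_pseudo")
        }
        out[[length(out) + 1L]] <- nb
        if (v == "copy")
          out[[length(out) + 1L]] <-
            list(kind = "spacer", seq = random_dna(25L, params$gc_target),
                 region = "")
        truth_anc <- c(truth_anc, b$tag)
        truth_ev <- c(truth_ev, paste(ev, collapse = ","))
        truth_syn <- c(truth_syn, n_syn); truth_non <- c(truth_non, n_non)
        truth_slot <- c(truth_slot, length(out) - (if (v == "copy") 1L else 0L))
      }
      if (r_gain > 0 && runif(1L) < r_gain) {
        len <- max(35L, as.integer(round(rnorm(1L, params$mean_gene_len_codons,
                                               0.35 * params$mean_gene_len_codons))))
        out[[length(out) + 1L]] <- list(
          kind = "gene", tag = "", seq = sample_gene_seq(len, usage),
          strand = sample(c("+", "-"), 1L), pseudo = FALSE,
          product = "hypothetical protein", ec = "", region = "")
        out[[length(out) + 1L]] <- new_spacer(params)
        truth_anc <- c(truth_anc, NA_character_); truth_ev <- c(truth_ev, "gain")
        truth_syn <- c(truth_syn, NA_integer_); truth_non <- c(truth_non, NA_integer_)
        truth_slot <- c(truth_slot, length(out) - 1L)
      }
    }
    if (!any(vapply(out, function(b) b$kind == "gene", logical(1))))
      stop("all genes lost during evolution; lower loss_rate or scale")
    g <- assemble_genome(id, out, tag_prefix = id)
    # recover descendant tags: genes were assembled in `out` order
    featst <- g$features[g$features$type %in% c("CDS", "rRNA", "tRNA"), ]
    gene_or_rna <- which(vapply(out, function(b) b$kind %in% c("gene", "rna"),
                                logical(1)))
    slot_to_tag <- setNames(featst$locus_tag[order(featst$start)], NULL)
    # features are emitted in block order, so slot k maps to k-th feature
    slot_map <- setNames(slot_to_tag, gene_or_rna)
    desc_tag <- ifelse(is.na(truth_slot), NA_character_,
                       slot_map[as.character(truth_slot)])
    truth <- data.frame(descendant_tag = desc_tag,
                        ancestor_tag = truth_anc,
                        n_syn = truth_syn, n_nonsyn = truth_non,
                        events = truth_ev, stringsAsFactors = FALSE)
    list(genome = g, truth = truth)
  })
  res
}

# compose truth maps: t1 maps mid -> ancestor, t2 maps desc -> mid;
# ancestor genes already lost on the first branch are carried over as
# losses so the composed record covers every ancestor gene
compose_truth <- function(t1, t2) {
  m <- match(t2$ancestor_tag, t1$descendant_tag)
  anc <- t1$ancestor_tag[m]
  ev1 <- t1$events[m]
  comp <- data.frame(descendant_tag = t2$descendant_tag,
                     ancestor_tag = anc,
                     n_syn = t2$n_syn + t1$n_syn[m],
                     n_nonsyn = t2$n_nonsyn + t1$n_nonsyn[m],
                     events = ifelse(is.na(ev1) | !nzchar(ev1), t2$events,
                                     ifelse(nzchar(t2$events),
                                            paste(ev1, t2$events, sep = ","), ev1)),
                     stringsAsFactors = FALSE)
  lost1 <- t1[is.na(t1$descendant_tag), , drop = FALSE]
  rbind(comp, lost1)
}

lysine_pathway_genes <- function() {
  data.frame(
    gene = c("lysC", "asd", "dapA", "dapB", "dapD", "araT", "hipO3", "dapF",
             "lysA"),
    ec = c("2.7.2.4", "1.2.1.11", "4.2.1.52", "1.3.1.26", "2.3.1.89",
           "2.6.1.57", "3.5.1.47", "5.1.1.7", "4.1.1.20"),
    product = c("aspartate kinase", "aspartate-semialdehyde dehydrogenase",
                "dihydrodipicolinate synthase", "dihydrodipicolinate reductase",
                "tetrahydrodipicolinate N-acetyltransferase",
                "aromatic amino acid aminotransferase",
                "N-acetyl-diaminopimelate deacetylase",
                "diaminopimelate epimerase", "diaminopimelate decarboxylase"),
    stringsAsFactors = FALSE)
}

#' Simulate a strain triplet with known ground truth
#'
#' Builds an ancestor carrying a planted segmental duplication (two
#' copies, second inverted) flanking a unique central region that holds a
#' complete lysine biosynthesis gene set, then evolves three strains:
#' A diverges on a short branch and keeps the central region; B and C
#' share an intermediate branch on which the central region is lost, then
#' diverge terminally. The ground-truth unrooted topology with the
#' ancestor as outgroup is ((B,C),(A,ancestor)). Three backbone genes
#' shared by all strains carry the lysC / asd / araT EC numbers, so the
#' lysine pathway matrix of the triplet reproduces a
#' complete-versus-three-step contrast.
#'
#' @param params a [sim_params].
#' @return list with `ancestor`, `A`, `B`, `C` (genomes), `truth`
#'   (list of A/B/C truth data.frames mapping to ancestor tags),
#'   `central_tags` (ancestor tags of central-region genes), `planted`
#'   (named coordinates of dup1/central/dup2 in the ancestor) and
#'   `params`.
#' @export
make_triplet <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  anc0 <- simulate_ancestor(params, id = "ANC")$genome
  usage <- codon_usage_table(params$codon_bias_strength)

  anc <- with_seed(derive_seed(params$seed, 1L), {
    blocks <- decompose_genome(anc0)
    # lysine backbone: three shared genes get lysC / asd / araT ECs
    lys <- lysine_pathway_genes()
    gene_idx <- which(vapply(blocks, function(b)
      b$kind == "gene" && !grepl("ribosomal", b$product), logical(1)))
    bb <- sample(gene_idx, 3L)
    for (j in 1:3) {
      blocks[[bb[j]]]$ec <- lys$ec[c(1, 2, 6)][j]
      blocks[[bb[j]]]$product <- lys$product[c(1, 2, 6)][j]
    }
    # central region: genes carrying the full 9-step pathway
    central <- list()
    total <- 0L
    gene_slots <- integer(0)
    while (total < params$unique_central_len_bp) {
      len <- max(35L, as.integer(round(rnorm(1L, params$mean_gene_len_codons,
                                             0.2 * params$mean_gene_len_codons))))
      gseq <- sample_gene_seq(len, usage)
      sp <- new_spacer(params, region = "central")
      central[[length(central) + 1L]] <- list(
        kind = "gene", tag = "", seq = gseq, strand = "+", pseudo = FALSE,
        product = "", ec = "", region = "central")
      gene_slots <- c(gene_slots, length(central))
      central[[length(central) + 1L]] <- sp
      total <- total + nchar(gseq) + nchar(sp$seq)
    }
    # distribute the nine pathway steps round-robin over the central
    # genes; with fewer than nine genes some become multifunctional
    # (several EC numbers), so the planted pathway is always complete
    for (r in seq_len(nrow(lys))) {
      slot <- gene_slots[((r - 1L) %% length(gene_slots)) + 1L]
      old_ec <- central[[slot]]$ec
      central[[slot]]$ec <- if (nzchar(old_ec))
        paste(old_ec, lys$ec[r], sep = ",") else lys$ec[r]
      central[[slot]]$product <- if (nzchar(central[[slot]]$product))
        paste0(central[[slot]]$product, " / ", lys$product[r]) else
        lys$product[r]
    }
    dup <- random_dna(params$planted_duplication_len_bp, params$gc_target)
    planted <- c(
      list(list(kind = "spacer", seq = dup, region = "dup1")),
      central,
      list(list(kind = "spacer", seq = revcomp(dup), region = "dup2")))
    at <- sample(which(vapply(blocks, function(b) b$kind == "spacer",
                              logical(1))), 1L)
    blocks <- append(blocks, planted, after = at)
    assemble_genome("ANC", blocks)
  })

  central_tags <- {
    rg <- attr(anc, "regions")$central
    f <- anc$features
    f$locus_tag[f$type == "CDS" & f$start >= rg[1] & f$end <= rg[2]]
  }

  A <- evolve_strain(anc, params, derive_seed(params$seed, 2L), id = "A",
                     scale = params$branch_a)
  I <- evolve_strain(anc, params, derive_seed(params$seed, 3L), id = "I",
                     scale = params$branch_shared, drop_tags = central_tags)
  B <- evolve_strain(I$genome, params, derive_seed(params$seed, 4L), id = "B",
                     scale = params$branch_terminal)
  C <- evolve_strain(I$genome, params, derive_seed(params$seed, 5L), id = "C",
                     scale = params$branch_terminal)

  list(ancestor = anc, A = A$genome, B = B$genome, C = C$genome,
       truth = list(A = A$truth,
                    B = compose_truth(I$truth, B$truth),
                    C = compose_truth(I$truth, C$truth)),
       central_tags = central_tags,
       planted = attr(anc, "regions"),
       params = params)
}

#' Evolve a reference panel of related genomes
#'
#' Panel genomes diverge from the ancestor on long branches with varied,
#' elevated gene loss, producing the gene-content variation that makes
#' phylogenetic profiles informative. The planted central region is
#' absent from all panel genomes.
#'
#' @param triplet result of [make_triplet] (or a list with `ancestor`,
#'   `central_tags`, `params`).
#' @param n_panel number of panel genomes.
#' @param seed seed.
#' @param divergence branch-scale factor for panel branches.
#' @param loss_range range of per-genome loss-rate scale factors.
#' @return named list of [genome] objects `P1..Pn`.
#' @export
make_panel <- function(triplet, n_panel = 6L, seed = 1L, divergence = 4,
                       loss_range = c(8, 20)) {
  params <- triplet$params
  out <- list()
  for (i in seq_len(n_panel)) {
    pp <- params
    fac <- loss_range[1] + (loss_range[2] - loss_range[1]) *
      ((i - 1) / max(1, n_panel - 1))
    pp$loss_rate <- min(0.6, params$loss_rate * fac / divergence)
    r <- evolve_strain(triplet$ancestor, pp, derive_seed(seed, 100L + i),
                       id = sprintf("P%d", i), scale = divergence,
                       drop_tags = triplet$central_tags)
    out[[sprintf("P%d", i)]] <- r$genome
  }
  out
}

#' Write a truth record as TSV
#' @param truth truth data.frame from [evolve_strain] / [make_triplet].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
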