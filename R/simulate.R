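#' Simulation configuration
#'
#' Conditions for the proteome-evolution simulator: a known binary tree,
#' single-copy core genes shared by all strains, and per-strain decoy genes
#' absent elsewhere, evolved under the uniform 20-state Markov model.
#' Defaults (12 taxa, 20 core genes of 200 residues, 5 decoys per strain,
#' mean root-to-tip depth 0.3 substitutions per site) are the desk-scale
#' stand-in for a bacterial species-group proteome set.
#'
#' @param n_taxa Number of strains (>= 4).
#' @param n_core_genes Single-copy core genes shared by all strains.
#' @param gene_length Residues per gene (>= 20).
#' @param n_decoy_genes Strain-specific decoy genes per strain.
#' @param tree_depth Mean root-to-tip path length, substitutions per site.
#' @param indel_rate Optional per-site gap-opening rate for stress tests
#'   (default 0: core genes stay length-aligned).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 12L, n_core_genes = 20L, gene_length = 200L,
                       n_decoy_genes = 5L, tree_depth = 0.3,
                       indel_rate = 0, seed = 42L) {
  stopifnot(n_taxa >= 4L, gene_length >= 20L, tree_depth > 0,
            n_core_genes >= 1L, n_decoy_genes >= 0L, indel_rate >= 0)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_core_genes = as.integer(n_core_genes),
                 gene_length = as.integer(gene_length),
                 n_decoy_genes = as.integer(n_decoy_genes),
                 tree_depth = tree_depth,
                 indel_rate = indel_rate,
                 seed = as.integer(seed),
                 model = "uniform 20-state Markov"),
            class = "sim_config")
}

#' Sample a random binary tree
#'
#' Random sequential addition: each new leaf is attached to a uniformly
#' chosen existing edge. Branch lengths are drawn Exp(1) and rescaled so
#' the mean root-to-tip path equals `tree_depth`. Deterministic for a
#' fixed seed.
#'
#' @param n_taxa Number of leaves (>= 4), named `S01`, `S02`, ...
#' @param tree_depth Target mean root-to-tip path length.
#' @param seed Integer seed.
#' @return Rooted binary `ape::phylo` tree with positive branch lengths.
#' @export
sample_tree <- function(n_taxa, tree_depth = 0.3, seed = 42L) {
  stopifnot(n_taxa >= 4L, tree_depth > 0)
  set.seed(seed)
  tips <- sprintf("S%02d", seq_len(n_taxa))
  # edges as (parent, child) over string node ids; root is "R"
  parent <- c("R", "R")
  child <- tips[1:2]
  next_internal <- 1L
  for (t in tips[-(1:2)]) {
    e <- sample.int(length(parent), 1L)
    w <- sprintf("I%03d", next_internal)
    next_internal <- next_internal + 1L
    old_child <- child[e]
    child[e] <- w
    parent <- c(parent, w, w)
    child <- c(child, old_child, t)
  }
  len <- stats::rexp(length(parent))
  # rescale: mean root-to-tip over leaves = tree_depth
  depth_of <- function(node) {
    d <- 0
    while (node != "R") {
      e <- match(node, child)
      d <- d + len[e]
      node <- parent[e]
    }
    d
  }
  len <- len * tree_depth / mean(vapply(tips, depth_of, 0))
  kids <- split(seq_along(parent), parent)
  nwk <- function(node) {
    if (!(node %in% names(kids))) return(node)
    es <- kids[[node]]
    paste0("(", paste(vapply(es, function(e)
      paste0(nwk(child[e]), sprintf(":%.17g", len[e])), ""),
      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk("R"), ";"))
}

# Evolve one integer-coded sequence along one branch: each site changes
# with probability (19/20)(1 - exp(-(20/19) b)) to a uniform different
# residue — the uniform 20-state Markov transition for branch length b.
mutate_branch <- function(seq_int, b) {
  p <- (19 / 20) * (1 - exp(-(20 / 19) * b))
  hit <- which(stats::runif(length(seq_int)) < p)
  if (length(hit)) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    seq_int[hit] <- ((seq_int[hit] - 1L + shift) %% 20L) + 1L
  }
  seq_int
}

#' Evolve proteomes along a tree
#'
#' For each core gene, a uniform-random root sequence evolves down the tree
#' under the uniform 20-state model; decoy genes are fresh random sequences
#' private to each strain. Protein ids are shuffled per strain so record
#' order carries no orthology signal. Uses the current RNG state; seed via
#' [simulate_proteomes] for reproducible runs.
#'
#' @param tree Rooted `ape::phylo` tree whose tips are the strain ids.
#' @param cfg A [sim_config].
#' @return List with `proteomes` (named list of [proteome]) and `truth`
#'   (list: `true_tree`, `ortholog_map` data frame gene/strain/protein_id,
#'   `decoy_ids` per strain).
#' @export
evolve_proteomes <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # preorder edge walk (parents always precede children)
  rt <- stats::reorder(tree, "cladewise")
  genes <- sprintf("g%03d", seq_len(cfg$n_core_genes))
  leaf_seqs <- list()  # [[strain]][[gene]] integer vector
  for (t in tree$tip.label) leaf_seqs[[t]] <- list()
  for (g in genes) {
    node_seq <- vector("list", nnode)
    node_seq[[root]] <- sample.int(20L, cfg$gene_length, replace = TRUE)
    for (e in seq_len(nrow(rt$edge))) {
      node_seq[[rt$edge[e, 2L]]] <-
        mutate_branch(node_seq[[rt$edge[e, 1L]]], rt$edge.length[e])
    }
    for (i in seq_len(ntip))
      leaf_seqs[[tree$tip.label[i]]][[g]] <- node_seq[[i]]
  }
  proteomes <- list()
  map <- list()
  decoy_ids <- list()
  for (strain in sort(tree$tip.label)) {
    n_total <- cfg$n_core_genes + cfg$n_decoy_genes
    ids <- sprintf("p%03d", sample.int(n_total))  # shuffled protein ids
    core_ids <- ids[seq_len(cfg$n_core_genes)]
    dec_ids <- if (cfg$n_decoy_genes > 0L)
      ids[cfg$n_core_genes + seq_len(cfg$n_decoy_genes)] else character(0)
    res <- c(vapply(genes, function(g)
               paste(AA20[leaf_seqs[[strain]][[g]]], collapse = ""), ""),
             vapply(seq_len(cfg$n_decoy_genes), function(i)
               paste(AA20[sample.int(20L, cfg$gene_length, replace = TRUE)],
                     collapse = ""), character(1L)))
    ord <- order(c(core_ids, dec_ids))
    all_ids <- c(core_ids, dec_ids)[ord]
    proteomes[[strain]] <- proteome(strain,
                                    seq_records(all_ids, res[ord],
                                                kind = "protein"))
    map[[strain]] <- data.frame(gene = genes, strain_id = strain,
                                protein_id = core_ids)
    decoy_ids[[strain]] <- dec_ids
  }
  list(proteomes = proteomes,
       truth = list(true_tree = tree,
                    ortholog_map = do.call(rbind, unname(map)),
                    decoy_ids = decoy_ids))
}

#' Simulate a full proteome set from scratch
#'
#' Samples a tree with [sample_tree] and evolves proteomes with
#' [evolve_proteomes] under one seed; the same seed yields byte-identical
#' output.
#'
#' @param cfg A [sim_config].
#' @return As [evolve_proteomes].
#' @export
simulate_proteomes <- function(cfg = sim_config()) {
  tree <- sample_tree(cfg$n_taxa, cfg$tree_depth, cfg$seed)
  # sample_tree seeds the RNG; evolution continues the same stream
  evolve_proteomes(tree, cfg)
}

#' Write a simulated dataset to disk
#'
#' Per-strain protein FASTA files, the true tree as Newick, and the
#' ground-truth ortholog map as TSV.
#'
#' @param sim Result of [simulate_proteomes].
#' @param dir Output directory (created if needed).
#' @export
write_sim_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in sim$proteomes)
    write_fasta(p$records, file.path(dir, paste0(p$strain_id, ".faa")))
  write_newick(sim$truth$true_tree, file.path(dir, "true_tree.nwk"))
  utils::write.table(sim$truth$ortholog_map,
                     file.path(dir, "ortholog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
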