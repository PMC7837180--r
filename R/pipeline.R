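#' Run the full core-proteome phylogenomics pipeline
#'
#' Executes, in order: reciprocal-best-hit core-ortholog extraction against
#' the reference strain, per-group progressive alignment, column-wise
#' concatenation into a super-alignment, conserved-block filtering with
#' published default parameters, Kimura-corrected distances, neighbor
#' joining, and bootstrap bipartition support. All intermediates are
#' written to `out_dir`; the run is fully deterministic for a fixed seed.
#'
#' @param proteomes Named list of [proteome] objects, or a directory of
#'   protein FASTA files (one per strain).
#' @param reference Strain id used as the RBH anchor.
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @param e_cutoff E-value cutoff for hits (default 1e-5).
#' @param bootstrap Number of bootstrap replicates (default 500).
#' @param seed Integer seed for the bootstrap resampler.
#' @param scheme A [scoring_scheme].
#' @param filter_params A [block_filter_params]; defaults to the published
#'   defaults for the strain count.
#' @param verbose Print one progress line per stage.
#' @return List of class `run_report`: strain/group counts, alignment
#'   lengths, retained and variable site counts, the annotated tree, the
#'   distance matrix, the super-alignment, the ortholog groups, and the
#'   configuration echo. The `tree_file` field is relative to `out_dir`,
#'   so reports are byte-identical across same-seed reruns.
#' @export
run_pipeline <- function(proteomes, reference, out_dir = NULL,
                         e_cutoff = 1e-5, bootstrap = 500L, seed = 42L,
                         scheme = scoring_scheme(), filter_params = NULL,
                         verbose = FALSE) {
  if (is.character(proteomes)) proteomes <- read_proteome_dir(proteomes)
  stopifnot(length(proteomes) >= 4L)
  names(proteomes) <- vapply(proteomes, `[[`, "", "strain_id")
  if (!(reference %in% names(proteomes)))
    stop("orthology: reference strain '", reference,
         "' not among the proteomes")
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- proteomes[[reference]]
  others <- proteomes[names(proteomes) != reference]
  groups <- extract_core_groups(ref, others, scheme, e_cutoff)
  if (length(groups) == 0L)
    stop("no core proteome: no reference protein has a reciprocal best ",
         "hit in every other proteome")
  say("orthology: %d proteomes -> %d core groups", length(proteomes),
      length(groups))
  if (!is.null(out_dir))
    write_groups_tsv(groups, file.path(out_dir, "groups.tsv"))

  by_id <- lapply(proteomes, function(p)
    stats::setNames(p$records$residues, p$records$ids))
  alignments <- lapply(groups, function(g) {
    seqs <- vapply(names(g$members), function(s)
      by_id[[s]][[g$members[[s]]]], "")
    progressive_align(seqs, scheme)
  })
  names(alignments) <- vapply(groups, `[[`, "", "reference_protein_id")
  say("msa: aligned %d groups", length(alignments))
  if (!is.null(out_dir)) {
    aln_dir <- file.path(out_dir, "aln_dir")
    dir.create(aln_dir, showWarnings = FALSE)
    for (gid in names(alignments))
      write_alignment_fasta(alignments[[gid]],
                            file.path(aln_dir, paste0(gid, ".fasta")))
  }

  sa <- concatenate(alignments)
  say("supermatrix: %d columns in %d partitions", ncol(sa$mat),
      nrow(sa$partitions))

  if (is.null(filter_params)) filter_params <- block_filter_params(nrow(sa$mat))
  sa <- apply_block_filter(sa, filter_params)
  retained <- sum(sa$mask)
  if (retained == 0L)
    warning("block filter retained no columns")
  say("blockfilter: retained %d / %d columns", retained, ncol(sa$mat))
  if (!is.null(out_dir))
    write_super_alignment(sa, file.path(out_dir, "super.fasta"),
                          file.path(out_dir, "partitions.tsv"),
                          file.path(out_dir, "mask.json"))

  D <- distance_matrix(sa)
  tree <- neighbor_joining(D)
  tree <- bootstrap_support(sa, tree, replicates = bootstrap, seed = seed)
  say("phylo: NJ tree with %d bootstrap replicates", bootstrap)
  if (!is.null(out_dir)) {
    write_phylip_dist(D, file.path(out_dir, "dist.phy"))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  }

  report <- structure(list(
    n_proteomes = length(proteomes),
    reference = reference,
    n_core_groups = length(groups),
    superalignment_length = ncol(sa$mat),
    retained_columns = retained,
    variable_sites = count_variable_sites(sa, respect_mask = TRUE),
    tree_file = if (is.null(out_dir)) NA_character_ else "tree.nwk",
    config = list(e_cutoff = e_cutoff, bootstrap = as.integer(bootstrap),
                  seed = as.integer(seed),
                  gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
                  filter = unclass(filter_params)),
    tree = tree, distances = D, super_alignment = sa, groups = groups),
    class = "run_report")
  stopifnot(report$retained_columns <= report$superalignment_length,
            report$variable_sites <= report$retained_columns)
  if (!is.null(out_dir))
    write_report_json(report, file.path(out_dir, "report.json"))
  report
}

#' Write the run report as JSON
#'
#' Serializes the scalar report fields and configuration echo (not the
#' in-memory objects). Deterministic: identical runs produce byte-identical
#' files.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- report[c("n_proteomes", "reference", "n_core_groups",
                  "superalignment_length", "retained_columns",
                  "variable_sites", "tree_file", "config")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("core-proteome phylogenomics run\n")
  cat(sprintf("  proteomes:            %d (reference %s)\n",
              x$n_proteomes, x$reference))
  cat(sprintf("  core ortholog groups: %d\n", x$n_core_groups))
  cat(sprintf("  super-alignment:      %d columns, %d retained\n",
              x$superalignment_length, x$retained_columns))
  cat(sprintf("  variable sites:       %d\n", x$variable_sites))
  cat(sprintf("  bootstrap replicates: %d (seed %d)\n",
              x$config$bootstrap, x$config$seed))
  invisible(x)
}
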