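#' Smith-Waterman local alignment score
#'
#' Maximal local-alignment score under affine gaps, where a gap of length k
#' costs `gap_open + k * gap_extend`. The local-alignment floor makes the
#' score non-negative. Full dynamic programming — no heuristic seeding — so
#' the score is exact.
#'
#' @param a,b Non-empty protein strings.
#' @param scheme A [scoring_scheme].
#' @return Numeric score (integer-valued for integer schemes).
#' @export
smith_waterman_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  sw_score_cpp(toupper(a), toupper(b), scheme_cpp_matrix(scheme),
               scheme$gap_open, scheme$gap_extend)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments scoring at least `score` between a length-m query and a
#' length-n subject.
#'
#' @param score Non-negative alignment score.
#' @param m,n Query and subject lengths (>= 1).
#' @param scheme A [scoring_scheme] supplying `lambda` and `K`.
#' @return Expectation value (non-negative).
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(all(score >= 0), all(m >= 1), all(n >= 1))
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Best hit of a query protein in a target proteome
#'
#' The highest-scoring target protein whose E-value passes the cutoff. Ties
#' on score are broken by the lexicographically smaller subject id, so the
#' result is deterministic.
#'
#' @param query_residues Protein string.
#' @param query_id Id used in the returned hit.
#' @param target A [proteome].
#' @param scheme A [scoring_scheme].
#' @param e_cutoff Maximum E-value (default 1e-5).
#' @return List `(query_id, subject_id, score, evalue)` or `NULL` if no
#'   target passes.
#' @export
best_hit <- function(query_residues, query_id, target,
                     scheme = scoring_scheme(), e_cutoff = 1e-5) {
  stopifnot(inherits(target, "proteome"))
  scores <- as.numeric(sw_score_all_cpp(query_residues,
                                        target$records$residues,
                                        scheme_cpp_matrix(scheme),
                                        scheme$gap_open, scheme$gap_extend))
  pick_best(scores,
            evalue(scores, nchar(query_residues),
                   nchar(target$records$residues), scheme),
            target$records$ids, query_id, e_cutoff)
}

pick_best <- function(scores, evalues, subject_ids, query_id, e_cutoff) {
  pass <- which(evalues <= e_cutoff)
  if (length(pass) == 0L) return(NULL)
  best <- pass[order(-scores[pass], subject_ids[pass])][1L]
  list(query_id = query_id, subject_id = subject_ids[best],
       score = scores[best], evalue = evalues[best])
}

# All-vs-all scores between two proteomes (rows: ref proteins, cols: other).
proteome_score_matrix <- function(ref, other, scheme) {
  S <- sw_score_all_cpp(ref$records$residues, other$records$residues,
                        scheme_cpp_matrix(scheme),
                        scheme$gap_open, scheme$gap_extend)
  dimnames(S) <- list(ref$records$ids, other$records$ids)
  S
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (r, s) is kept iff s is r's best hit in `other` and r is s's best
#' hit in `ref`, both passing the E-value cutoff. Local-alignment scores are
#' symmetric, so one all-vs-all score matrix serves both directions.
#'
#' @param ref,other [proteome] objects.
#' @param scheme A [scoring_scheme].
#' @param e_cutoff Maximum E-value for a hit to count.
#' @return Named character vector: ref protein id -> other protein id
#'   (one-to-one by construction).
#' @export
reciprocal_best_hits <- function(ref, other, scheme = scoring_scheme(),
                                 e_cutoff = 1e-5) {
  stopifnot(inherits(ref, "proteome"), inherits(other, "proteome"))
  S <- proteome_score_matrix(ref, other, scheme)
  E <- evalue(S,
              matrix(nchar(ref$records$residues), nrow(S), ncol(S)),
              matrix(nchar(other$records$residues), nrow(S), ncol(S),
                     byrow = TRUE),
              scheme)
  rid <- rownames(S); oid <- colnames(S)
  fwd <- vapply(seq_len(nrow(S)), function(i) {
    h <- pick_best(S[i, ], E[i, ], oid, rid[i], e_cutoff)
    if (is.null(h)) NA_character_ else h$subject_id
  }, "")
  rev <- vapply(seq_len(ncol(S)), function(j) {
    h <- pick_best(S[, j], E[, j], rid, oid[j], e_cutoff)
    if (is.null(h)) NA_character_ else h$subject_id
  }, "")
  names(fwd) <- rid
  names(rev) <- oid
  keep <- !is.na(fwd) & rev[fwd] == rid
  keep[is.na(keep)] <- FALSE
  out <- fwd[keep]
  stopifnot(!anyDuplicated(out))  # strict RBH is injective
  out
}

#' Extract single-copy core ortholog groups
#'
#' One group per reference protein that has a reciprocal best hit in every
#' other proteome — the reference-anchored core proteome. Groups are ordered
#' by reference protein id.
#'
#' @param ref Reference [proteome].
#' @param others List of [proteome] objects (>= 1).
#' @param scheme A [scoring_scheme].
#' @param e_cutoff Maximum E-value.
#' @return List of `ortholog_group` objects, each with
#'   `reference_protein_id` and `members` (strain id -> protein id, covering
#'   every strain including the reference).
#' @export
extract_core_groups <- function(ref, others, scheme = scoring_scheme(),
                                e_cutoff = 1e-5) {
  stopifnot(length(others) >= 1L)
  maps <- lapply(others, reciprocal_best_hits, ref = ref, scheme = scheme,
                 e_cutoff = e_cutoff)
  core_ids <- Reduce(intersect, lapply(maps, names))
  core_ids <- sort(core_ids)
  other_strains <- vapply(others, `[[`, "", "strain_id")
  lapply(core_ids, function(rid) {
    members <- c(stats::setNames(rid, ref$strain_id),
                 stats::setNames(vapply(maps, `[[`, "", rid), other_strains))
    structure(list(reference_protein_id = rid,
                   members = members[order(names(members))]),
              class = "ortholog_group")
  })
}

#' Write ortholog groups as TSV
#'
#' Columns: `group_id` (the reference protein id), `strain_id`,
#' `protein_id`.
#'
#' @param groups Result of [extract_core_groups].
#' @param path Output path.
#' @export
write_groups_tsv <- function(groups, path) {
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(group_id = g$reference_protein_id,
               strain_id = names(g$members),
               protein_id = unname(g$members))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
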