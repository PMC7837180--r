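#' k-mer dissimilarity between two sequences
#'
#' `1 - shared / min(distinct(a), distinct(b))` over distinct k-mers — the
#' cheap alignment-free distance used to build the guide tree of the
#' progressive aligner.
#'
#' @param a,b Sequences of length >= k.
#' @param k Word size (default 3).
#' @return Dissimilarity in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, k = 3L) {
  if (nchar(a) < k || nchar(b) < k)
    stop("sequence shorter than k = ", k)
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                         seq.int(k, nchar(a))))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                         seq.int(k, nchar(b))))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' UPGMA guide tree
#'
#' Average-linkage agglomeration over a symmetric dissimilarity matrix.
#' Ties are broken by the lexicographically smallest pair of cluster labels
#' (a cluster's label is its smallest member name), so the merge order is
#' deterministic.
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames.
#' @return Nested-list binary tree: a leaf is a taxon name; an internal node
#'   is `list(left, right, height)`.
#' @export
build_guide_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 2L, !is.null(rownames(d)))
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  labels <- rownames(d)
  nodes <- as.list(labels)
  members <- as.list(labels)     # label = lexicographic min of members
  sizes <- rep(1L, length(labels))
  D <- d
  active <- seq_along(labels)
  while (length(active) > 1L) {
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    hits <- which(sub == mn, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    lab <- cbind(vapply(active[hits[, 1L]], function(i) min(members[[i]]), ""),
                 vapply(active[hits[, 2L]], function(i) min(members[[i]]), ""))
    lab_lo <- pmin(lab[, 1L], lab[, 2L])
    lab_hi <- pmax(lab[, 1L], lab[, 2L])
    pick <- order(lab_lo, lab_hi)[1L]
    i <- active[hits[pick, 1L]]
    j <- active[hits[pick, 2L]]
    new <- length(nodes) + 1L
    nodes[[new]] <- list(left = nodes[[i]], right = nodes[[j]],
                         height = mn / 2)
    members[[new]] <- c(members[[i]], members[[j]])
    sizes[new] <- sizes[i] + sizes[j]
    D <- rbind(cbind(D, 0), 0)
    for (k in setdiff(active, c(i, j)))
      D[new, k] <- D[k, new] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / sizes[new]
    active <- c(setdiff(active, c(i, j)), new)
  }
  nodes[[active]]
}

aln_char_matrix <- function(rows) {
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

# frequency profile over MSA_SYMBOLS (columns of the alignment matrix)
profile_counts <- function(mat) {
  idx <- match(mat, MSA_SYMBOLS)
  out <- matrix(0, length(MSA_SYMBOLS), ncol(mat))
  for (j in seq_len(ncol(mat)))
    out[, j] <- tabulate(idx[(j - 1L) * nrow(mat) + seq_len(nrow(mat))],
                         nbins = length(MSA_SYMBOLS))
  out
}

# pairwise column score matrix between two profiles: mean-of-pairs BLOSUM
# score, gaps scoring zero against everything
profile_score_matrix <- function(P1, P2, scheme) {
  B <- matrix(0, length(MSA_SYMBOLS), length(MSA_SYMBOLS))
  res <- intersect(PROTEIN_ALPHABET, rownames(scheme$matrix))
  ii <- match(res, MSA_SYMBOLS)
  B[ii, ii] <- scheme$matrix[res, res]
  if (!("X" %in% res)) {
    xi <- match("X", MSA_SYMBOLS)
    B[xi, seq_len(21L)] <- B[seq_len(21L), xi] <- -1
  }
  n1 <- sum(P1[, 1L]); n2 <- sum(P2[, 1L])
  crossprod(P1, B %*% P2) / (n1 * n2)
}

merge_alignments <- function(m1, m2, scheme, gap_open, gap_extend) {
  S <- profile_score_matrix(profile_counts(m1), profile_counts(m2), scheme)
  res <- nw_profile_path_cpp(S, gap_open, gap_extend)
  expand <- function(m, path) {
    out <- matrix("-", nrow(m), length(path),
                  dimnames = list(rownames(m), NULL))
    nz <- path > 0L
    out[, nz] <- m[, path[nz], drop = FALSE]
    out
  }
  rbind(expand(m1, res$path1), expand(m2, res$path2))
}

#' Progressive multiple alignment of one ortholog group
#'
#' A MUSCLE-style first pass: k-mer distances feed a UPGMA guide tree, and
#' profiles are merged bottom-up by global profile-profile alignment
#' (mean-of-pairs substitution score, affine gaps, terminal gaps penalized
#' like internal ones). No iterative refinement. Output row order equals
#' input order; de-gapping any row reproduces its input sequence exactly.
#'
#' @param seqs Named character vector (strain id -> protein string), >= 2.
#' @param scheme A [scoring_scheme] for the substitution scores.
#' @param k Guide-tree word size (default 3; lowered automatically when a
#'   sequence is shorter than k).
#' @param gap_open,gap_extend Profile-stage affine gap costs
#'   (defaults 10 and 0.5).
#' @return Object of class `alignment`: list with `ids` and equal-length
#'   aligned `rows`.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), k = 3L,
                              gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  ids <- names(seqs)
  k <- min(k, min(nchar(seqs)))
  if (length(seqs) == 2L) {
    guide <- list(left = ids[1L], right = ids[2L], height = 0)
  } else {
    d <- matrix(0, length(seqs), length(seqs), dimnames = list(ids, ids))
    for (i in seq_along(seqs))
      for (j in seq_len(i - 1L))
        d[i, j] <- d[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k)
    guide <- build_guide_tree(d)
  }
  build <- function(node) {
    if (is.character(node)) {
      m <- matrix(strsplit(seqs[[node]], "", fixed = TRUE)[[1L]], nrow = 1L)
      rownames(m) <- node
      return(m)
    }
    merge_alignments(build(node$left), build(node$right),
                     scheme, gap_open, gap_extend)
  }
  m <- build(guide)
  m <- m[match(ids, rownames(m)), , drop = FALSE]
  new_alignment(ids, apply(m, 1L, paste, collapse = ""))
}

#' Construct an alignment object
#'
#' @param ids Row ids (unique).
#' @param rows Aligned strings of equal length; no column may be all gaps.
#' @return Object of class `alignment`.
#' @export
new_alignment <- function(ids, rows) {
  rows <- unname(rows)
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids),
            length(unique(nchar(rows))) == 1L, nchar(rows[[1L]]) >= 1L)
  m <- aln_char_matrix(rows)
  if (any(colSums(m != "-") == 0L)) stop("alignment contains an all-gap column")
  structure(list(ids = ids, rows = rows), class = "alignment")
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  writeLines(paste0(">", aln$ids, "\n", aln$rows), path)
  invisible(path)
}
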