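#' Observed proportion of differing sites between two aligned rows
#'
#' Pairwise deletion: only masked columns where both rows carry a non-gap,
#' non-X residue are compared.
#'
#' @param row_a,row_b Aligned strings of equal length.
#' @param mask Logical vector of retained columns (default: all).
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(row_a, row_b, mask = NULL) {
  a <- strsplit(row_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("rows differ in length")
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  comparable <- mask & !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  n <- sum(comparable)
  if (n == 0L) stop("no comparable sites between the two rows")
  sum(a[comparable] != b[comparable]) / n
}

#' Kimura multiple-hit correction for protein distances
#'
#' `d = -ln(1 - p - 0.2 p^2)`, the standard protein-distance correction
#' applied to the observed difference proportion p. Where the log argument
#' is non-positive (p above ~0.854) the distance is capped with a warning
#' rather than returned infinite.
#'
#' @param p Observed difference proportion(s) in `[0, 1]`.
#' @param cap Distance assigned when the correction diverges (default 10).
#' @return Corrected distance(s), substitutions per site.
#' @export
kimura_correct <- function(p, cap = 10) {
  stopifnot(all(p >= 0 & p <= 1))
  arg <- 1 - p - 0.2 * p^2
  out <- ifelse(arg > 0, -log(pmax(arg, .Machine$double.xmin)), cap)
  if (any(arg <= 0))
    warning(sum(arg <= 0), " distance(s) capped at ", cap,
            " (p too large for the Kimura correction)")
  out
}

#' Kimura-corrected distance matrix from a super-alignment
#'
#' Pairwise [p_distance] over retained columns, corrected with
#' [kimura_correct].
#'
#' @param sa A `super_alignment` with at least 3 strains.
#' @param cap Cap for diverged distances.
#' @return Symmetric numeric matrix with strain ids as dimnames.
#' @export
distance_matrix <- function(sa, cap = 10) {
  stopifnot(inherits(sa, "super_alignment"), nrow(sa$mat) >= 3L)
  pd <- pdist_precompute(sa$mat, which(sa$mask))
  pdist_matrix(pd, seq_along(which(sa$mask)), cap)
}

# Precompute per-pair per-column difference/comparability indicators so the
# bootstrap can resample columns without touching characters again.
pdist_precompute <- function(mat, cols) {
  if (length(cols) == 0L) stop("retention mask is empty")
  taxa <- rownames(mat)
  n <- length(taxa)
  ok <- !(mat[, cols, drop = FALSE] %in% c("-", "X"))
  ok <- matrix(ok, n, length(cols))
  pairs <- utils::combn(n, 2L)
  diffs <- matrix(FALSE, ncol(pairs), length(cols))
  comps <- matrix(FALSE, ncol(pairs), length(cols))
  sub <- mat[, cols, drop = FALSE]
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    comp <- ok[i, ] & ok[j, ]
    comps[k, ] <- comp
    diffs[k, ] <- comp & (sub[i, ] != sub[j, ])
  }
  list(taxa = taxa, pairs = pairs, diffs = diffs, comps = comps)
}

pdist_matrix <- function(pd, col_idx, cap = 10) {
  n <- length(pd$taxa)
  ncomp <- rowSums(pd$comps[, col_idx, drop = FALSE])
  ndiff <- rowSums(pd$diffs[, col_idx, drop = FALSE])
  if (any(ncomp == 0L)) {
    k <- which(ncomp == 0L)[1L]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 pd$taxa[pd$pairs[1L, k]], pd$taxa[pd$pairs[2L, k]]))
  }
  d <- kimura_correct(ndiff / ncomp, cap)
  D <- matrix(0, n, n, dimnames = list(pd$taxa, pd$taxa))
  for (k in seq_len(ncol(pd$pairs)))
    D[pd$pairs[1L, k], pd$pairs[2L, k]] <-
      D[pd$pairs[2L, k], pd$pairs[1L, k]] <- d[k]
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion. On an
#' additive matrix the returned unrooted tree reproduces the input
#' path-length metric exactly. Negative branch-length estimates are clamped
#' to zero; Q ties are broken by the lexicographically smallest taxon pair
#' (a cluster is labelled by its smallest member), so output is
#' deterministic.
#'
#' @param d Symmetric matrix with zero diagonal, finite non-negative
#'   entries, and taxon dimnames (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, !is.null(rownames(d)))
  if (!all(is.finite(d))) stop("distance matrix has non-finite entries")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  labels <- rownames(d)
  n0 <- length(labels)
  # working node strings are partial Newick fragments
  frag <- labels
  clab <- labels                       # lexicographic cluster labels
  D <- d
  active <- seq_len(n0)
  while (length(active) > 3L) {
    m <- length(active)
    sub <- D[active, active, drop = FALSE]
    r <- rowSums(sub)
    Q <- (m - 2) * sub - outer(r, r, `+`)
    diag(Q) <- Inf
    mn <- min(Q)
    hits <- which(Q <= mn + 1e-12 * max(1, abs(mn)), arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    la <- clab[active[hits[, 1L]]]
    lb <- clab[active[hits[, 2L]]]
    pick <- order(pmin(la, lb), pmax(la, lb))[1L]
    i <- active[hits[pick, 1L]]
    j <- active[hits[pick, 2L]]
    ri <- r[match(i, active)]; rj <- r[match(j, active)]
    li <- D[i, j] / 2 + (ri - rj) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new <- length(frag) + 1L
    frag[new] <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    clab[new] <- min(clab[i], clab[j])
    D <- rbind(cbind(D, 0), 0)
    for (k in setdiff(active, c(i, j)))
      D[new, k] <- D[k, new] <- (D[i, k] + D[j, k] - D[i, j]) / 2
    active <- c(setdiff(active, c(i, j)), new)
  }
  a <- active[order(clab[active])]
  if (length(a) == 3L) {
    x <- D[a[1L], a[2L]]; y <- D[a[1L], a[3L]]; z <- D[a[2L], a[3L]]
    bl <- pmax(c((x + y - z) / 2, (x + z - y) / 2, (y + z - x) / 2), 0)
    nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                   frag[a[1L]], bl[1L], frag[a[2L]], bl[2L],
                   frag[a[3L]], bl[3L])
  } else {
    stop("neighbor joining needs at least 3 taxa")
  }
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of the non-trivial splits of an unrooted tree.
# Each split is represented by the sorted member list of the side NOT
# containing the alphabetically first taxon.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  clades <- vector("list", ntip + tree$Nnode)
  collect <- function(node) {
    if (node <= ntip) {
      clades[[node]] <<- tree$tip.label[node]
    } else {
      for (ch in kids[[as.character(node)]]) collect(ch)
      clades[[node]] <<- sort(unlist(
        lapply(kids[[as.character(node)]], function(ch) clades[[ch]])))
    }
  }
  collect(root)
  keys <- character(0)
  nodes <- integer(0)
  for (node in setdiff(seq_len(ntip + tree$Nnode), c(seq_len(ntip), root))) {
    cl <- clades[[node]]
    if (length(cl) < 2L || length(cl) > ntip - 2L) next
    side <- if (anchor %in% cl) sort(setdiff(tree$tip.label, cl)) else cl
    keys <- c(keys, paste(side, collapse = "|"))
    nodes <- c(nodes, node)
  }
  stats::setNames(keys, nodes)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees. Both trees must share the same leaf set.
#'
#' @param t1,t2 `ape::phylo` trees.
#' @return Integer split distance.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- unname(tree_bipartitions(ape::unroot(t1)))
  b2 <- unname(tree_bipartitions(ape::unroot(t2)))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap bipartition support for a reference tree
#'
#' Resamples retained columns with replacement (same count), recomputes the
#' Kimura distance matrix and NJ tree per replicate, and writes, for each
#' internal edge of the reference, the percentage of replicate trees
#' containing that bipartition into the reference's node labels. One
#' seedable generator drives the whole run, so a fixed seed fixes every
#' support value.
#'
#' @param sa A `super_alignment` with at least 4 strains and mask set.
#' @param reference The full-data NJ tree to annotate.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param cap Cap for diverged distances.
#' @return `reference` with integer-percent support values as
#'   `node.label` (empty at the root).
#' @export
bootstrap_support <- function(sa, reference, replicates = 500L, seed = 1L,
                              cap = 10) {
  stopifnot(inherits(sa, "super_alignment"), inherits(reference, "phylo"),
            replicates >= 1L)
  if (nrow(sa$mat) < 4L)
    stop("bootstrap support is undefined for fewer than 4 taxa")
  reference <- ape::unroot(reference)
  cols <- which(sa$mask)
  pd <- pdist_precompute(sa$mat, cols)
  L <- length(cols)
  counts <- integer(0)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    D <- pdist_matrix(pd, idx, cap)
    keys <- unname(tree_bipartitions(neighbor_joining(D)))
    for (k in keys) {
      if (is.na(match(k, names(counts)))) counts[k] <- 0L
      counts[k] <- counts[k] + 1L
    }
  }
  ref_bp <- tree_bipartitions(reference)
  support <- round(100 * ifelse(is.na(counts[ref_bp]), 0L,
                                counts[ref_bp]) / replicates)
  ntip <- length(reference$tip.label)
  labels <- rep("", reference$Nnode)
  node_ids <- as.integer(names(ref_bp))
  labels[node_ids - ntip] <- as.character(as.integer(support))
  reference$node.label <- labels
  reference
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric matrix with taxon dimnames.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste0(formatC(rownames(d)[i], width = -10L),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), ""))
  writeLines(lines, path)
  invisible(path)
}
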