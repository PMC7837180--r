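#' Concatenate per-group alignments into a super-alignment
#'
#' Columns are appended in list order with partition bookkeeping (0-based
#' half-open ranges). Every alignment must cover exactly the same strain
#' set; a missing strain is an error naming the group and strain, never
#' silently gap-padded — core-group construction guarantees full occupancy,
#' so a gap here is a pipeline bug.
#'
#' @param alignments Named list of `alignment` objects; names are group ids.
#' @return Object of class `super_alignment`: `mat` (strain x column
#'   character matrix), `partitions` (data frame `group_id`, `start`,
#'   `end`), `mask` (per-column logical, initialized all-`TRUE`).
#' @export
concatenate <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  strains <- sort(alignments[[1L]]$ids)
  mats <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    stopifnot(inherits(a, "alignment"))
    missing <- setdiff(strains, a$ids)
    extra <- setdiff(a$ids, strains)
    if (length(missing) || length(extra))
      stop(sprintf("group '%s': strain set mismatch (%s)",
                   names(alignments)[i],
                   paste(c(missing, extra), collapse = ", ")))
    m <- aln_char_matrix(a$rows)
    rownames(m) <- a$ids
    mats[[i]] <- m[strains, , drop = FALSE]
  }
  lens <- vapply(mats, ncol, 0L)
  ends <- cumsum(lens)
  sa <- structure(list(mat = do.call(cbind, mats),
                       partitions = data.frame(group_id = names(alignments),
                                               start = ends - lens,
                                               end = ends),
                       mask = rep(TRUE, sum(lens))),
                  class = "super_alignment")
  rownames(sa$mat) <- strains
  sa
}

#' Count variable sites
#'
#' A variable site is a column with at least two distinct non-gap, non-X
#' residues, so the count is invariant to gap coding and ambiguity.
#'
#' @param sa A `super_alignment`.
#' @param respect_mask Count only retained columns (default `TRUE`).
#' @return Integer count.
#' @export
count_variable_sites <- function(sa, respect_mask = TRUE) {
  stopifnot(inherits(sa, "super_alignment"))
  cols <- if (respect_mask) which(sa$mask) else seq_len(ncol(sa$mat))
  if (length(cols) == 0L) return(0L)
  sum(vapply(cols, function(j) {
    r <- unique(sa$mat[, j])
    length(setdiff(r, c("-", "X"))) >= 2L
  }, TRUE))
}

#' Write a super-alignment and its partition table
#'
#' The alignment goes out as aligned FASTA; partitions as a TSV with
#' columns `group_id`, `start`, `end` (0-based half-open); the retention
#' mask, if requested, as a JSON list of retained 0-based column indices.
#'
#' @param sa A `super_alignment`.
#' @param fasta_path,partitions_path Output paths.
#' @param mask_path Optional JSON path for the retained-column indices.
#' @export
write_super_alignment <- function(sa, fasta_path, partitions_path,
                                  mask_path = NULL) {
  stopifnot(inherits(sa, "super_alignment"))
  rows <- apply(sa$mat, 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(sa$mat), "\n", rows), fasta_path)
  utils::write.table(sa$partitions, partitions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mask_path))
    jsonlite::write_json(which(sa$mask) - 1L, mask_path)
  invisible(fasta_path)
}

#' Read an aligned FASTA back into a super-alignment
#'
#' @param fasta_path Aligned FASTA of equal-length rows.
#' @param mask_path Optional JSON list of retained 0-based column indices.
#' @return A `super_alignment` with a single partition.
#' @export
read_super_alignment <- function(fasta_path, mask_path = NULL) {
  # aligned FASTA carries gaps, so plain-protein alphabet checks don't apply
  set <- Biostrings::readBStringSet(fasta_path)
  rows <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  stopifnot(length(unique(nchar(rows))) == 1L)
  m <- aln_char_matrix(rows)
  rownames(m) <- ids
  mask <- rep(TRUE, ncol(m))
  if (!is.null(mask_path)) {
    keep <- unlist(jsonlite::read_json(mask_path)) + 1L
    mask <- seq_len(ncol(m)) %in% keep
  }
  structure(list(mat = m,
                 partitions = data.frame(group_id = "all", start = 0L,
                                         end = ncol(m)),
                 mask = mask),
            class = "super_alignment")
}
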