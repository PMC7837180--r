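#' Block-filter parameters
#'
#' The column-selection parameters of the classic conserved-block filter,
#' with the published defaults derived from the number of sequences N:
#' minimum sequences for a conserved column `IS = floor(N/2) + 1`, minimum
#' sequences for a highly-conserved (flank) column `FS = ceiling(0.85 N)`,
#' maximum run of contiguous nonconserved columns `CP = 8`, minimum block
#' length `BL = 10`, and no gap columns allowed.
#'
#' @param n_seq Number of sequences N.
#' @param min_conserved,min_flank,max_contig_nonconserved,min_block_length
#'   Overrides for IS, FS, CP, BL.
#' @param allow_gaps Gap tolerance; only `"none"` is implemented.
#' @return Object of class `block_filter_params`.
#' @export
block_filter_params <- function(n_seq,
                                min_conserved = floor(n_seq / 2) + 1,
                                min_flank = ceiling(0.85 * n_seq),
                                max_contig_nonconserved = 8L,
                                min_block_length = 10L,
                                allow_gaps = "none") {
  min_flank <- max(min_flank, min_conserved)
  if (!(min_conserved > n_seq / 2 && min_conserved <= min_flank &&
        min_flank <= n_seq))
    stop("require N/2 < min_conserved <= min_flank <= N")
  if (max_contig_nonconserved < 1L || min_block_length < 2L)
    stop("require max_contig_nonconserved >= 1 and min_block_length >= 2")
  allow_gaps <- match.arg(allow_gaps, c("none", "half", "all"))
  if (allow_gaps != "none")
    stop("only allow_gaps = 'none' is implemented")
  structure(list(n_seq = as.integer(n_seq),
                 min_conserved = as.integer(min_conserved),
                 min_flank = as.integer(min_flank),
                 max_contig_nonconserved = as.integer(max_contig_nonconserved),
                 min_block_length = as.integer(min_block_length),
                 allow_gaps = allow_gaps),
            class = "block_filter_params")
}

#' Classify super-alignment columns
#'
#' A column is `gap` if any sequence has a gap there; otherwise, with c the
#' count of its most frequent residue (exact character identity; X counts
#' only as itself), it is `nonconserved` if c < IS, `highly_conserved` if
#' c >= FS, and `conserved` in between.
#'
#' @param sa A `super_alignment`.
#' @param params A [block_filter_params] for `nrow(sa$mat)` sequences.
#' @return Character vector of per-column labels.
#' @export
classify_columns <- function(sa, params = block_filter_params(nrow(sa$mat))) {
  stopifnot(inherits(sa, "super_alignment"),
            params$n_seq == nrow(sa$mat))
  vapply(seq_len(ncol(sa$mat)), function(j) {
    col <- sa$mat[, j]
    if (any(col == "-")) return("gap")
    c_max <- max(table(col))
    if (c_max < params$min_conserved) "nonconserved"
    else if (c_max >= params$min_flank) "highly_conserved"
    else "conserved"
  }, "")
}

#' Select conserved blocks from a column classification
#'
#' Applies, in order: (1) remove every gap column together with any
#' contiguous run of nonconserved columns adjacent to it; (2) remove every
#' contiguous run of more than CP nonconserved columns; (3) trim each
#' surviving segment from both ends up to (and excluding) its first
#' highly-conserved column; (4) drop segments shorter than BL. Empty
#' retention is a legal outcome.
#'
#' @param status Per-column labels from [classify_columns].
#' @param params A [block_filter_params].
#' @return Data frame of retained ranges (`start`, `end`, 0-based
#'   half-open), with the full-length logical mask as attribute `"mask"`.
#' @export
select_blocks <- function(status, params) {
  L <- length(status)
  removed <- logical(L)
  # step 1: gap columns + adjacent nonconserved runs
  gaps <- which(status == "gap")
  removed[gaps] <- TRUE
  for (g in gaps) {
    j <- g - 1L
    while (j >= 1L && status[j] == "nonconserved") {
      removed[j] <- TRUE; j <- j - 1L
    }
    j <- g + 1L
    while (j <= L && status[j] == "nonconserved") {
      removed[j] <- TRUE; j <- j + 1L
    }
  }
  # step 2: over-long nonconserved stretches
  runs <- rle(status == "nonconserved" & !removed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in which(runs$values & runs$lengths > params$max_contig_nonconserved))
    removed[starts[i]:ends[i]] <- TRUE
  # step 3: trim segments to their highly-conserved flanks
  seg <- rle(!removed)
  seg_ends <- cumsum(seg$lengths)
  seg_starts <- seg_ends - seg$lengths + 1L
  ranges <- list()
  for (i in which(seg$values)) {
    a <- seg_starts[i]; b <- seg_ends[i]
    while (a <= b && status[a] != "highly_conserved") a <- a + 1L
    while (b >= a && status[b] != "highly_conserved") b <- b - 1L
    # step 4: minimum block length
    if (a <= b && (b - a + 1L) >= params$min_block_length)
      ranges[[length(ranges) + 1L]] <- c(a - 1L, b)  # 0-based half-open
  }
  out <- if (length(ranges))
    data.frame(start = vapply(ranges, `[[`, 0L, 1L),
               end = vapply(ranges, `[[`, 0L, 2L))
  else data.frame(start = integer(), end = integer())
  mask <- logical(L)
  for (r in ranges) mask[(r[1L] + 1L):r[2L]] <- TRUE
  attr(out, "mask") <- mask
  out
}

#' Apply the block filter to a super-alignment
#'
#' Classifies columns, selects blocks, and writes the result into the
#' super-alignment's retention mask.
#'
#' @param sa A `super_alignment`.
#' @param params A [block_filter_params]; defaults to published defaults
#'   for `nrow(sa$mat)` sequences.
#' @return The `super_alignment` with `mask` set; retained ranges attached
#'   as attribute `"blocks"`.
#' @export
apply_block_filter <- function(sa,
                               params = block_filter_params(nrow(sa$mat))) {
  status <- classify_columns(sa, params)
  blocks <- select_blocks(status, params)
  sa$mask <- attr(blocks, "mask")
  attr(sa, "blocks") <- blocks
  sa
}

#' Human-readable block-filter report
#'
#' One character per column (`.` removed, `*` retained) plus retained
#' ranges in 1-based inclusive coordinates, in the style of the original
#' filter's text output.
#'
#' @param blocks Result of [select_blocks].
#' @param path Output path.
#' @export
write_block_report <- function(blocks, path) {
  mask <- attr(blocks, "mask")
  lines <- c(paste(ifelse(mask, "*", "."), collapse = ""),
             if (nrow(blocks))
               sprintf("block %d: [%d, %d]", seq_len(nrow(blocks)),
                       blocks$start + 1L, blocks$end))
  writeLines(lines, path)
  invisible(path)
}
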