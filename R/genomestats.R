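#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguous bases (`N` and any other
#' IUPAC code) are excluded from both numerator and denominator.
#'
#' @param seq Nucleotide string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  counts <- base_counts(seq)
  denom <- sum(counts)
  if (denom == 0L) stop("sequence has no unambiguous A/C/G/T bases")
  (counts[["G"]] + counts[["C"]]) / denom
}

base_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  m <- match(chars, c("A", "C", "G", "T"))
  counts <- tabulate(m, nbins = 4L)
  names(counts) <- c("A", "C", "G", "T")
  counts
}

#' Windowed GC-skew profile
#'
#' Tiles the sequence with non-overlapping windows (the last may be short)
#' and computes per-window skew (G - C) / (G + C), per-window GC content,
#' and the running sum of defined skews — the cumulative-skew track whose
#' sign change marks replication origin/terminus on bacterial chromosomes.
#' Windows with no G or C get `NA` skew and are excluded from the
#' cumulative sum. The sequence is treated as linear; no wraparound window
#' is formed for circular chromosomes.
#'
#' @param seq Nucleotide string.
#' @param window Window size in bases (default 10000).
#' @return Object of class `skew_profile`: list with `window_size` and a
#'   data frame `values` (columns `window_start` 0-based, `gc_content`,
#'   `skew`, `cumulative`).
#' @export
gc_skew_profile <- function(seq, window = 10000L) {
  stopifnot(window >= 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L == 0L) stop("empty sequence")
  cg <- cumsum(chars == "G")
  cc <- cumsum(chars == "C")
  ca <- cumsum(chars == "A")
  ct <- cumsum(chars == "T")
  starts <- seq.int(0L, L - 1L, by = window)
  ends <- pmin(starts + window, L)      # half-open [start, end)
  win_sum <- function(cs) cs[ends] - c(0L, cs[starts[-1L]])
  g <- win_sum(cg); c_ <- win_sum(cc); a <- win_sum(ca); t_ <- win_sum(ct)
  gc <- g + c_
  skew <- ifelse(gc > 0L, (g - c_) / gc, NA_real_)
  gcc <- ifelse(a + t_ + gc > 0L, gc / (a + t_ + gc), NA_real_)
  cumulative <- cumsum(ifelse(is.na(skew), 0, skew))
  structure(list(window_size = as.integer(window),
                 values = data.frame(window_start = starts,
                                     gc_content = gcc,
                                     skew = skew,
                                     cumulative = cumulative)),
            class = "skew_profile")
}

#' Write genome composition tracks as TSV
#'
#' Columns: `window_start` (0-based), `gc_content`, `gc_skew`,
#' `cumulative_skew`.
#'
#' @param profile A [gc_skew_profile] result.
#' @param path Output TSV path.
#' @export
write_skew_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "skew_profile"))
  df <- profile$values
  names(df) <- c("window_start", "gc_content", "gc_skew", "cumulative_skew")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome summary: length and overall GC content
#'
#' @param path Nucleotide FASTA; multiple records are summed.
#' @return List with `length_bp` and `gc_content`.
#' @export
genome_summary <- function(path) {
  recs <- read_fasta(path, "nucleotide")
  counts <- Reduce(`+`, lapply(recs$residues, base_counts))
  list(length_bp = sum(nchar(recs$residues)),
       gc_content = (counts[["G"]] + counts[["C"]]) / sum(counts))
}
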