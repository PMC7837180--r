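# Independent alignment oracles: every monotone alignment path is walked by
# explicit recursion (no dynamic-programming tables), charging a gap run of
# length k as open + k * ext. Exponential, so only used on short sequences.

brute_global_affine <- function(a, b, B, open, ext) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(ac); n <- length(bc)
  rec <- function(i, j, prev) {
    if (i == m && j == n) return(0)
    best <- -Inf
    if (i < m && j < n)
      best <- max(best, B[ac[i + 1L], bc[j + 1L]] + rec(i + 1L, j + 1L, "m"))
    if (i < m)
      best <- max(best, -(ext + if (prev == "x") 0 else open) +
                    rec(i + 1L, j, "x"))
    if (j < n)
      best <- max(best, -(ext + if (prev == "y") 0 else open) +
                    rec(i, j + 1L, "y"))
    best
  }
  rec(0L, 0L, "start")
}

# local score = best global score over all non-empty substring pairs, with
# the empty alignment (score 0) always available
brute_local_affine <- function(a, b, B, open, ext) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b))
      best <- max(best, brute_global_affine(substr(a, i1, i2),
                                            substr(b, j1, j2), B, open, ext))
  best
}

# score an existing two-row alignment under the affine convention
score_pairwise_rows <- function(r1, r2, B, open, ext) {
  a <- strsplit(r1, "", fixed = TRUE)[[1L]]
  b <- strsplit(r2, "", fixed = TRUE)[[1L]]
  s <- 0
  prev <- "m"
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      s <- s + B[a[k], b[k]]
      prev <- "m"
    } else {
      state <- if (a[k] == "-") "y" else "x"
      s <- s - ext - if (prev == state) 0 else open
      prev <- state
    }
  }
  s
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1L]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# tiny proteome from named residue strings
toy_proteome <- function(strain, seqs) {
  proteome(strain, seq_records(names(seqs), unname(seqs), kind = "protein"))
}

# super-alignment straight from aligned rows (one partition)
toy_super <- function(rows) {
  concatenate(list(g1 = new_alignment(names(rows), unname(rows))))
}

# random column-status string for block-filter property tests
random_status <- function(n) {
  sample(c("gap", "nonconserved", "conserved", "highly_conserved"), n,
         replace = TRUE, prob = c(0.08, 0.32, 0.25, 0.35))
}

# reverse complement for the genome-composition properties
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}
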