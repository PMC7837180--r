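#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout distributed with BLAST (comment lines
#' starting with `#`, a header row of residue letters, then one labelled row
#' per residue).
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue letters as row and column names.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a valid NCBI matrix file: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  mat <- matrix(0L, length(body), length(header),
                dimnames = list(vapply(body, `[[`, "", 1L), header))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.integer(body[[i]][-1L]))
    if (length(vals) != length(header) || anyNA(vals))
      stop("malformed matrix row: ", lines[[i + 1L]])
    mat[i, ] <- vals
  }
  if (!identical(rownames(mat), colnames(mat)))
    stop("matrix row and column labels differ")
  mat
}

#' Alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap costs, and the Karlin-Altschul
#' statistical constants used to turn raw local-alignment scores into
#' expectation values. Defaults are the classic gapped-BLOSUM62 protein
#' parameters: gap open 11, gap extend 1, lambda = 0.267 nats per score unit,
#' K = 0.041. A gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param matrix Substitution matrix with residue letters as dimnames;
#'   defaults to the BLOSUM62 matrix shipped with the package.
#' @param gap_open,gap_extend Positive affine gap costs.
#' @param lambda,K Karlin-Altschul constants (positive).
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (!isTRUE(all(matrix == t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend >= 1))
    stop("require gap_open >= gap_extend >= 1")
  if (!(lambda > 0 && K > 0)) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' The packaged BLOSUM62 matrix
#'
#' @return Integer substitution matrix (24 x 24, standard NCBI letters).
#' @export
blosum62 <- function() {
  env <- .phylocore_cache
  if (is.null(env$blosum62)) {
    env$blosum62 <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "phylocore",
                  mustWork = TRUE))
  }
  env$blosum62
}

.phylocore_cache <- new.env(parent = emptyenv())

# Expand a labelled substitution matrix to the 27x27 letter-indexed integer
# matrix the C++ kernels expect. Letters absent from the scheme get a large
# negative sentinel; X falls back to -1 if the matrix lacks an X row.
scheme_cpp_matrix <- function(scheme) {
  big <- matrix(-10000L, 27L, 27L)
  letters_av <- intersect(rownames(scheme$matrix), LETTERS)
  ix <- match(letters_av, LETTERS)
  big[ix, ix] <- scheme$matrix[letters_av, letters_av]
  if (!("X" %in% letters_av)) {
    xi <- match("X", LETTERS)
    big[xi, ] <- -1L
    big[, xi] <- -1L
  }
  storage.mode(big) <- "integer"
  big
}
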