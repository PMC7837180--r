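#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
NULL

#' Construct a set of sequence records
#'
#' The in-memory carrier for FASTA content: parallel vectors of ids,
#' free-text descriptions and uppercase residue strings.
#'
#' @param ids Character vector of unique, whitespace-free ids.
#' @param residues Character vector of residue strings.
#' @param descriptions Character vector of descriptions (default empty).
#' @param kind `"protein"` or `"nucleotide"`; controls alphabet validation.
#' @return Object of class `seq_records`.
#' @export
seq_records <- function(ids, residues, descriptions = character(length(ids)),
                        kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  stopifnot(length(ids) == length(residues),
            length(ids) == length(descriptions))
  if (length(ids) == 0L) stop("record set must contain at least one record")
  if (any(!nzchar(ids)) || any(grepl("\\s", ids)))
    stop("record ids must be non-empty and contain no whitespace")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id: ", dup[[1L]])
  residues <- toupper(residues)
  if (any(!nzchar(residues))) {
    bad <- ids[!nzchar(residues)][[1L]]
    stop("empty sequence for record: ", bad)
  }
  alphabet <- if (kind == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  ok <- grepl(sprintf("^[%s]*$", paste(alphabet, collapse = "")), residues)
  if (!all(ok)) {
    i <- which(!ok)[[1L]]
    chars <- setdiff(strsplit(residues[[i]], "")[[1L]], alphabet)
    stop(sprintf("record '%s' contains character '%s' outside the %s alphabet",
                 ids[[i]], chars[[1L]], kind))
  }
  structure(list(ids = unname(ids), descriptions = unname(descriptions),
                 residues = unname(residues), kind = kind),
            class = "seq_records")
}

#' Read a FASTA file
#'
#' Headers are split at the first whitespace: the leading token is the record
#' id, the remainder its description. Multi-line sequences are joined,
#' residues uppercased, and the declared alphabet enforced. Stop characters
#' (`*`) in protein sequences are stripped with a warning, as is common in
#' exported proteomes. LF and CRLF files are both accepted.
#'
#' @param path FASTA file (plain or gzip).
#' @param kind `"protein"` or `"nucleotide"`.
#' @return A [seq_records] object preserving file order.
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  residues <- unname(toupper(as.character(set)))
  residues <- gsub("\r", "", residues, fixed = TRUE)
  if (kind == "protein" && any(grepl("*", residues, fixed = TRUE))) {
    warning("stripping '*' stop characters from ", path)
    residues <- gsub("*", "", residues, fixed = TRUE)
  }
  seq_records(ids, residues, descriptions, kind)
}

#' Write records as FASTA
#'
#' Round-trips exactly through [read_fasta]: ids, descriptions and residues
#' are preserved. Lines are LF-terminated.
#'
#' @param records A [seq_records] object.
#' @param path Output path.
#' @param width Positive number of residues per sequence line.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(inherits(records, "seq_records"), width >= 1L)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$descriptions),
                       paste(records$ids, records$descriptions),
                       records$ids)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Construct a proteome
#'
#' @param strain_id Strain identifier (non-empty token).
#' @param records Protein [seq_records].
#' @return Object of class `proteome`.
#' @export
proteome <- function(strain_id, records) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L, nzchar(strain_id),
            inherits(records, "seq_records"), records$kind == "protein")
  structure(list(strain_id = strain_id, records = records), class = "proteome")
}

#' Read one strain's proteome from a protein FASTA file
#'
#' @param path Protein multi-FASTA.
#' @param strain_id Strain id; defaults to the file name without extension.
#' @return A `proteome`.
#' @export
read_proteome <- function(path, strain_id = NULL) {
  if (is.null(strain_id))
    strain_id <- sub("\\.(fa|faa|fasta)(\\.gz)?$", "", basename(path))
  proteome(strain_id, read_fasta(path, "protein"))
}

#' Read all proteomes in a directory
#'
#' @param dir Directory of `.fa`/`.faa`/`.fasta` files (optionally gzipped),
#'   one per strain; the file stem is the strain id.
#' @return Named list of `proteome` objects, sorted by strain id.
#' @export
read_proteome_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|faa|fasta)(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no proteome FASTA files in ", dir)
  ps <- lapply(files, read_proteome)
  names(ps) <- vapply(ps, `[[`, "", "strain_id")
  if (anyDuplicated(names(ps))) stop("duplicate strain ids in ", dir)
  ps[order(names(ps))]
}

#' Serialize a tree as Newick
#'
#' Branch lengths are written with six decimals; bootstrap support values, if
#' present as node labels, are emitted as internal-node labels. The string is
#' `;`-terminated and parseable by any standard Newick reader.
#'
#' @param tree An `ape::phylo` tree with named leaves.
#' @param path Output path, or `NULL` to return the string.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label))
    stop("tree has unnamed leaves")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  labels <- tree$node.label
  fmt <- function(node, edge_idx) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      ch <- kids[[as.character(node)]]
      parts <- vapply(ch, function(e) fmt(tree$edge[e, 2L], e), "")
      lab <- paste0("(", paste(parts, collapse = ","), ")")
      nl <- if (!is.null(labels)) labels[node - ntip] else ""
      if (!is.na(nl) && nzchar(nl)) lab <- paste0(lab, nl)
    }
    if (!is.null(edge_idx) && !is.null(tree$edge.length))
      lab <- paste0(lab, sprintf(":%.6f", tree$edge.length[edge_idx]))
    lab
  }
  s <- paste0(fmt(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    invisible(s)
  } else s
}
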