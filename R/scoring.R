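#' Scoring scheme for local sequence alignment
#'
#' Bundles a symmetric amino-acid substitution matrix with affine gap
#' penalties. A gap of length L costs \code{gap_open + L * gap_extend}.
#' The default matrix is BLOSUM62 with the ambiguity code \code{X} scoring 0
#' against every residue, the usual convention when reconciling an isoform
#' sequence with the observed residues of a crystal structure.
#'
#' @param matrix square numeric matrix with one-letter amino-acid dimnames;
#'   default BLOSUM62 (from \pkg{Biostrings}) restricted to the 20 standard
#'   residues plus \code{X}.
#' @param gap_open non-negative gap opening penalty (default 11).
#' @param gap_extend non-negative gap extension penalty (default 1); must not
#'   exceed \code{gap_open}.
#' @return An object of class \code{scoring_scheme}.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["W", "W"]
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    sv_stop("substitution matrix must be square")
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    sv_stop("substitution matrix must have identical row and column names")
  if (max(abs(matrix - t(matrix))) > 0)
    sv_stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0)
    sv_stop("gap penalties must be non-negative")
  if (gap_extend > gap_open)
    sv_stop("gap_extend must not exceed gap_open")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

# BLOSUM62 over the package alphabet; X scores 0 vs everything
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (comment lines
#' starting with \code{#}, a header row of residue letters, one labelled row
#' per residue).
#'
#' @param path path to the matrix file.
#' @return numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) sv_stop("no matrix content in '%s'", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}
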