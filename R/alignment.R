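#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two amino-acid sequences under the classic
#' Gotoh dynamic programme. Used to reconcile an isoform sequence with the
#' observed-residue sequence of a structure chain, which may differ through
#' unresolved loops, engineered mutations or isoform mismatches.
#'
#' Traceback ties are broken deterministically, preferring diagonal over up
#' (gap in target) over left (gap in query); among equal-scoring end cells the
#' first in column-major order is used. When no residue pair scores positive
#' the alignment is empty with score 0.
#'
#' @param query,target amino-acid strings over the 20 standard residues plus
#'   \code{X} (which scores 0 against everything under the default scheme).
#' @param scheme a [scoring_scheme()].
#' @return An object of class \code{local_alignment}: list with \code{score},
#'   \code{columns} (data.frame \code{q}, \code{t}, \code{q_aa}, \code{t_aa};
#'   \code{NA} marks a gap) and \code{identity}, the fraction of
#'   residue-residue columns whose residues are equal (0 for an empty
#'   alignment).
#' @examples
#' aln <- smith_waterman("HEAGAWGHEE", "PAWHEAE")
#' aln$score
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(target))
    sv_stop("sequences must be non-empty")
  assert_aa(query, "query")
  assert_aa(target, "target")
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  S <- scheme$matrix
  oe <- scheme$gap_open + scheme$gap_extend
  ge <- scheme$gap_extend
  sub <- S[qc, tc, drop = FALSE]   # n x m pair scores

  NEG <- -.Machine$double.xmax / 4
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (left moves)
  F <- matrix(NEG, n + 1L, m + 1L)  # gap in target (up moves)
  for (i in seq_len(n)) {
    Hi1 <- H[i, ]; Fi1 <- F[i, ]
    Hi <- H[i + 1L, ]; Ei <- E[i + 1L, ]; Fi <- F[i + 1L, ]
    for (j in seq_len(m)) {
      e <- max(Hi[j] - oe, Ei[j] - ge)
      f <- max(Hi1[j + 1L] - oe, Fi1[j + 1L] - ge)
      h <- max(0, Hi1[j] + sub[i, j], f, e)
      Ei[j + 1L] <- e; Fi[j + 1L] <- f; Hi[j + 1L] <- h
    }
    H[i + 1L, ] <- Hi; E[i + 1L, ] <- Ei; F[i + 1L, ] <- Fi
  }

  best <- which.max(H)
  score <- H[best]
  if (score <= 0)
    return(new_local_alignment(0, integer(0), integer(0), qc, tc))

  bi <- (best - 1L) %% (n + 1L)       # query index (1-based via H offset)
  bj <- (best - 1L) %/% (n + 1L)      # target index
  qs <- integer(0); ts <- integer(0)
  i <- bi; j <- bj; state <- "H"
  repeat {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h <= 0) break
      if (i > 0L && j > 0L && h == H[i, j] + sub[i, j]) {
        qs <- c(i, qs); ts <- c(j, ts); i <- i - 1L; j <- j - 1L
      } else if (h == F[i + 1L, j + 1L]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") {        # gap in target, consume query residue i
      qs <- c(i, qs); ts <- c(NA_integer_, ts)
      if (F[i + 1L, j + 1L] == H[i, j + 1L] - oe) state <- "H"
      i <- i - 1L
    } else {                          # gap in query, consume target residue j
      qs <- c(NA_integer_, qs); ts <- c(j, ts)
      if (E[i + 1L, j + 1L] == H[i + 1L, j] - oe) state <- "H"
      j <- j - 1L
    }
  }
  new_local_alignment(score, qs, ts, qc, tc)
}

new_local_alignment <- function(score, qs, ts, qc, tc) {
  cols <- data.frame(q = qs, t = ts,
                     q_aa = ifelse(is.na(qs), NA_character_, qc[qs]),
                     t_aa = ifelse(is.na(ts), NA_character_, tc[ts]),
                     stringsAsFactors = FALSE)
  matches <- !is.na(cols$q) & !is.na(cols$t)
  identity <- if (any(matches))
    mean(cols$q_aa[matches] == cols$t_aa[matches]) else 0
  structure(list(score = score, columns = cols, identity = identity),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: score %.1f, %d columns, identity %.3f\n",
              x$score, nrow(x$columns), x$identity))
  invisible(x)
}

#' Build an isoform-to-structure position map from a local alignment
#'
#' Every residue-residue column of the alignment contributes one entry
#' \code{isoform position -> structure residue identifier} (author number plus
#' insertion code). Mismatched columns are kept but flagged. A map whose
#' alignment identity falls below \code{min_identity} is returned with
#' \code{accepted = FALSE} and should be excluded from annotation.
#'
#' @param aln a \code{local_alignment} of the isoform sequence (query) against
#'   the chain's observed-residue sequence (target).
#' @param query_offset 1-based isoform position of the first query residue
#'   (1 when the whole isoform sequence was aligned).
#' @param structure_residues character vector of residue identifiers of the
#'   chain, in observed order; target positions index into it.
#' @param protein_id,structure_id,chain_id identifiers stored in the map.
#' @param min_identity acceptance threshold on alignment identity
#'   (default 0.8).
#' @return An object of class \code{position_map}: list with \code{table}
#'   (data.frame \code{iso_pos}, \code{residue}, \code{mismatch}),
#'   \code{identity}, \code{score}, \code{accepted} and the identifiers.
#' @export
build_position_map <- function(aln, query_offset = 1L, structure_residues,
                               protein_id = NA_character_,
                               structure_id = NA_character_,
                               chain_id = NA_character_,
                               min_identity = 0.8) {
  cols <- aln$columns
  keep <- !is.na(cols$q) & !is.na(cols$t)
  cols <- cols[keep, , drop = FALSE]
  if (nrow(cols) > 0L && max(cols$t) > length(structure_residues))
    sv_stop("alignment target positions exceed the %d residues of chain %s",
            length(structure_residues), chain_id)
  tab <- data.frame(iso_pos = cols$q + query_offset - 1L,
                    residue = structure_residues[cols$t],
                    mismatch = cols$q_aa != cols$t_aa,
                    stringsAsFactors = FALSE)
  structure(list(protein_id = protein_id, structure_id = structure_id,
                 chain_id = chain_id, table = tab,
                 identity = aln$identity, score = aln$score,
                 accepted = aln$identity >= min_identity),
            class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat(sprintf("Position map %s -> %s chain %s: %d positions, identity %.3f%s\n",
              x$protein_id, x$structure_id, x$chain_id, nrow(x$table),
              x$identity, if (x$accepted) "" else " (rejected)"))
  invisible(x)
}

#' Look up a structure residue for an isoform position
#'
#' @param pm an accepted \code{position_map}.
#' @param pos 1-based isoform position.
#' @return list with \code{status} (\code{"mapped"} or \code{"unmapped"}),
#'   \code{residue} (identifier or \code{NA}) and \code{mismatch}. Positions
#'   in alignment gaps or outside the aligned region are reported unmapped,
#'   never extrapolated.
#' @export
map_position <- function(pm, pos) {
  if (!isTRUE(pm$accepted))
    sv_stop("position map %s/%s was not accepted (identity %.3f)",
            pm$structure_id, pm$chain_id, pm$identity)
  hit <- match(pos, pm$table$iso_pos)
  if (is.na(hit))
    return(list(status = "unmapped", residue = NA_character_, mismatch = NA))
  list(status = "mapped", residue = pm$table$residue[hit],
       mismatch = pm$table$mismatch[hit])
}

# inverse lookup: structure residue id -> isoform position (NA if absent)
unmap_residue <- function(pm, residue) {
  hit <- match(residue, pm$table$residue)
  if (is.na(hit)) NA_integer_ else pm$table$iso_pos[hit]
}
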