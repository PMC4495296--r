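#' Parse a PDB-format structure
#'
#' Reads ATOM records of a PDB file (fixed-column format, via
#' \pkg{bio3d}) into a \code{structure3d} object holding heavy atoms only.
#' Hydrogens (and deuteriums) and waters are dropped; for alternate-location
#' duplicates of an atom the highest-occupancy copy is kept (ties go to the
#' first listed); residues left with no atoms are removed. Only the first
#' MODEL of a multi-model file is read. HETATM ligand records are excluded by
#' default.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param structure_id identifier for the structure.
#' @param source \code{"experimental"} or \code{"model"}.
#' @param chain_protein named character vector mapping chain id to protein
#'   accession (at most two mapped chains: monomers and binary complexes).
#' @param include_hetatm keep non-water HETATM records (default \code{FALSE}).
#' @return An object of class \code{structure3d}: list with
#'   \code{structure_id}, \code{source}, \code{chain_protein},
#'   \code{residues} (data.frame \code{chain}, \code{resno}, \code{icode},
#'   \code{aa}, \code{key} in file order) and \code{atoms} (data.frame with
#'   \code{chain}, \code{resno}, \code{icode}, \code{key}, \code{atom},
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{ridx}).
#' @export
parse_pdb <- function(input, structure_id = "structure",
                      source = c("experimental", "model"),
                      chain_protein = character(0),
                      include_hetatm = FALSE) {
  source <- match.arg(source)
  if (length(chain_protein) > 2L)
    sv_stop("at most two mapped chains are supported (got %d)",
            length(chain_protein))
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(startsWith(lines, "ATOM  ")))
    sv_stop("no ATOM records in structure '%s'", structure_id)
  bad <- which(is_atom & (nchar(lines) < 54L |
                 is.na(suppressWarnings(as.numeric(substr(lines, 31, 38))))))
  if (length(bad) > 0L)
    sv_stop("malformed fixed-width ATOM record at line %d of '%s'",
            bad[1L], structure_id)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]

  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                gsub("[^A-Za-z].*$|^[0-9 ]+", "", at$elety),
                                at$elesy)))
  elem[elem == ""] <- substr(gsub("[0-9 ]", "", at$elety), 1L, 1L)[elem == ""]
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  elem <- elem[!elem %in% c("H", "D")]
  if (nrow(at) == 0L)
    sv_stop("no heavy atoms left in structure '%s' after filtering",
            structure_id)

  occ <- ifelse(is.na(at$o), 1, at$o)
  icode <- ifelse(is.na(at$insert) | at$insert %in% c("", " "), "", at$insert)
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  atom_key <- paste(chain, at$resno, icode, at$elety, sep = "\r")
  # alt-loc resolution: highest occupancy wins, ties to the first listed
  ord <- order(atom_key, -occ, seq_len(nrow(at)))
  keep <- ord[!duplicated(atom_key[ord])]
  keep <- sort(keep)                       # restore file order
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]; occ <- occ[keep]
  icode <- icode[keep]; chain <- chain[keep]

  key <- res_key(chain, at$resno, icode)
  ridx <- match(key, unique(key))
  residues <- data.frame(chain = chain, resno = at$resno, icode = icode,
                         aa = bio3d::aa321(at$resid), key = key,
                         stringsAsFactors = FALSE)[!duplicated(key), ,
                                                   drop = FALSE]
  residues$aa[is.na(residues$aa)] <- "X"
  rownames(residues) <- NULL
  atoms <- data.frame(chain = chain, resno = at$resno, icode = icode,
                      key = key, atom = trimws(at$elety), element = elem,
                      x = at$x, y = at$y, z = at$z, occupancy = occ,
                      ridx = ridx, stringsAsFactors = FALSE)
  structure(list(structure_id = structure_id, source = source,
                 chain_protein = chain_protein, residues = residues,
                 atoms = atoms),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d %s (%s): %d chains, %d residues, %d heavy atoms\n",
              x$structure_id, x$source, length(unique(x$residues$chain)),
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' Observed-residue sequence of a chain
#'
#' @param s a \code{structure3d}.
#' @param chain chain identifier.
#' @return list with \code{sequence} (one-letter string in observed order) and
#'   \code{residues} (character vector of residue identifiers, author number
#'   plus insertion code).
#' @export
chain_sequence <- function(s, chain) {
  res <- s$residues[s$residues$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) sv_stop("chain '%s' not found in %s", chain,
                               s$structure_id)
  list(sequence = paste(res$aa, collapse = ""),
       residues = res_id(res$resno, res$icode))
}

#' Minimum heavy-atom distance between two residues
#'
#' @param r1,r2 data.frames of heavy-atom coordinates with columns \code{x},
#'   \code{y}, \code{z} (as in the \code{atoms} slot of a
#'   \code{structure3d}).
#' @return minimum Euclidean distance in Angstrom over all atom pairs.
#' @export
residue_min_distance <- function(r1, r2) {
  m1 <- as.matrix(r1[, c("x", "y", "z")])
  m2 <- as.matrix(r2[, c("x", "y", "z")])
  if (nrow(m1) == 0L || nrow(m2) == 0L)
    sv_stop("both residues must have at least one heavy atom")
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), `+`) - 2 * (m1 %*% t(m2))
  sqrt(max(min(d2), 0))
}

# grid-accelerated search for all residue pairs with min heavy-atom distance
# <= cutoff; cells of edge `cutoff` so contacts only span adjacent cells
residue_contact_pairs <- function(s, cutoff) {
  at <- s$atoms
  aidx <- ridx <- i.aidx <- i.ridx <- x <- y <- z <- ix <- iy <- iz <- NULL
  dt <- data.table::data.table(
    aidx = seq_len(nrow(at)), ridx = at$ridx,
    x = at$x, y = at$y, z = at$z,
    ix = as.integer(floor(at$x / cutoff)),
    iy = as.integer(floor(at$y / cutoff)),
    iz = as.integer(floor(at$z / cutoff)))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifted <- dt[rep(seq_len(nrow(dt)), nrow(off))]
  rep_off <- off[rep(seq_len(nrow(off)), each = nrow(dt)), , drop = FALSE]
  shifted[, `:=`(ix = ix + rep_off[, 1L], iy = iy + rep_off[, 2L],
                 iz = iz + rep_off[, 3L])]
  data.table::setkey(dt, ix, iy, iz)
  pairs <- dt[shifted, on = c("ix", "iy", "iz"), allow.cartesian = TRUE,
              nomatch = NULL]
  pairs <- pairs[aidx < i.aidx & ridx != i.ridx]
  if (nrow(pairs) == 0L)
    return(data.frame(r1 = integer(0), r2 = integer(0),
                      distance = numeric(0)))
  pairs[, distance := sqrt((x - i.x)^2 + (y - i.y)^2 + (z - i.z)^2)]
  pairs <- pairs[distance <= cutoff]
  if (nrow(pairs) == 0L)
    return(data.frame(r1 = integer(0), r2 = integer(0),
                      distance = numeric(0)))
  r1 <- pmin(pairs$ridx, pairs$i.ridx)
  r2 <- pmax(pairs$ridx, pairs$i.ridx)
  agg <- data.table::data.table(r1 = r1, r2 = r2,
                                distance = pairs$distance)
  agg <- agg[, list(distance = min(distance)), by = c("r1", "r2")]
  data.table::setorder(agg, r1, r2)
  as.data.frame(agg)
}

#' Residues in spatial contact with a given residue
#'
#' All residues of the structure whose minimum heavy-atom distance to the
#' center residue is at or below the cutoff (inclusive). Neighbours on the
#' same chain are labelled \code{intra_chain}, those on the other chain
#' \code{interface_partner}; same-chain neighbours adjacent in sequence
#' (author number differing by 1) are additionally flagged
#' \code{sequence_adjacent} so downstream rules can discount them.
#'
#' @param s a \code{structure3d}.
#' @param chain,resno,icode identity of the center residue.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return An object of class \code{neighbor_set}: data.frame with columns
#'   \code{chain}, \code{resno}, \code{icode}, \code{key}, \code{aa},
#'   \code{distance}, \code{relation}, \code{sequence_adjacent}, sorted by
#'   distance then residue key; attributes \code{center} and \code{cutoff}.
#' @export
spatial_neighbors <- function(s, chain, resno, icode = "", cutoff = 5.0) {
  ckey <- res_key(chain, resno, icode)
  cidx <- match(ckey, s$residues$key)
  if (is.na(cidx)) sv_stop("residue %s not found in %s", ckey, s$structure_id)
  pairs <- residue_contact_pairs(s, cutoff)
  hit <- pairs$r1 == cidx | pairs$r2 == cidx
  other <- ifelse(pairs$r1[hit] == cidx, pairs$r2[hit], pairs$r1[hit])
  res <- s$residues[other, , drop = FALSE]
  out <- data.frame(chain = res$chain, resno = res$resno, icode = res$icode,
                    key = res$key, aa = res$aa,
                    distance = pairs$distance[hit],
                    stringsAsFactors = FALSE)
  out$relation <- ifelse(out$chain == chain, "intra_chain",
                         "interface_partner")
  out$sequence_adjacent <- out$chain == chain & abs(out$resno - resno) == 1L
  out <- out[order(out$distance, out$key), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, center = ckey, cutoff = cutoff,
            class = c("neighbor_set", "data.frame"))
}

#' Interface residue pairs between two chains
#'
#' All cross-chain residue pairs whose minimum heavy-atom distance is at or
#' below the cutoff. The interface residue set of chain A is the set of
#' distinct \code{residue_a} values; the result is symmetric under swapping
#' the chains (columns swap accordingly).
#'
#' @param s a \code{structure3d} with both chains present.
#' @param chain_a,chain_b distinct chain identifiers.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return data.frame with columns \code{residue_a}, \code{residue_b}
#'   (residue identifiers) and \code{distance}, sorted by the pair.
#' @export
interface_residues <- function(s, chain_a, chain_b, cutoff = 5.0) {
  if (identical(chain_a, chain_b))
    sv_stop("chain_a and chain_b must be distinct")
  for (ch in c(chain_a, chain_b))
    if (!ch %in% s$residues$chain)
      sv_stop("chain '%s' not found in %s", ch, s$structure_id)
  pairs <- residue_contact_pairs(s, cutoff)
  c1 <- s$residues$chain[pairs$r1]
  c2 <- s$residues$chain[pairs$r2]
  ab <- c1 == chain_a & c2 == chain_b
  ba <- c1 == chain_b & c2 == chain_a
  ia <- c(pairs$r1[ab], pairs$r2[ba])
  ib <- c(pairs$r2[ab], pairs$r1[ba])
  dd <- c(pairs$distance[ab], pairs$distance[ba])
  out <- data.frame(
    residue_a = res_id(s$residues$resno[ia], s$residues$icode[ia]),
    residue_b = res_id(s$residues$resno[ib], s$residues$icode[ib]),
    distance = dd, stringsAsFactors = FALSE)
  out <- out[order(ia, ib), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a structure index table
#'
#' The index maps protein accessions to structure files and chains, one row
#' per chain: columns \code{structure_id}, \code{file}, \code{source},
#' \code{chain}, \code{protein_id}.
#'
#' @param path path to the tab-separated index.
#' @param base_dir directory against which relative \code{file} entries are
#'   resolved (default: the index's own directory).
#' @return data.frame of the index with resolved file paths.
#' @export
read_structure_index <- function(path, base_dir = dirname(path)) {
  idx <- read_tsv(path, colClasses = "character")
  need <- c("structure_id", "file", "source", "chain", "protein_id")
  if (!all(need %in% names(idx)))
    sv_stop("structure index must have columns: %s",
            paste(need, collapse = ", "))
  bad <- !idx$source %in% c("experimental", "model")
  if (any(bad))
    sv_stop("unknown structure source '%s' in index row %d",
            idx$source[which(bad)[1L]], which(bad)[1L])
  rel <- !file.exists(idx$file)
  idx$file[rel] <- file.path(base_dir, idx$file[rel])
  idx
}

# load every structure referenced by an index into structure3d objects
load_structures <- function(index) {
  out <- list()
  for (sid in unique(index$structure_id)) {
    rows <- index[index$structure_id == sid, , drop = FALSE]
    cp <- setNames(rows$protein_id, rows$chain)
    out[[sid]] <- parse_pdb(rows$file[1L], structure_id = sid,
                            source = rows$source[1L], chain_protein = cp)
  }
  out
}
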