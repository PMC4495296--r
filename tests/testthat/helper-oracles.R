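# Independent oracles, coded from first principles and kept free of the
# package's own algorithmic routes.

# --- local alignment: explicit-gap-length DP straight from the definition
# H[i,j] = best score of a local alignment ending at (i,j); gaps of length k
# cost open + k * ext, enumerated exhaustively.
oracle_blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYVX", "")[[1]]
  m <- env$BLOSUM62[aa, aa]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
})

oracle_sw_score <- function(q, t, open = 11, ext = 1, S = oracle_blosum62) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- max(0, H[i, j] + S[qc[i], tc[j]])
    for (k in seq_len(i)) best <- max(best, H[i - k + 1, j + 1] - open - k * ext)
    for (k in seq_len(j)) best <- max(best, H[i + 1, j - k + 1] - open - k * ext)
    H[i + 1, j + 1] <- best
  }
  max(H)
}

# re-score an alignment's columns from scratch (consistency oracle)
oracle_rescore <- function(aln, open = 11, ext = 1, S = oracle_blosum62) {
  cols <- aln$columns
  if (nrow(cols) == 0) return(0)
  score <- 0
  k <- 1
  while (k <= nrow(cols)) {
    if (!is.na(cols$q[k]) && !is.na(cols$t[k])) {
      score <- score + S[cols$q_aa[k], cols$t_aa[k]]
      k <- k + 1
    } else {
      gap_in_q <- is.na(cols$q[k])
      len <- 0
      while (k <= nrow(cols) && is.na(cols[[if (gap_in_q) "q" else "t"]][k])) {
        len <- len + 1
        k <- k + 1
      }
      score <- score - open - len * ext
    }
  }
  score
}

random_aa_string <- function(len, with_x = FALSE) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  if (with_x) aa <- c(aa, "X")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# --- geometry: quadratic all-pairs minimum over heavy atoms, aggregated per
# residue pair from the full atom-atom distance matrix
oracle_contact_pairs <- function(s, cutoff) {
  at <- s$atoms
  na <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  D <- sqrt(pmax(outer(rowSums(xyz^2), rowSums(xyz^2), `+`) -
                   2 * xyz %*% t(xyz), 0))
  ii <- rep(at$ridx, times = na)
  jj <- rep(at$ridx, each = na)
  keep <- ii < jj
  key <- paste(ii[keep], jj[keep])
  mins <- tapply(as.vector(D)[keep], key, min)
  hit <- mins <= cutoff
  parts <- strsplit(names(mins)[hit], " ", fixed = TRUE)
  out <- data.frame(r1 = as.integer(vapply(parts, `[`, "", 1)),
                    r2 = as.integer(vapply(parts, `[`, "", 2)),
                    distance = unname(mins[hit]))
  out[order(out$r1, out$r2), , drop = FALSE]
}

# random residue cloud as a structure3d object (1-3 heavy atoms per residue,
# two chains), built directly rather than through the PDB writer
random_structure <- function(n_residues, box = 30, chains = c("A", "B")) {
  chain <- sample(chains, n_residues, replace = TRUE)
  chain <- chain[order(chain)]
  resno <- unlist(lapply(table(chain), seq_len), use.names = FALSE)
  aa <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n_residues,
               replace = TRUE)
  natoms <- sample(1:3, n_residues, replace = TRUE)
  centers <- matrix(runif(3 * n_residues, 0, box), ncol = 3)
  rows <- lapply(seq_len(n_residues), function(i) {
    off <- matrix(runif(3 * natoms[i], -0.8, 0.8), ncol = 3)
    data.frame(chain = chain[i], resno = resno[i], icode = "",
               key = paste0(chain[i], ":", resno[i]), aa = aa[i],
               atom = c("CA", "CB", "CG")[seq_len(natoms[i])],
               element = "C",
               x = centers[i, 1] + off[, 1], y = centers[i, 2] + off[, 2],
               z = centers[i, 3] + off[, 3], occupancy = 1,
               ridx = i, stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  residues <- data.frame(chain = chain, resno = resno, icode = "", aa = aa,
                         key = paste0(chain, ":", resno),
                         stringsAsFactors = FALSE)
  cp <- stats::setNames(paste0("PROT", seq_along(chains)), chains)
  structure(list(structure_id = "rand", source = "experimental",
                 chain_protein = cp, residues = residues, atoms = atoms),
            class = "structure3d")
}

# rigid motion: random proper rotation + translation applied to all atoms
apply_rigid_motion <- function(s, seed) {
  if (!exists(".Random.seed", globalenv())) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- runif(3, -50, 50)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t0[1]
  s$atoms$y <- xyz[, 2] + t0[2]
  s$atoms$z <- xyz[, 3] + t0[3]
  s
}

# --- translation: whole-CDS re-translation after mutating the chromosome.
# CDS extraction and reverse complement are coded independently (substring
# and chartr) of the package's Biostrings-based route.
oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

oracle_protein <- function(tm, chrom_seq) {
  ex <- tm$cds_exons
  cds <- paste(vapply(seq_len(nrow(ex)), function(i)
    substr(chrom_seq, ex[i, "start"], ex[i, "end"]), ""), collapse = "")
  if (tm$strand == "-") cds <- oracle_revcomp(cds)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# expected outcome of a genomic SNV by diffing whole-protein translations
oracle_translate <- function(gv, tm, chrom_seq) {
  p_ref <- oracle_protein(tm, chrom_seq)
  mut <- chrom_seq
  substr(mut, gv$pos, gv$pos) <- gv$alt
  p_alt <- oracle_protein(tm, mut)
  diff <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(diff) == 0)
    list(type = "synonymous")
  else
    list(type = "substitution", position = diff[1],
         ref_aa = substr(p_ref, diff[1], diff[1]),
         alt_aa = substr(p_alt, diff[1], diff[1]))
}

# --- metrics: independent formula route
oracle_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / n,
       precision = if (tp + fp == 0) NaN else tp / (tp + fp),
       recall = if (tp + fn == 0) NaN else tp / (tp + fn),
       mcc = if (mcc_den == 0) NaN else (tp * tn - fp * fn) / mcc_den)
}
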