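#' Parse a variant input file
#'
#' Two dialects are supported. \code{protein_tsv} is a tab-separated table
#' with header \code{protein_id position ref_aa alt_aa} describing amino-acid
#' substitutions directly. \code{vcf_lite} is the body of a VCF v4 file
#' (columns CHROM POS ID REF ALT, \code{#}-prefixed header lines ignored)
#' restricted to single-nucleotide variants; records with multi-nucleotide
#' REF or ALT are skipped with a warning, as the system's scope is SNVs.
#'
#' @param input path to the file, or a character vector of its lines.
#' @param dialect \code{"protein_tsv"} or \code{"vcf_lite"}.
#' @return For \code{protein_tsv} a data.frame of class
#'   \code{protein_substitutions} with columns \code{protein_id},
#'   \code{position}, \code{ref_aa}, \code{alt_aa}, \code{line}; for
#'   \code{vcf_lite} a data.frame of class \code{genomic_variants} with
#'   columns \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{line}.
#'   Input order is preserved and \code{line} records the source line number.
#' @export
parse_variants <- function(input, dialect = c("protein_tsv", "vcf_lite")) {
  dialect <- match.arg(dialect)
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  if (dialect == "protein_tsv") parse_protein_tsv(lines)
  else parse_vcf_lite(lines)
}

parse_protein_tsv <- function(lines) {
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) sv_stop("no content in variant input")
  header <- strsplit(lines[keep[1L]], "\t", fixed = TRUE)[[1]]
  need <- c("protein_id", "position", "ref_aa", "alt_aa")
  if (!identical(header[seq_along(need)], need))
    sv_stop("protein_tsv header must be: %s", paste(need, collapse = "\t"))
  rows <- lapply(keep[-1L], function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      sv_stop("line %d: expected 4 tab-separated fields, got %d", ln,
              length(f))
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L)
      sv_stop("line %d: position '%s' is not a positive integer", ln, f[2L])
    for (k in 3:4)
      if (!f[k] %in% c(AA_ALPHABET, "*"))
        sv_stop("line %d: '%s' is not an amino-acid code", ln, f[k])
    if (f[3L] == f[4L])
      sv_stop("line %d: ref_aa equals alt_aa ('%s')", ln, f[3L])
    data.frame(protein_id = f[1L], position = pos, ref_aa = f[3L],
               alt_aa = f[4L], line = ln, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(protein_id = character(0), position = integer(0),
               ref_aa = character(0), alt_aa = character(0),
               line = integer(0))
  class(out) <- c("protein_substitutions", "data.frame")
  out
}

parse_vcf_lite <- function(lines) {
  rows <- list()
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(trimws(l)) || startsWith(l, "#")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      sv_stop("line %d: expected at least 5 VCF fields, got %d", ln,
              length(f))
    ref <- toupper(f[4L]); alt <- toupper(f[5L])
    if (nchar(ref) != 1L || nchar(alt) != 1L) {
      warning(sprintf("line %d: skipping non-SNV record (%s>%s)", ln, ref,
                      alt), call. = FALSE)
      next
    }
    if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
      sv_stop("line %d: alleles must be single nucleotides (got %s>%s)", ln,
              ref, alt)
    if (ref == alt)
      sv_stop("line %d: REF equals ALT ('%s')", ln, ref)
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L)
      sv_stop("line %d: POS '%s' is not a positive integer", ln, f[2L])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1L], pos = pos, ref = ref, alt = alt, line = ln,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      line = integer(0))
  else out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("genomic_variants", "data.frame")
  out
}

#' Serialize parsed variants back to their input dialect
#'
#' Inverse of [parse_variants()] on well-formed records.
#'
#' @param variants a \code{protein_substitutions} or \code{genomic_variants}
#'   data.frame.
#' @return character vector of file lines (including the header for
#'   protein_tsv).
#' @export
serialize_variants <- function(variants) {
  if (inherits(variants, "protein_substitutions"))
    c("protein_id\tposition\tref_aa\talt_aa",
      sprintf("%s\t%d\t%s\t%s", variants$protein_id, variants$position,
              variants$ref_aa, variants$alt_aa))
  else if (inherits(variants, "genomic_variants"))
    c("#CHROM\tPOS\tID\tREF\tALT",
      sprintf("%s\t%d\t.\t%s\t%s", variants$chrom, variants$pos,
              variants$ref, variants$alt))
  else sv_stop("unknown variant table class")
}

#' Read transcript models from a TSV
#'
#' Columns: \code{transcript_id}, \code{protein_id}, \code{gene_id},
#' \code{chrom}, \code{strand} (\code{+} or \code{-}) and \code{cds_exons},
#' the ordered coding intervals as \code{start-end} pairs joined by \code{;}
#' (1-based inclusive genomic coordinates, sorted by genomic start,
#' non-overlapping). The translation phase of the first CDS base is assumed
#' 0, so the total CDS length must be divisible by 3; violating models are
#' rejected at load.
#'
#' @param path path to the TSV.
#' @return list of transcript models, each a list with the fields above and
#'   \code{cds_exons} as a two-column integer matrix (\code{start},
#'   \code{end}).
#' @export
read_transcript_models <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("transcript_id", "protein_id", "gene_id", "chrom", "strand",
            "cds_exons")
  if (!all(need %in% names(df)))
    sv_stop("transcript model TSV must have columns: %s",
            paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    parts <- strsplit(strsplit(df$cds_exons[i], ";", fixed = TRUE)[[1]],
                      "-", fixed = TRUE)
    ex <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
    colnames(ex) <- c("start", "end")
    if (any(is.na(ex)) || any(ex[, "end"] < ex[, "start"]))
      sv_stop("transcript %s: malformed cds_exons", df$transcript_id[i])
    if (is.unsorted(ex[, "start"], strictly = TRUE))
      sv_stop("transcript %s: exons must be sorted by genomic start",
              df$transcript_id[i])
    if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"]))
      sv_stop("transcript %s: exons overlap", df$transcript_id[i])
    if (!df$strand[i] %in% c("+", "-"))
      sv_stop("transcript %s: strand must be + or -", df$transcript_id[i])
    if (sum(ex[, "end"] - ex[, "start"] + 1L) %% 3L != 0L)
      sv_stop("transcript %s: CDS length not divisible by 3",
              df$transcript_id[i])
    list(transcript_id = df$transcript_id[i], protein_id = df$protein_id[i],
         gene_id = df$gene_id[i], chrom = df$chrom[i], strand = df$strand[i],
         cds_exons = ex)
  })
}

# genomic position -> 1-based CDS offset (NA when outside all CDS exons)
cds_offset_of <- function(tm, pos) {
  ex <- tm$cds_exons
  lens <- ex[, "end"] - ex[, "start"] + 1L
  hit <- which(pos >= ex[, "start"] & pos <= ex[, "end"])
  if (length(hit) == 0L) return(NA_integer_)
  if (tm$strand == "+") {
    before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
    as.integer(unname(before + (pos - ex[hit, "start"] + 1L)))
  } else {
    # on the minus strand the CDS starts at the highest genomic coordinate
    after <- if (hit < nrow(ex)) sum(lens[seq(hit + 1L, nrow(ex))]) else 0L
    as.integer(unname(after + (ex[hit, "end"] - pos + 1L)))
  }
}

# coding-strand CDS sequence of a transcript model
cds_sequence <- function(tm, genome) {
  chrom_seq <- genome[[tm$chrom]]
  if (is.null(chrom_seq)) sv_stop("chromosome '%s' not in genome", tm$chrom)
  pieces <- apply(tm$cds_exons, 1L, function(e)
    as.character(Biostrings::subseq(chrom_seq, e[1L], e[2L])))
  cds <- paste(pieces, collapse = "")
  if (tm$strand == "-")
    cds <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

#' Translate a genomic SNV into a protein substitution
#'
#' Locates the variant within the transcript's CDS (strand-aware: on the
#' minus strand the CDS runs 3' to 5' along genomic coordinates with
#' complemented bases), computes codon index
#' \code{floor((cds_offset - 1) / 3) + 1}, and translates the reference and
#' mutated codons with the standard genetic code. Stop codons translate to
#' \code{*}; stop-gain and stop-loss substitutions are carried through, not
#' dropped.
#'
#' @param gv one genomic variant: list or single-row data.frame with
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}.
#' @param tm a transcript model (see [read_transcript_models()]).
#' @param genome a named list of \code{DNAString} chromosome sequences (see
#'   [read_genome()]).
#' @return list with \code{type} one of \code{"substitution"},
#'   \code{"synonymous"}, \code{"non_coding"}; for coding outcomes also
#'   \code{protein_id}, \code{position} (codon index), \code{ref_aa},
#'   \code{alt_aa}, \code{cds_offset}.
#' @export
translate_genomic_variant <- function(gv, tm, genome) {
  if (gv$chrom != tm$chrom)
    sv_stop("variant chromosome '%s' does not match transcript '%s'",
            gv$chrom, tm$chrom)
  off <- cds_offset_of(tm, gv$pos)
  if (is.na(off)) return(list(type = "non_coding"))
  cds <- cds_sequence(tm, genome)
  ref_base <- gv$ref; alt_base <- gv$alt
  if (tm$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_base <- comp[[ref_base]]; alt_base <- comp[[alt_base]]
  }
  if (substr(cds, off, off) != ref_base)
    sv_stop(paste0("reference mismatch at %s:%d: genome has '%s' on the ",
                   "coding strand, variant says '%s'"),
            gv$chrom, gv$pos, substr(cds, off, off), ref_base)
  codon_idx <- (off - 1L) %/% 3L + 1L
  c0 <- 3L * (codon_idx - 1L) + 1L
  ref_codon <- substr(cds, c0, c0 + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, off - c0 + 1L, off - c0 + 1L) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- code[[ref_codon]]; alt_aa <- code[[alt_codon]]
  if (ref_aa == alt_aa)
    return(list(type = "synonymous", protein_id = tm$protein_id,
                position = codon_idx, ref_aa = ref_aa, alt_aa = alt_aa,
                cds_offset = off))
  list(type = "substitution", protein_id = tm$protein_id,
       position = codon_idx, ref_aa = ref_aa, alt_aa = alt_aa,
       cds_offset = off)
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file of chromosome sequences.
#' @return named list of \code{DNAString} objects; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) set[[i]])
  names(out) <- names(set)
  out
}

#' Read an isoform catalog
#'
#' Columns: \code{gene_id}, \code{protein_id}, \code{principal}
#' (\code{0}/\code{1}), \code{sequence} (amino-acid string over the 20
#' standard residues plus \code{X}). A consistent catalog flags at most one
#' principal isoform per gene.
#'
#' @param path path to the TSV.
#' @return data.frame of class \code{isoform_catalog}.
#' @export
read_isoform_catalog <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("gene_id", "protein_id", "principal", "sequence")
  if (!all(need %in% names(df)))
    sv_stop("isoform catalog must have columns: %s",
            paste(need, collapse = ", "))
  df$principal <- df$principal %in% c("1", "TRUE", "true", "yes")
  if (any(!nzchar(df$sequence)))
    sv_stop("isoform catalog contains an empty sequence")
  for (i in seq_len(nrow(df))) assert_aa(df$sequence[i], df$protein_id[i])
  nprin <- tapply(df$principal, df$gene_id, sum)
  if (any(nprin > 1L))
    sv_stop("gene %s flags more than one principal isoform",
            names(nprin)[which(nprin > 1L)[1L]])
  class(df) <- c("isoform_catalog", "data.frame")
  df
}

#' Select the principal isoform of a gene
#'
#' Returns the protein flagged principal; if no entry is flagged, the longest
#' sequence wins, with remaining ties broken by the lexicographically
#' smallest protein accession so the choice is deterministic.
#'
#' @param gene_id gene accession.
#' @param catalog an \code{isoform_catalog}.
#' @return protein accession of the selected isoform.
#' @export
select_principal_isoform <- function(gene_id, catalog) {
  rows <- catalog[catalog$gene_id == gene_id, , drop = FALSE]
  if (nrow(rows) == 0L) sv_stop("gene '%s' not in isoform catalog", gene_id)
  flagged <- rows[rows$principal, , drop = FALSE]
  if (nrow(flagged) >= 1L) return(flagged$protein_id[1L])
  len <- nchar(rows$sequence)
  rows <- rows[order(-len, rows$protein_id), , drop = FALSE]
  rows$protein_id[1L]
}

# catalog sequence for a protein accession (NA when absent)
catalog_sequence <- function(catalog, protein_id) {
  hit <- match(protein_id, catalog$protein_id)
  if (is.na(hit)) NA_character_ else catalog$sequence[hit]
}
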