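#' Specification of the synthetic validation fixture
#'
#' Describes a deterministic synthetic study: a two-chain complex with
#' engineered interface contacts, planted sequence features, somatic records
#' and predictor calls, and a labelled variant set. The same seed and spec
#' always produce byte-identical files.
#'
#' The default spec emulates the shape of a structure-aware validation
#' study on a binary complex: 24 variants on the first protein, 14 labelled
#' pathogenic and 10 neutral. Eleven pathogenic variants are planted with
#' evidence spanning the five rule clauses (three on functional sites, two at
#' interface contacts whose partner residue carries a binding site, two at
#' bare interface contacts, two on somatic hotspots, two with a damaging
#' predictor majority); three pathogenic variants carry no evidence at all
#' (they have only tolerated predictions), and the ten neutral variants sit
#' in feature-free regions with tolerated predictions. Under the default
#' rule the implied confusion matrix is therefore
#' \code{tp = 11, fp = 0, fn = 3, tn = 10}.
#'
#' @param seed integer RNG seed.
#' @param n_residues_per_chain residues per chain (default 40).
#' @param chain_separation baseline distance between the chains in Angstrom
#'   (default 20).
#' @param contact_distance engineered minimum heavy-atom distance for
#'   interface contacts in Angstrom (default 4.5).
#' @param label_plants data.frame with \code{position} (isoform position on
#'   the first protein), \code{label} (\code{pathogenic}/\code{neutral}) and
#'   \code{evidence}, one of \code{direct_site}, \code{interface_feature},
#'   \code{interface}, \code{somatic}, \code{predictor}, \code{none};
#'   \code{NULL} for the default 14+10 design.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, n_residues_per_chain = 40L,
                         chain_separation = 20, contact_distance = 4.5,
                         label_plants = NULL) {
  if (is.null(label_plants)) {
    label_plants <- data.frame(
      position = c(8L, 10L, 12L, 16L, 20L, 24L, 28L, 32L, 34L, 36L, 38L,
                   40L, 42L, 44L,
                   7L, 9L, 13L, 15L, 18L, 22L, 26L, 30L, 43L, 47L),
      label = c(rep("pathogenic", 14L), rep("neutral", 10L)),
      evidence = c("direct_site", "direct_site", "direct_site",
                   "interface_feature", "interface_feature",
                   "interface", "interface", "somatic", "somatic",
                   "predictor", "predictor", "none", "none", "none",
                   rep("none", 10L)),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(label_plants$position))
    sv_stop("label plant positions must be distinct")
  structure(list(seed = as.integer(seed),
                 n_residues_per_chain = as.integer(n_residues_per_chain),
                 chain_separation = chain_separation,
                 contact_distance = contact_distance,
                 label_plants = label_plants,
                 protein_a = "ENSPTEST001", protein_b = "ENSPTEST002",
                 gene_a = "ENSGTEST001", gene_b = "ENSGTEST002",
                 structure_id = "cplx1",
                 # chain A covers isoform positions 6..(5 + n) of protein A,
                 # with author numbering offset by +100
                 iso_offset_a = 5L, resno_offset_a = 100L),
            class = "fixture_spec")
}

# run fn with a seeded, restored RNG state
with_fixture_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# deterministic protein sequences of the fixture (no X, 20 standard residues)
fixture_sequences <- function(spec) {
  n <- spec$n_residues_per_chain
  with_fixture_rng(spec$seed, function() {
    aa <- AA_ALPHABET[AA_ALPHABET != "X"]
    list(protein_a = paste(sample(aa, n + 10L, replace = TRUE),
                           collapse = ""),
         protein_b = paste(sample(aa, n, replace = TRUE), collapse = ""))
  })
}

# interface contact pairs implied by the plants: chain indices + distance
fixture_contacts <- function(spec) {
  lp <- spec$label_plants
  pos <- lp$position[lp$evidence %in% c("interface", "interface_feature")]
  data.frame(a = pos - spec$iso_offset_a, b = pos - spec$iso_offset_a,
             distance = rep(spec$contact_distance, length(pos)))
}

# deterministic alternate residue for a reference residue
fixture_alt_aa <- function(ref) {
  aa <- AA_ALPHABET[AA_ALPHABET != "X"]
  aa[ifelse(match(ref, aa) == length(aa), 1L, match(ref, aa) + 1L)]
}

#' Generate a synthetic two-chain PDB structure
#'
#' Lays two chains of Calpha/Cbeta pseudo-residues on extended, slightly
#' jittered paths separated by \code{chain_separation} Angstrom, then places
#' each requested contact pair so that its minimum heavy-atom distance equals
#' the target exactly. Output is valid fixed-column PDB text; the same spec
#' and seed give identical bytes.
#'
#' @param spec a [fixture_spec()].
#' @return character vector of PDB lines.
#' @export
generate_structure <- function(spec) {
  contacts <- fixture_contacts(spec)
  if (nrow(contacts) > 0L && any(contacts$distance < 1.0))
    sv_stop("contact distances must be >= 1 Angstrom")
  n <- spec$n_residues_per_chain
  if (nrow(contacts) > 0L &&
      (any(contacts$a < 1L | contacts$a > n | contacts$b < 1L |
           contacts$b > n)))
    sv_stop("contact residues outside the chains")
  seqs <- fixture_sequences(spec)
  seq_a <- substr(seqs$protein_a, spec$iso_offset_a + 1L,
                  spec$iso_offset_a + n)
  seq_b <- seqs$protein_b
  jitter <- with_fixture_rng(spec$seed + 1L,
                             function() round(runif(2L * n, -0.3, 0.3), 3))
  za <- jitter[seq_len(n)]; zb <- jitter[n + seq_len(n)]
  xa <- 4 * seq_len(n); ya <- rep(0, n)
  xb <- 4 * seq_len(n); yb <- rep(spec$chain_separation, n)
  for (k in seq_len(nrow(contacts))) {
    a <- contacts$a[k]; b <- contacts$b[k]
    xb[b] <- xa[a]; yb[b] <- ya[a] + contacts$distance[k]; zb[b] <- za[a]
  }
  aa3 <- setNames(bio3d::aa123(AA_ALPHABET[AA_ALPHABET != "X"]),
                  AA_ALPHABET[AA_ALPHABET != "X"])
  fmt <- function(serial, name, resid, chain, resno, x, y, z)
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, name, resid, chain, resno, x, y, z, 1.00, 20.00)
  lines <- character(0); serial <- 0L
  emit_chain <- function(chain, seq, resno0, x, y, z) {
    res <- strsplit(seq, "")[[1]]
    for (i in seq_along(res)) {
      serial <<- serial + 1L
      lines[[length(lines) + 1L]] <<- fmt(serial, "CA", aa3[[res[i]]], chain,
                                          resno0 + i, x[i], y[i], z[i])
      serial <<- serial + 1L
      yb_cb <- if (chain == "A") y[i] - 1.5 else y[i] + 1.5
      lines[[length(lines) + 1L]] <<- fmt(serial, "CB", aa3[[res[i]]], chain,
                                          resno0 + i, x[i], yb_cb, z[i])
    }
  }
  emit_chain("A", seq_a, spec$iso_offset_a + spec$resno_offset_a, xa, ya, za)
  lines[[length(lines) + 1L]] <- "TER"
  emit_chain("B", seq_b, 0L, xb, yb, zb)
  lines[[length(lines) + 1L]] <- "TER"
  lines[[length(lines) + 1L]] <- "END"
  unlist(lines)
}

#' Generate the full labelled validation fixture
#'
#' Materializes everything a pipeline run needs: the two-chain structure and
#' its index, the isoform catalog, the feature/somatic/prediction tables, the
#' variant list and the labels, all derived deterministically from the spec.
#' Pathogenic variants are planted on or near planted evidence per
#' \code{label_plants}; \code{none}-evidence variants receive only tolerated
#' predictor calls, so the confusion matrix of the default rule is implied by
#' the spec itself.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with the file paths (\code{variants}, \code{labels},
#'   \code{features}, \code{somatic}, \code{predictions}, \code{catalog},
#'   \code{structure_index}), the \code{spec}, and
#'   \code{expected_confusion} (\code{tp}, \code{fp}, \code{fn}, \code{tn}
#'   implied by the plants under the default rule).
#' @export
generate_validation_set <- function(spec = fixture_spec(),
                                    dir = tempfile("fixture")) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  seqs <- fixture_sequences(spec)
  lp <- spec$label_plants
  n <- spec$n_residues_per_chain

  writeLines(generate_structure(spec),
             file.path(dir, "structures", "complex1.pdb"))
  writeLines(c("structure_id\tfile\tsource\tchain\tprotein_id",
               sprintf("%s\tstructures/complex1.pdb\texperimental\tA\t%s",
                       spec$structure_id, spec$protein_a),
               sprintf("%s\tstructures/complex1.pdb\texperimental\tB\t%s",
                       spec$structure_id, spec$protein_b)),
             file.path(dir, "structure_index.tsv"))
  writeLines(c("gene_id\tprotein_id\tprincipal\tsequence",
               sprintf("%s\t%s\t1\t%s", spec$gene_a, spec$protein_a,
                       seqs$protein_a),
               sprintf("%s\t%s\t1\t%s", spec$gene_b, spec$protein_b,
                       seqs$protein_b)),
             file.path(dir, "catalog.tsv"))

  ref <- function(pos) substr(seqs$protein_a, pos, pos)
  alt <- fixture_alt_aa(vapply(lp$position, ref, character(1)))

  # features: direct sites on protein A, partner binding sites on protein B,
  # plus one covering domain annotation on the structured region
  site_cats <- c("catalytic_site", "ptm_site", "binding_site")
  direct <- lp$position[lp$evidence == "direct_site"]
  feat <- sprintf("%s\t%d\t%d\t%s\tSITE%d", spec$protein_a, direct, direct,
                  site_cats[(seq_along(direct) - 1L) %% 3L + 1L],
                  seq_along(direct))
  partner <- lp$position[lp$evidence == "interface_feature"] -
    spec$iso_offset_a
  feat <- c(feat, sprintf("%s\t%d\t%d\tbinding_site\tPARTNER_SITE%d",
                          spec$protein_b, partner, partner,
                          seq_along(partner)))
  feat <- c(feat, sprintf("%s\t%d\t%d\tdomain\tPfam:TESTDOM", spec$protein_a,
                          spec$iso_offset_a + 1L, spec$iso_offset_a + n))
  writeLines(c("protein_id\tstart\tend\tcategory\tlabel", feat),
             file.path(dir, "features.tsv"))

  som_pos <- lp$position[lp$evidence == "somatic"]
  som <- sprintf("%s\t%d\t%s\t%s\tTCGA-%02d\tbladder\tcarcinoma",
                 spec$protein_a, som_pos,
                 vapply(som_pos, ref, character(1)),
                 fixture_alt_aa(vapply(som_pos, ref, character(1))),
                 seq_along(som_pos))
  writeLines(c(paste("protein_id", "position", "ref_aa", "alt_aa",
                     "sample_id", "tumor_site", "histology", sep = "\t"),
               som),
             file.path(dir, "somatic.tsv"))

  # predictor plants: damaging majority (2 of 3) for `predictor` evidence,
  # all-tolerated for every `none`-evidence variant
  pred <- character(0)
  pline <- function(pos, aa, method, score, call)
    sprintf("%s\t%d\t%s\t%s\t%.3f\t%s", spec$protein_a, pos, aa, method,
            score, call)
  for (i in seq_len(nrow(lp))) {
    if (lp$evidence[i] == "predictor")
      pred <- c(pred,
                pline(lp$position[i], alt[i], "SIFT", 0.01, "damaging"),
                pline(lp$position[i], alt[i], "Polyphen2", 0.98, "damaging"),
                pline(lp$position[i], alt[i], "MutationTaster", 0.20,
                      "tolerated"))
    else if (lp$evidence[i] == "none")
      pred <- c(pred,
                pline(lp$position[i], alt[i], "SIFT", 0.60, "tolerated"),
                pline(lp$position[i], alt[i], "Polyphen2", 0.05,
                      "tolerated"),
                pline(lp$position[i], alt[i], "MutationTaster", 0.10,
                      "tolerated"))
  }
  writeLines(c("protein_id\tposition\talt_aa\tmethod\tscore\tcall", pred),
             file.path(dir, "predictions.tsv"))

  writeLines(c("protein_id\tposition\tref_aa\talt_aa",
               sprintf("%s\t%d\t%s\t%s", spec$protein_a, lp$position,
                       vapply(lp$position, ref, character(1)), alt)),
             file.path(dir, "variants.tsv"))
  writeLines(c("protein_id\tposition\talt_aa\tlabel",
               sprintf("%s\t%d\t%s\t%s", spec$protein_a, lp$position, alt,
                       lp$label)),
             file.path(dir, "labels.tsv"))

  damaging_expected <- lp$evidence != "none"
  pathogenic <- lp$label == "pathogenic"
  list(dir = dir,
       variants = file.path(dir, "variants.tsv"),
       labels = file.path(dir, "labels.tsv"),
       features = file.path(dir, "features.tsv"),
       somatic = file.path(dir, "somatic.tsv"),
       predictions = file.path(dir, "predictions.tsv"),
       catalog = file.path(dir, "catalog.tsv"),
       structure_index = file.path(dir, "structure_index.tsv"),
       spec = spec,
       expected_confusion = list(
         tp = sum(damaging_expected & pathogenic),
         fp = sum(damaging_expected & !pathogenic),
         fn = sum(!damaging_expected & pathogenic),
         tn = sum(!damaging_expected & !pathogenic)))
}

#' Generate a random transcript-model fixture
#'
#' Builds a random chromosome sequence and a spliced coding transcript on it
#' (CDS length divisible by 3), for exercising genomic-to-protein
#' translation. Deterministic in the seed.
#'
#' @param seed integer RNG seed.
#' @param n_exons number of CDS exons (default 2).
#' @param codons_total total CDS length in codons (default 12).
#' @param strand \code{"+"} or \code{"-"}.
#' @param chrom chromosome name.
#' @return list with \code{tm} (transcript model), \code{genome} (named list
#'   of \code{DNAString}), \code{genome_fasta} and \code{transcript_tsv}
#'   (character vectors of file lines).
#' @export
generate_transcript_fixture <- function(seed = 1L, n_exons = 2L,
                                        codons_total = 12L, strand = "+",
                                        chrom = "chrT") {
  with_fixture_rng(seed, function() {
    cds_len <- 3L * codons_total
    # split the CDS over exons (each >= 3 bases), introns of 5-30 bases
    cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), n_exons - 1L))
    exon_lens <- diff(c(0L, cuts, cds_len))
    introns <- if (n_exons > 1L) sample(5:30, n_exons - 1L, replace = TRUE)
    else integer(0)
    lead <- sample(10:40, 1L)
    starts <- integer(n_exons); ends <- integer(n_exons)
    cursor <- lead + 1L
    for (i in seq_len(n_exons)) {
      starts[i] <- cursor
      ends[i] <- cursor + exon_lens[i] - 1L
      cursor <- ends[i] + 1L + (if (i < n_exons) introns[i] else 0L)
    }
    total_len <- ends[n_exons] + sample(10:40, 1L)
    genome_seq <- paste(sample(c("A", "C", "G", "T"), total_len,
                               replace = TRUE), collapse = "")
    tm <- list(transcript_id = "ENSTTEST001", protein_id = "ENSPTESTT01",
               gene_id = "ENSGTESTT01", chrom = chrom, strand = strand,
               cds_exons = cbind(start = starts, end = ends))
    list(tm = tm,
         genome = setNames(list(Biostrings::DNAString(genome_seq)), chrom),
         genome_fasta = c(paste0(">", chrom), genome_seq),
         transcript_tsv = c(paste("transcript_id", "protein_id", "gene_id",
                                  "chrom", "strand", "cds_exons",
                                  sep = "\t"),
                            sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                                    tm$transcript_id, tm$protein_id,
                                    tm$gene_id, chrom, strand,
                                    paste(sprintf("%d-%d", starts, ends),
                                          collapse = ";"))))
  })
}
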