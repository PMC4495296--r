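test_that("protein_tsv and vcf_lite records parse with line provenance", {
  subs <- parse_variants(c("protein_id\tposition\tref_aa\talt_aa",
                           "ENSP000001\t427\tS\tF",
                           "ENSP000002\t10\tA\t*"), "protein_tsv")
  expect_s3_class(subs, "protein_substitutions")
  expect_equal(subs$protein_id, c("ENSP000001", "ENSP000002"))
  expect_equal(subs$position, c(427L, 10L))
  expect_equal(subs$alt_aa, c("F", "*"))
  expect_equal(subs$line, c(2L, 3L))

  gvs <- parse_variants(c("##fileformat=VCFv4.2",
                          "#CHROM\tPOS\tID\tREF\tALT",
                          "chrT\t104\t.\tG\tA"), "vcf_lite")
  expect_s3_class(gvs, "genomic_variants")
  expect_equal(gvs$chrom, "chrT")
  expect_equal(gvs$pos, 104L)
  expect_equal(gvs$ref, "G")
  expect_equal(gvs$alt, "A")
})

test_that("malformed variant lines are rejected with their line number", {
  expect_error(parse_variants(c("protein_id\tposition\tref_aa\talt_aa",
                                "P1\t427\tS\tS"), "protein_tsv"),
               "line 2.*ref_aa equals alt_aa")
  expect_error(parse_variants(c("protein_id\tposition\tref_aa\talt_aa",
                                "P1\tabc\tS\tF"), "protein_tsv"),
               "line 2.*position")
  expect_error(parse_variants(c("protein_id\tposition\tref_aa\talt_aa",
                                "P1\t5\tS"), "protein_tsv"),
               "line 2.*4 tab-separated fields")
  expect_error(parse_variants("chr1\t5\t.\tG\tG", "vcf_lite"),
               "line 1.*REF equals ALT")
})

test_that("multi-nucleotide vcf_lite records are skipped with a warning", {
  expect_warning(
    gvs <- parse_variants(c("chr1\t5\t.\tGT\tG", "chr1\t9\t.\tA\tC"),
                          "vcf_lite"),
    "skipping non-SNV")
  expect_equal(nrow(gvs), 1L)
  expect_equal(gvs$pos, 9L)
})

test_that("parse after serialize is the identity on well-formed records", {
  set.seed(11)
  subs <- parse_variants(c("protein_id\tposition\tref_aa\talt_aa",
                           sprintf("P%d\t%d\t%s\t%s", 1:20,
                                   sample(1:500, 20),
                                   sample(c("A", "S", "W"), 20, TRUE),
                                   sample(c("F", "G", "Y"), 20, TRUE))),
                         "protein_tsv")
  expect_equal(parse_variants(serialize_variants(subs), "protein_tsv")[
    , c("protein_id", "position", "ref_aa", "alt_aa")],
    subs[, c("protein_id", "position", "ref_aa", "alt_aa")])
  gvs <- parse_variants(sprintf("chr%d\t%d\t.\tG\tA", 1:5, 101:105),
                        "vcf_lite")
  expect_equal(parse_variants(serialize_variants(gvs), "vcf_lite")[
    , c("chrom", "pos", "ref", "alt")],
    gvs[, c("chrom", "pos", "ref", "alt")])
})

test_that("plus-strand SNV translation matches hand-derived codons", {
  genome <- list(chrT = Biostrings::DNAString(
    paste0(strrep("T", 100), "ATGGCGTGA", strrep("T", 20))))
  tm <- list(transcript_id = "T1", protein_id = "P1", gene_id = "G1",
             chrom = "chrT", strand = "+",
             cds_exons = cbind(start = 101L, end = 109L))
  tr <- translate_genomic_variant(list(chrom = "chrT", pos = 104L,
                                       ref = "G", alt = "A"), tm, genome)
  expect_equal(tr[c("type", "position", "ref_aa", "alt_aa")],
               list(type = "substitution", position = 2L, ref_aa = "A",
                    alt_aa = "T"))
  # outside the CDS
  expect_equal(translate_genomic_variant(
    list(chrom = "chrT", pos = 100L, ref = "T", alt = "C"), tm,
    genome)$type, "non_coding")
  # stop-loss carries '*' as the reference residue
  tr2 <- translate_genomic_variant(list(chrom = "chrT", pos = 107L,
                                        ref = "T", alt = "C"), tm, genome)
  expect_equal(tr2[c("type", "position", "ref_aa", "alt_aa")],
               list(type = "substitution", position = 3L, ref_aa = "*",
                    alt_aa = "R"))
  # third-base wobble is reported synonymous
  tr3 <- translate_genomic_variant(list(chrom = "chrT", pos = 106L,
                                        ref = "G", alt = "A"), tm, genome)
  expect_equal(tr3$type, "synonymous")
  # reference mismatch names the position
  expect_error(translate_genomic_variant(
    list(chrom = "chrT", pos = 104L, ref = "C", alt = "A"), tm, genome),
    "reference mismatch at chrT:104")
})

test_that("minus-strand translation mirrors the plus-strand case", {
  genome <- list(chrT = Biostrings::DNAString(
    paste0(strrep("T", 200), "TCACGCCAT", strrep("T", 20))))
  tm <- list(transcript_id = "T1", protein_id = "P1", gene_id = "G1",
             chrom = "chrT", strand = "-",
             cds_exons = cbind(start = 201L, end = 209L))
  tr <- translate_genomic_variant(list(chrom = "chrT", pos = 206L,
                                       ref = "C", alt = "T"), tm, genome)
  expect_equal(tr[c("type", "position", "ref_aa", "alt_aa")],
               list(type = "substitution", position = 2L, ref_aa = "A",
                    alt_aa = "T"))
})

test_that("incremental codon translation agrees with whole-CDS oracle", {
  for (seed in 1:6) {
    strand <- if (seed %% 2 == 0) "-" else "+"
    fx <- generate_transcript_fixture(seed = seed, n_exons = 1 + seed %% 3,
                                      codons_total = 8, strand = strand)
    chrom_seq <- as.character(fx$genome$chrT)
    ex <- fx$tm$cds_exons
    coding <- unlist(lapply(seq_len(nrow(ex)),
                            function(i) ex[i, "start"]:ex[i, "end"]))
    for (pos in coding) {
      ref <- substr(chrom_seq, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        gv <- list(chrom = "chrT", pos = pos, ref = ref, alt = alt)
        got <- translate_genomic_variant(gv, fx$tm, fx$genome)
        want <- oracle_translate(gv, fx$tm, chrom_seq)
        expect_equal(got$type, want$type)
        if (want$type == "substitution")
          expect_equal(got[c("position", "ref_aa", "alt_aa")],
                       want[c("position", "ref_aa", "alt_aa")])
      }
    }
  }
})

test_that("a transcript and its reverse-complement twin give identical substitutions", {
  fx <- generate_transcript_fixture(seed = 42, n_exons = 2,
                                    codons_total = 6, strand = "+")
  chrom_seq <- as.character(fx$genome$chrT)
  L <- nchar(chrom_seq)
  rc <- oracle_revcomp(chrom_seq)
  ex <- fx$tm$cds_exons
  twin <- fx$tm
  twin$strand <- "-"
  # mirrored exon coordinates on the reverse-complemented chromosome
  twin$cds_exons <- cbind(start = rev(L - ex[, "end"] + 1L),
                          end = rev(L - ex[, "start"] + 1L))
  twin_genome <- list(chrT = Biostrings::DNAString(rc))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  coding <- unlist(lapply(seq_len(nrow(ex)),
                          function(i) ex[i, "start"]:ex[i, "end"]))
  for (pos in coding[c(1, 5, 9, 13, 18)]) {
    ref <- substr(chrom_seq, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    a <- translate_genomic_variant(list(chrom = "chrT", pos = pos,
                                        ref = ref, alt = alt),
                                   fx$tm, fx$genome)
    b <- translate_genomic_variant(
      list(chrom = "chrT", pos = L - pos + 1L, ref = comp[[ref]],
           alt = comp[[alt]]), twin, twin_genome)
    expect_equal(a[c("type", "position", "ref_aa", "alt_aa")],
                 b[c("type", "position", "ref_aa", "alt_aa")])
  }
})

test_that("transcript models violating the CDS contract are rejected at load", {
  hdr <- "transcript_id\tprotein_id\tgene_id\tchrom\tstrand\tcds_exons"
  expect_error(read_transcript_models(write_lines(
    c(hdr, "T1\tP1\tG1\tchr1\t+\t10-17"))), "not divisible by 3")
  expect_error(read_transcript_models(write_lines(
    c(hdr, "T1\tP1\tG1\tchr1\t+\t10-18;15-20"))), "overlap")
  expect_error(read_transcript_models(write_lines(
    c(hdr, "T1\tP1\tG1\tchr1\t+\t30-35;10-15"))), "sorted")
})

test_that("principal isoform selection: flag, then length, then accession", {
  catalog <- read_isoform_catalog(write_lines(c(
    "gene_id\tprotein_id\tprincipal\tsequence",
    sprintf("G1\tP1\t1\t%s", strrep("A", 100)),
    sprintf("G1\tP2\t0\t%s", strrep("A", 200)),
    sprintf("G2\tP3\t0\t%s", strrep("A", 150)),
    sprintf("G2\tP4\t0\t%s", strrep("A", 200)),
    sprintf("G3\tP5\t0\t%s", strrep("A", 80)),
    sprintf("G3\tP6\t0\t%s", strrep("A", 80)))))
  expect_equal(select_principal_isoform("G1", catalog), "P1")
  expect_equal(select_principal_isoform("G2", catalog), "P4")
  expect_equal(select_principal_isoform("G3", catalog), "P5")
  expect_error(select_principal_isoform("G9", catalog), "not in isoform")
})
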