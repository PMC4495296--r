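# small construction helpers shared across test files

# hand-rolled fixed-column ATOM line (independent of the package's writer)
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1.00, b = 20.00, element = "C",
                          altloc = " ", icode = " ", record = "ATOM  ") {
  sprintf("%s%5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, formatC(name, width = -4), altloc, resid, chain,
          resno, icode, x, y, z, occ, b, element)
}

# structure with explicitly placed single-atom residues:
# placements = data.frame(chain, resno, aa3, x, y, z)
placed_structure <- function(placements, chain_protein = c(A = "P1"),
                             structure_id = "toy",
                             source = "experimental") {
  lines <- vapply(seq_len(nrow(placements)), function(i)
    pdb_atom_line(i, "CA", placements$aa3[i], placements$chain[i],
                  placements$resno[i], placements$x[i], placements$y[i],
                  placements$z[i]), "")
  parse_pdb(c(lines, "END"), structure_id = structure_id, source = source,
            chain_protein = chain_protein)
}

write_lines <- function(lines, dir = tempdir(), name = "file.tsv") {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# annotation store built from in-memory tables
toy_store <- function(features = NULL, somatic = NULL, predictions = NULL) {
  d <- tempfile("store")
  dir.create(d)
  fp <- sp <- pp <- NULL
  if (!is.null(features))
    fp <- write_lines(c("protein_id\tstart\tend\tcategory\tlabel", features),
                      d, "features.tsv")
  if (!is.null(somatic))
    sp <- write_lines(c(paste("protein_id", "position", "ref_aa", "alt_aa",
                              "sample_id", "tumor_site", "histology",
                              sep = "\t"), somatic), d, "somatic.tsv")
  if (!is.null(predictions))
    pp <- write_lines(c("protein_id\tposition\talt_aa\tmethod\tscore\tcall",
                        predictions), d, "predictions.tsv")
  load_annotation_tables(fp, sp, pp)
}

# a bare annotation row for classify_variant tests
toy_row <- function(direct = NULL, neighbor = NULL, interface = FALSE,
                    somatic = NULL, predictions = NULL) {
  empty_feat <- data.frame(protein_id = character(0), start = integer(0),
                           end = integer(0), category = character(0),
                           label = character(0))
  nf <- data.frame(category = character(0), label = character(0),
                   neighbor_protein = character(0),
                   neighbor_position = integer(0),
                   neighbor_residue = character(0), distance = numeric(0),
                   relation = character(0), sequence_adjacent = logical(0),
                   stringsAsFactors = FALSE)
  structure(list(protein_id = "P1", position = 10L, ref_aa = "A",
                 alt_aa = "V", structure_id = "toy", source = "experimental",
                 chain = "A", mapped_residue = "10",
                 interface_flag = interface,
                 direct_features = direct %||% empty_feat,
                 neighbor_features = neighbor %||% nf,
                 somatic_matches = somatic %||%
                   data.frame(sample_id = character(0),
                              tumor_site = character(0),
                              histology = character(0)),
                 predictions = predictions %||%
                   data.frame(method = character(0), score = numeric(0),
                              call = character(0)),
                 flags = character(0)),
            class = "annotation_row")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
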