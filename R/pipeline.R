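#' Pipeline run configuration
#'
#' Gathers every input path and tunable of an annotation run. Genomic input
#' (\code{vcf_lite}) additionally needs the transcript model TSV and genome
#' FASTA; protein-level input does not.
#'
#' @param variants path to the variant file.
#' @param dialect \code{"protein_tsv"} or \code{"vcf_lite"}.
#' @param structure_index path to the structure index TSV (\code{NULL} for a
#'   structure-free run).
#' @param catalog path to the isoform catalog TSV.
#' @param features,somatic,predictions annotation table paths (each may be
#'   \code{NULL}).
#' @param transcripts,genome transcript model TSV and genome FASTA (genomic
#'   input only).
#' @param cutoff spatial cutoff in Angstrom (default 5.0, must be positive).
#' @param min_identity position-map acceptance threshold in (0, 1]
#'   (default 0.8).
#' @param rule a [rule_config()].
#' @param out output report path (\code{NULL} to skip writing).
#' @param format \code{"tsv"}, \code{"json"} or \code{"both"}.
#' @param verbose log progress (default \code{FALSE}).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(variants, dialect = "protein_tsv",
                       structure_index = NULL, catalog = NULL,
                       features = NULL, somatic = NULL, predictions = NULL,
                       transcripts = NULL, genome = NULL, cutoff = 5.0,
                       min_identity = 0.8, rule = rule_config(), out = NULL,
                       format = c("tsv", "json", "both"), verbose = FALSE) {
  format <- match.arg(format)
  if (cutoff <= 0) sv_stop("cutoff must be positive")
  if (min_identity <= 0 || min_identity > 1)
    sv_stop("min_identity must lie in (0, 1]")
  if (dialect == "vcf_lite" && (is.null(transcripts) || is.null(genome)))
    sv_stop("vcf_lite input needs transcript models and a genome FASTA")
  structure(list(variants = variants, dialect = dialect,
                 structure_index = structure_index, catalog = catalog,
                 features = features, somatic = somatic,
                 predictions = predictions, transcripts = transcripts,
                 genome = genome, cutoff = cutoff,
                 min_identity = min_identity, rule = rule, out = out,
                 format = format, verbose = verbose),
            class = "run_config")
}

#' Run the full annotation pipeline
#'
#' Parses variants, translates genomic SNVs through their transcript models
#' (selecting the principal isoform per gene and flagging hits to
#' non-principal isoforms), builds Smith-Waterman position maps for every
#' indexed structure chain, extracts spatial neighbourhoods and interface
#' residues, joins the annotation tables, applies the damaging-call rule and
#' writes the report. The run is fully deterministic: identical inputs give
#' byte-identical TSV output.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with \code{report} (flattened data.frame, one row
#'   per variant-structure context), \code{rows} (nested
#'   \code{annotation_row} objects) and \code{summary} (counts: variants in,
#'   translated, mapped to at least one structure, rows out, damaging
#'   calls).
#' @export
run_pipeline <- function(cfg) {
  parsed <- parse_variants(cfg$variants, cfg$dialect)
  if (nrow(parsed) == 0L) sv_stop("zero variants parsed from '%s'",
                                  cfg$variants)
  catalog <- if (is.null(cfg$catalog)) NULL
  else read_isoform_catalog(cfg$catalog)

  n_translated <- NA_integer_
  if (cfg$dialect == "vcf_lite") {
    tms <- read_transcript_models(cfg$transcripts)
    genome <- read_genome(cfg$genome)
    subs <- translate_variant_table(parsed, tms, genome, catalog,
                                    cfg$verbose)
    n_translated <- nrow(subs)
    if (nrow(subs) == 0L) sv_stop("no variant produced a substitution")
  } else {
    subs <- parsed
    subs$flags <- ""
  }

  store <- load_annotation_tables(cfg$features, cfg$somatic,
                                  cfg$predictions, verbose = cfg$verbose)
  context <- list()
  if (!is.null(cfg$structure_index)) {
    idx <- read_structure_index(cfg$structure_index)
    structs <- load_structures(idx)
    if (is.null(catalog))
      sv_stop("structural annotation needs an isoform catalog")
    context <- build_structure_context(structs, catalog,
                                       min_identity = cfg$min_identity,
                                       verbose = cfg$verbose)
  }

  all_rows <- list()
  for (i in seq_len(nrow(subs))) {
    sub <- as.list(subs[i, , drop = FALSE])
    rows <- annotate_variant(sub, store, context, cutoff = cfg$cutoff,
                             rule = cfg$rule, catalog = catalog)
    for (r in rows) {
      r$flags <- unique(c(r$flags,
                          strsplit(sub$flags %||% "", ";")[[1]]))
      all_rows[[length(all_rows) + 1L]] <- r
    }
  }
  report <- flatten_report(all_rows)
  mapped_variants <- unique(report[!is.na(report$structure_id),
                                   c("protein_id", "position", "alt_aa")])
  summary <- list(
    variants_in = nrow(parsed),
    translated = n_translated,
    variants = nrow(subs),
    mapped_to_structure = nrow(mapped_variants),
    rows_out = nrow(report),
    damaging_calls = sum(report$call == "damaging"))
  sv_log(cfg$verbose,
         "pipeline: %d variants in, %d rows out, %d damaging calls",
         summary$variants, summary$rows_out, summary$damaging_calls)

  if (!is.null(cfg$out)) {
    if (cfg$format %in% c("tsv", "both"))
      write_report_tsv(report, if (cfg$format == "both")
        paste0(cfg$out, ".tsv") else cfg$out)
    if (cfg$format %in% c("json", "both"))
      write_report_json(all_rows, if (cfg$format == "both")
        paste0(cfg$out, ".json") else cfg$out)
  }
  invisible(list(report = report, rows = all_rows, summary = summary))
}

# genomic variants -> protein substitutions on principal isoforms
translate_variant_table <- function(gvs, tms, genome, catalog, verbose) {
  out <- list()
  for (i in seq_len(nrow(gvs))) {
    gv <- as.list(gvs[i, , drop = FALSE])
    hits <- Filter(function(tm) tm$chrom == gv$chrom &&
                     !is.na(cds_offset_of(tm, gv$pos)), tms)
    if (length(hits) == 0L) {
      sv_log(verbose, "variant %s:%d is non-coding", gv$chrom, gv$pos)
      next
    }
    for (tm in hits) {
      tr <- translate_genomic_variant(gv, tm, genome)
      if (tr$type != "substitution") {
        sv_log(verbose, "variant %s:%d on %s: %s", gv$chrom, gv$pos,
               tm$transcript_id, tr$type)
        next
      }
      flags <- character(0)
      if (!is.null(catalog) && tm$gene_id %in% catalog$gene_id) {
        principal <- select_principal_isoform(tm$gene_id, catalog)
        if (!identical(principal, tm$protein_id))
          flags <- c(flags, "non_principal")
      }
      out[[length(out) + 1L]] <- data.frame(
        protein_id = tr$protein_id, position = tr$position,
        ref_aa = tr$ref_aa, alt_aa = tr$alt_aa,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      flags = character(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# nested annotation rows -> one flat data.frame row each
flatten_report <- function(rows) {
  if (length(rows) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      structure_id = character(0), source = character(0),
                      chain = character(0), mapped_residue = character(0),
                      interface_flag = logical(0),
                      direct_features = character(0),
                      neighbor_features = character(0),
                      somatic_matches = character(0),
                      predictions = character(0), call = character(0),
                      evidence = character(0), flags = character(0)))
  join <- function(x) paste(x, collapse = ";")
  do.call(rbind, c(lapply(rows, function(r) {
    df <- r$direct_features; nf <- r$neighbor_features
    sm <- r$somatic_matches; pr <- r$predictions
    data.frame(
      protein_id = r$protein_id, position = r$position, ref_aa = r$ref_aa,
      alt_aa = r$alt_aa, structure_id = r$structure_id, source = r$source,
      chain = r$chain, mapped_residue = r$mapped_residue,
      interface_flag = r$interface_flag,
      direct_features = join(sprintf("%s(%s)%d-%d", df$category, df$label,
                                     df$start, df$end)),
      neighbor_features = join(sprintf("%s(%s)@%s:%d|%s|%.2f|%s%s",
                                       nf$category, nf$label,
                                       nf$neighbor_protein,
                                       nf$neighbor_position,
                                       nf$neighbor_residue, nf$distance,
                                       nf$relation,
                                       ifelse(nf$sequence_adjacent,
                                              "|sequence_adjacent", ""))),
      somatic_matches = join(sprintf("%s|%s|%s", sm$sample_id,
                                     sm$tumor_site, sm$histology)),
      predictions = join(sprintf("%s=%s(%.3f)", pr$method, pr$call,
                                 pr$score)),
      call = r$call, evidence = join(r$evidence),
      flags = join(r$flags), stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

#' Write a flattened report as TSV
#'
#' @param report data.frame from [run_pipeline()].
#' @param path output path.
#' @export
write_report_tsv <- function(report, path) {
  write_tsv(report, path)
}

#' Write the nested report as JSON
#'
#' Mirrors the TSV row set with nested feature/somatic/prediction records.
#'
#' @param rows list of \code{annotation_row} objects.
#' @param path output path.
#' @export
write_report_json <- function(rows, path) {
  payload <- lapply(rows, function(r) {
    list(protein_id = r$protein_id, position = r$position,
         ref_aa = r$ref_aa, alt_aa = r$alt_aa,
         structure_id = r$structure_id, source = r$source,
         chain = r$chain, mapped_residue = r$mapped_residue,
         interface_flag = r$interface_flag,
         direct_features = r$direct_features,
         neighbor_features = r$neighbor_features,
         somatic_matches = r$somatic_matches,
         predictions = r$predictions,
         call = r$call, evidence = as.list(r$evidence),
         flags = as.list(r$flags))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
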