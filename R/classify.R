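#' Configuration of the damaging-call rule
#'
#' The default call is a disjunction of five evidence clauses, each
#' individually toggleable:
#' \describe{
#'   \item{direct_site}{the substituted position carries a site feature
#'     (ptm_site, catalytic_site, binding_site or mutagenesis_site);}
#'   \item{neighbor_site}{a residue in spatial contact (within the cutoff,
#'     excluding sequence-adjacent neighbours) carries a site feature;}
#'   \item{interface}{the mapped residue lies at a protein-protein
#'     interface;}
#'   \item{somatic}{at least one somatic mutation record at the position;}
#'   \item{predictor_majority}{a strict majority of the damage predictors
#'     with a non-unknown call say damaging (ties do not fire).}
#' }
#' A variant is called \code{damaging} when any enabled clause fires,
#' \code{neutral} when at least one prediction exists and no clause fires,
#' and \code{no_evidence} otherwise.
#'
#' @param direct_site,neighbor_site,interface,somatic,predictor_majority
#'   logical toggles, all \code{TRUE} by default.
#' @param count_sequence_adjacent include sequence-adjacent neighbours in the
#'   neighbor_site clause (default \code{FALSE}).
#' @return list of class \code{rule_config}.
#' @export
rule_config <- function(direct_site = TRUE, neighbor_site = TRUE,
                        interface = TRUE, somatic = TRUE,
                        predictor_majority = TRUE,
                        count_sequence_adjacent = FALSE) {
  structure(list(direct_site = direct_site, neighbor_site = neighbor_site,
                 interface = interface, somatic = somatic,
                 predictor_majority = predictor_majority,
                 count_sequence_adjacent = count_sequence_adjacent),
            class = "rule_config")
}

#' Apply the damaging-call rule to an annotated report row
#'
#' @param row an \code{annotation_row} as produced by [annotate_variant()].
#' @param rule a [rule_config()].
#' @return list with \code{call} (\code{"damaging"}, \code{"neutral"} or
#'   \code{"no_evidence"}) and \code{evidence}, a character vector of
#'   \code{clause:detail} strings, non-empty exactly when the call is
#'   damaging.
#' @export
classify_variant <- function(row, rule = rule_config()) {
  ev <- character(0)
  df <- row$direct_features
  if (isTRUE(rule$direct_site) && nrow(df) > 0L) {
    sites <- df[df$category %in% SITE_CATEGORIES, , drop = FALSE]
    if (nrow(sites) > 0L)
      ev <- c(ev, sprintf("direct_site:%s(%s)@%d", sites$category,
                          sites$label, row$position))
  }
  nf <- row$neighbor_features
  if (isTRUE(rule$neighbor_site) && nrow(nf) > 0L) {
    keep <- nf$category %in% SITE_CATEGORIES
    if (!isTRUE(rule$count_sequence_adjacent))
      keep <- keep & !nf$sequence_adjacent
    hits <- nf[keep, , drop = FALSE]
    if (nrow(hits) > 0L)
      ev <- c(ev, sprintf("neighbor_site:%s(%s)@%s:%d|%s|%.2fA|%s",
                          hits$category, hits$label, hits$neighbor_protein,
                          hits$neighbor_position, hits$neighbor_residue,
                          hits$distance, hits$relation))
  }
  if (isTRUE(rule$interface) && isTRUE(row$interface_flag))
    ev <- c(ev, sprintf("interface:%s@%s", row$mapped_residue %||% "",
                        row$structure_id %||% ""))
  sm <- row$somatic_matches
  if (isTRUE(rule$somatic) && nrow(sm) > 0L)
    ev <- c(ev, sprintf("somatic:%s|%s|%s", sm$sample_id, sm$tumor_site,
                        sm$histology))
  pr <- row$predictions
  if (isTRUE(rule$predictor_majority) && nrow(pr) > 0L) {
    voting <- pr[pr$call != "unknown", , drop = FALSE]
    ndam <- sum(voting$call == "damaging")
    if (nrow(voting) > 0L && ndam > nrow(voting) / 2)
      ev <- c(ev, sprintf("predictor_majority:%d/%d damaging", ndam,
                          nrow(voting)))
  }
  if (length(ev) > 0L) list(call = "damaging", evidence = ev)
  else if (nrow(pr) > 0L) list(call = "neutral", evidence = character(0))
  else list(call = "no_evidence", evidence = character(0))
}

#' Annotate one protein substitution against structures and the store
#'
#' Produces one report row per structure whose accepted position map covers
#' the substituted position, plus exactly one structure-free row when no
#' structure covers it. Each structural row carries: features at the position
#' itself; features at isoform positions back-mapped from spatially
#' contacting residues (each chain uses its own position map); an interface
#' flag, true when the mapped residue has at least one heavy atom within the
#' cutoff of the partner chain; somatic records and damage predictions at the
#' position; and the rule-based call with its evidence. Rows are ordered
#' experimental structures first, then models, then by structure id.
#'
#' If the catalog holds a sequence for the protein and its residue at the
#' position disagrees with \code{ref_aa}, a single structure-free row is
#' emitted with a \code{ref_mismatch} flag and no structural annotation.
#'
#' @param sub one substitution: list or single-row data.frame with
#'   \code{protein_id}, \code{position}, \code{ref_aa}, \code{alt_aa}.
#' @param store an \code{annotation_store}.
#' @param structures list of entries, each a list with \code{structure} (a
#'   \code{structure3d}) and \code{maps} (named list chain id ->
#'   \code{position_map}); see [build_structure_context()].
#' @param cutoff neighbourhood cutoff in Angstrom (default 5.0).
#' @param rule a [rule_config()].
#' @param catalog optional \code{isoform_catalog} used for the reference
#'   residue check.
#' @return list of \code{annotation_row} objects.
#' @export
annotate_variant <- function(sub, store, structures = list(), cutoff = 5.0,
                             rule = rule_config(), catalog = NULL) {
  sub <- as.list(sub)
  flags <- character(0)
  if (!is.null(catalog)) {
    seq <- catalog_sequence(catalog, sub$protein_id)
    if (!is.na(seq)) {
      if (sub$position > nchar(seq))
        flags <- c(flags, "position_out_of_range")
      else if (substr(seq, sub$position, sub$position) != sub$ref_aa)
        flags <- c(flags, "ref_mismatch")
    }
  }
  base <- list(protein_id = sub$protein_id, position = sub$position,
               ref_aa = sub$ref_aa, alt_aa = sub$alt_aa,
               somatic_matches = somatic_at(store, sub$protein_id,
                                            sub$position),
               predictions = predictions_for(store, sub$protein_id,
                                             sub$position, sub$alt_aa),
               direct_features = features_at(store, sub$protein_id,
                                             sub$position))
  if (length(flags) > 0L)
    return(list(finish_row(base, NULL, NULL, store, cutoff, rule, flags)))

  rows <- list()
  for (entry in structures) {
    s <- entry$structure
    chains <- names(s$chain_protein)[s$chain_protein == sub$protein_id]
    for (ch in chains) {
      pm <- entry$maps[[ch]]
      if (is.null(pm) || !isTRUE(pm$accepted)) next
      hit <- match(sub$position, pm$table$iso_pos)
      if (is.na(hit)) next
      rows[[length(rows) + 1L]] <-
        finish_row(base, entry, ch, store, cutoff, rule, flags,
                   residue = pm$table$residue[hit],
                   mismatch = pm$table$mismatch[hit])
    }
  }
  if (length(rows) == 0L)
    return(list(finish_row(base, NULL, NULL, store, cutoff, rule, flags)))
  src <- vapply(rows, function(r) r$source, character(1))
  sid <- vapply(rows, function(r) r$structure_id, character(1))
  rows[order(match(src, c("experimental", "model")), sid)]
}

empty_neighbor_features <- function() {
  data.frame(category = character(0), label = character(0),
             feature_start = integer(0), feature_end = integer(0),
             neighbor_protein = character(0), neighbor_position = integer(0),
             neighbor_residue = character(0), distance = numeric(0),
             relation = character(0), sequence_adjacent = logical(0),
             stringsAsFactors = FALSE)
}

finish_row <- function(base, entry, chain, store, cutoff, rule, flags,
                       residue = NULL, mismatch = FALSE) {
  row <- base
  row$flags <- flags
  if (is.null(entry)) {
    row$structure_id <- NA_character_
    row$source <- NA_character_
    row$chain <- NA_character_
    row$mapped_residue <- NA_character_
    row$interface_flag <- FALSE
    row$neighbor_features <- empty_neighbor_features()
  } else {
    s <- entry$structure
    row$structure_id <- s$structure_id
    row$source <- s$source
    row$chain <- chain
    row$mapped_residue <- residue
    if (isTRUE(mismatch)) row$flags <- c(row$flags, "map_mismatch")
    ri <- match(res_key_from_id(chain, residue), s$residues$key)
    nb <- spatial_neighbors(s, s$residues$chain[ri], s$residues$resno[ri],
                            s$residues$icode[ri], cutoff = cutoff)
    row$interface_flag <- any(nb$relation == "interface_partner")
    nf <- empty_neighbor_features()
    for (k in seq_len(nrow(nb))) {
      nch <- nb$chain[k]
      nprot <- s$chain_protein[[nch]] %||% NA_character_
      if (is.na(nprot)) next
      npm <- entry$maps[[nch]]
      if (is.null(npm) || !isTRUE(npm$accepted)) next
      npos <- unmap_residue(npm, res_id(nb$resno[k], nb$icode[k]))
      if (is.na(npos)) next
      fs <- features_at(store, nprot, npos)
      if (nrow(fs) == 0L) next
      nf <- rbind(nf, data.frame(
        category = fs$category, label = fs$label, feature_start = fs$start,
        feature_end = fs$end, neighbor_protein = nprot,
        neighbor_position = npos, neighbor_residue = nb$key[k],
        distance = nb$distance[k], relation = nb$relation[k],
        sequence_adjacent = nb$sequence_adjacent[k],
        stringsAsFactors = FALSE))
    }
    row$neighbor_features <- nf
  }
  cls <- classify_variant(row, rule)
  row$call <- cls$call
  row$evidence <- cls$evidence
  class(row) <- "annotation_row"
  row
}

# split a "A" chain + "123A" residue id back into a residue key
res_key_from_id <- function(chain, residue) paste0(chain, ":", residue)

#' @export
print.annotation_row <- function(x, ...) {
  ctx <- if (is.na(x$structure_id)) "no structure"
  else sprintf("%s chain %s residue %s", x$structure_id, x$chain,
               x$mapped_residue)
  cat(sprintf("%s %s%d%s [%s]: %s\n", x$protein_id, x$ref_aa, x$position,
              x$alt_aa, ctx, x$call))
  invisible(x)
}

#' Build per-structure alignment context for annotation
#'
#' Aligns each mapped chain's protein sequence (from the catalog) against the
#' chain's observed residues and derives the position map. Chains whose map
#' identity falls below \code{min_identity} are kept but marked rejected; a
#' note is logged when \code{verbose}.
#'
#' @param structs list of \code{structure3d} objects (see
#'   [read_structure_index()] / internal loader).
#' @param catalog an \code{isoform_catalog}.
#' @param scheme a [scoring_scheme()].
#' @param min_identity map acceptance threshold (default 0.8).
#' @param verbose log rejected maps.
#' @return list of entries (\code{structure}, \code{maps}) suitable for
#'   [annotate_variant()].
#' @export
build_structure_context <- function(structs, catalog,
                                    scheme = scoring_scheme(),
                                    min_identity = 0.8, verbose = FALSE) {
  lapply(structs, function(s) {
    maps <- list()
    for (ch in names(s$chain_protein)) {
      prot <- s$chain_protein[[ch]]
      seq <- catalog_sequence(catalog, prot)
      if (is.na(seq)) next
      cs <- chain_sequence(s, ch)
      aln <- smith_waterman(seq, cs$sequence, scheme)
      pm <- build_position_map(aln, 1L, cs$residues, protein_id = prot,
                               structure_id = s$structure_id, chain_id = ch,
                               min_identity = min_identity)
      if (!pm$accepted)
        sv_log(verbose, "map %s/%s rejected: identity %.3f < %.2f",
               s$structure_id, ch, pm$identity, min_identity)
      maps[[ch]] <- pm
    }
    list(structure = s, maps = maps)
  })
}
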