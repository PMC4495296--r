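FEATURE_CATEGORIES <- c("ptm_site", "catalytic_site", "binding_site",
                        "mutagenesis_site", "domain", "signal_peptide",
                        "transmembrane", "secondary_structure")
SITE_CATEGORIES <- c("ptm_site", "catalytic_site", "binding_site",
                     "mutagenesis_site")
PREDICTION_METHODS <- c("SIFT", "Polyphen2", "LRT", "MutationTaster",
                        "MutationAssessor", "FATHMM", "VEST3", "CADD")
PREDICTION_CALLS <- c("damaging", "tolerated", "unknown")

#' Load the annotation tables into an indexed store
#'
#' Reads three tab-separated snapshots: sequence features (sites and ranges;
#' the kind of content UniProt/InterPro provide), somatic mutation records
#' with tumour site and histology (COSMIC-style), and per-position damage
#' predictions (dbNSFP-style). Column contracts:
#' \itemize{
#'   \item features: \code{protein_id start end category label}, with
#'     \code{category} one of ptm_site, catalytic_site, binding_site,
#'     mutagenesis_site, domain, signal_peptide, transmembrane,
#'     secondary_structure; \code{start == end} for single-residue sites.
#'   \item somatic: \code{protein_id position ref_aa alt_aa sample_id
#'     tumor_site histology}.
#'   \item predictions: \code{protein_id position alt_aa method score call},
#'     with \code{method} from the SIFT/Polyphen2/LRT/MutationTaster/
#'     MutationAssessor/FATHMM/VEST3/CADD vocabulary and \code{call} one of
#'     damaging, tolerated, unknown.
#' }
#' Any of the paths may be \code{NULL} for an empty table.
#'
#' @param feature_tsv,somatic_tsv,prediction_tsv file paths or \code{NULL}.
#' @param verbose log record counts (default \code{FALSE}).
#' @return An object of class \code{annotation_store}.
#' @export
load_annotation_tables <- function(feature_tsv = NULL, somatic_tsv = NULL,
                                   prediction_tsv = NULL, verbose = FALSE) {
  feats <- if (is.null(feature_tsv)) {
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), category = character(0),
               label = character(0))
  } else {
    f <- read_tsv(feature_tsv)
    f$start <- as.integer(f$start); f$end <- as.integer(f$end)
    bad <- which(!f$category %in% FEATURE_CATEGORIES)
    if (length(bad) > 0L)
      sv_stop("unknown feature category '%s' at feature line %d",
              f$category[bad[1L]], bad[1L] + 1L)
    if (any(f$start < 1L | f$end < f$start))
      sv_stop("feature ranges must satisfy 1 <= start <= end")
    f
  }
  som <- if (is.null(somatic_tsv)) {
    data.frame(protein_id = character(0), position = integer(0),
               ref_aa = character(0), alt_aa = character(0),
               sample_id = character(0), tumor_site = character(0),
               histology = character(0))
  } else {
    s <- read_tsv(somatic_tsv)
    s$position <- as.integer(s$position)
    if (any(s$position < 1L)) sv_stop("somatic positions must be >= 1")
    s
  }
  pred <- if (is.null(prediction_tsv)) {
    data.frame(protein_id = character(0), position = integer(0),
               alt_aa = character(0), method = character(0),
               score = numeric(0), call = character(0))
  } else {
    p <- read_tsv(prediction_tsv)
    p$position <- as.integer(p$position)
    p$score <- as.numeric(p$score)
    bad <- which(!p$method %in% PREDICTION_METHODS)
    if (length(bad) > 0L)
      sv_stop("unknown prediction method '%s' at prediction line %d",
              p$method[bad[1L]], bad[1L] + 1L)
    bad <- which(!p$call %in% PREDICTION_CALLS)
    if (length(bad) > 0L)
      sv_stop("unknown prediction call '%s' at prediction line %d",
              p$call[bad[1L]], bad[1L] + 1L)
    p
  }
  if (verbose)
    sv_log(TRUE, "annotation store: %d features, %d somatic, %d predictions",
           nrow(feats), nrow(som), nrow(pred))
  structure(list(features = feats, somatic = som, predictions = pred),
            class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf("annotation_store: %d features, %d somatic, %d predictions\n",
              nrow(x$features), nrow(x$somatic), nrow(x$predictions)))
  invisible(x)
}

#' Sequence features overlapping a residue position
#'
#' @param store an \code{annotation_store}.
#' @param protein_id protein accession.
#' @param position 1-based residue position.
#' @return data.frame of feature records whose inclusive \code{[start, end]}
#'   range contains the position.
#' @export
features_at <- function(store, protein_id, position) {
  f <- store$features
  f[f$protein_id == protein_id & f$start <= position & f$end >= position, ,
    drop = FALSE]
}

#' Somatic mutation records at a residue position
#'
#' @inheritParams features_at
#' @return data.frame of somatic records at the position.
#' @export
somatic_at <- function(store, protein_id, position) {
  s <- store$somatic
  s[s$protein_id == protein_id & s$position == position, , drop = FALSE]
}

#' Damage predictions for a specific substitution
#'
#' @inheritParams features_at
#' @param alt_aa the substituting amino acid.
#' @return data.frame of prediction records for the substitution.
#' @export
predictions_for <- function(store, protein_id, position, alt_aa) {
  p <- store$predictions
  p[p$protein_id == protein_id & p$position == position &
      p$alt_aa == alt_aa, , drop = FALSE]
}
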