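#' Confusion-matrix evaluation metrics
#'
#' Accuracy, precision, recall and the Matthews correlation coefficient from
#' the four confusion counts. Metrics with a zero denominator are reported as
#' \code{NaN}, never coerced to 0. Values are stored at full precision;
#' display rounds to two decimals.
#'
#' @param tp,fp,fn,tn non-negative counts; their sum must be positive.
#' @return An object of class \code{confusion_metrics}: list with the four
#'   counts and \code{accuracy}, \code{precision}, \code{recall},
#'   \code{mcc}.
#' @examples
#' compute_metrics(tp = 11, fp = 0, fn = 3, tn = 10)
#' @export
compute_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) sv_stop("confusion counts must be non-negative")
  total <- tp + fp + fn + tn
  if (total <= 0) sv_stop("confusion counts must sum to a positive total")
  div <- function(num, den) if (den == 0) NaN else num / den
  mcc_den <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / total,
                 precision = div(tp, tp + fp),
                 recall = div(tp, tp + fn),
                 mcc = if (mcc_den == 0) NaN
                       else (tp * tn - fp * fn) / mcc_den),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy: %.2f, recall: %.2f, precision: %.2f, MCC: %.2f\n",
              x$accuracy, x$recall, x$precision, x$mcc))
  invisible(x)
}

#' Evaluate pipeline calls against a labelled validation set
#'
#' A variant is predicted positive when any of its report rows carries a
#' damaging call. \code{no_evidence} counts as a negative prediction by
#' default (set \code{no_evidence_negative = FALSE} to drop such variants
#' from the tally instead). Labels are matched on
#' (\code{protein_id}, \code{position}, \code{alt_aa}).
#'
#' @param labels data.frame with \code{protein_id}, \code{position},
#'   \code{alt_aa}, \code{label} (\code{"pathogenic"} or \code{"neutral"}).
#' @param report flattened report data.frame as written by [run_pipeline()]
#'   (needs \code{protein_id}, \code{position}, \code{alt_aa}, \code{call}).
#' @param no_evidence_negative count no-evidence variants as negative calls
#'   (default \code{TRUE}).
#' @return a \code{confusion_metrics} object.
#' @export
evaluate_calls <- function(labels, report, no_evidence_negative = TRUE) {
  if (!all(labels$label %in% c("pathogenic", "neutral")))
    sv_stop("labels must be 'pathogenic' or 'neutral'")
  key <- function(d) paste(d$protein_id, d$position, d$alt_aa)
  rk <- key(report)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(labels))) {
    calls <- report$call[rk == key(labels[i, , drop = FALSE])]
    if (length(calls) == 0L)
      sv_stop("no report rows for labelled variant %s %d %s",
              labels$protein_id[i], labels$position[i], labels$alt_aa[i])
    if (!no_evidence_negative && all(calls == "no_evidence")) next
    damaging <- any(calls == "damaging")
    pathogenic <- labels$label[i] == "pathogenic"
    if (damaging && pathogenic) tp <- tp + 1L
    else if (damaging && !pathogenic) fp <- fp + 1L
    else if (!damaging && pathogenic) fn <- fn + 1L
    else tn <- tn + 1L
  }
  compute_metrics(tp, fp, fn, tn)
}
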