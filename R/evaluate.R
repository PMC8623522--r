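# CAID-style residue metrics, fragment-restricted evaluation, and
# region-level detection rates.

#' Confusion counts (disordered = positive)
#'
#' @param calls Logical predictions (TRUE = disordered).
#' @param labels Character labels (`D`/`O`) or logical truth.
#' @export
confusion_counts <- function(calls, labels) {
  truth <- if (is.character(labels)) labels == "D" else as.logical(labels)
  stopifnot(length(calls) == length(truth))
  c(TP = sum(calls & truth), FP = sum(calls & !truth),
    TN = sum(!calls & !truth), FN = sum(!calls & truth))
}

#' Residue-level classification metrics
#'
#' Sensitivity, specificity, balanced accuracy and Matthews correlation
#' from confusion counts. Metrics with a zero denominator are reported
#' as `NA`, never silently as 0.
#'
#' @param counts Named vector `c(TP=, FP=, TN=, FN=)`.
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `mcc`.
#' @export
residue_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0)
    (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = bal, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random
#' disordered residue scores above a random ordered one, ties counted
#' half.
#'
#' @param scores Numeric scores.
#' @param labels `D`/`O` labels or logical truth (TRUE = disordered).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  truth <- if (is.character(labels)) labels == "D" else as.logical(labels)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Restrict predictions to evaluation fragments
#'
#' Keeps only residues lying inside the given fragments that carry a
#' definite order/disorder label and are not membrane-embedded, and
#' attaches the fragment label; residues covered by several fragments
#' are counted once.
#'
#' @param pred Data frame from [predict_disorder()] (or any frame with
#'   `protein_id` and `position` columns), possibly covering several
#'   proteins.
#' @param fragments List of `fragment` objects.
#' @return Subset of `pred` rows with an added `label` column.
#' @export
restrict_to_fragments <- function(pred, fragments) {
  keys <- list()
  for (f in fragments) {
    pos <- seq.int(f$start, f$end)
    keep <- f$labels %in% c("D", "O") &
      as.character(f$category) != "MEMBRANE"
    if (!any(keep)) next
    keys[[length(keys) + 1L]] <-
      data.frame(protein_id = f$parent_id, position = pos[keep],
                 label = f$labels[keep], stringsAsFactors = FALSE)
  }
  if (length(keys) == 0)
    return(cbind(pred[0, , drop = FALSE], label = character(0)))
  keys <- do.call(rbind, keys)
  keys <- keys[!duplicated(paste(keys$protein_id, keys$position)), ,
               drop = FALSE]
  bad <- !paste(keys$protein_id, keys$position) %in%
    paste(pred$protein_id, pred$position)
  if (any(bad) && max(keys$position[bad]) >
      max(pred$position[pred$protein_id %in% keys$protein_id[bad]], 0))
    stop("fragment extends beyond the predicted sequence")
  merge(pred, keys, by = c("protein_id", "position"))
}

#' Region-level detection
#'
#' A region counts as detected when at least `threshold` of its residues
#' are called disordered (boundary inclusive).
#'
#' @param regions Data frame with `protein_id`, `start`, `end`
#'   (1-based, closed).
#' @param pred Prediction frame with `protein_id`, `position` and a
#'   logical call column.
#' @param call_column Which call column to use (default
#'   `"call_sensitive"`).
#' @param threshold Detection threshold (default 0.60).
#' @return List with `regions` (the input plus `fraction` and
#'   `detected`) and `rate`.
#' @export
region_detection <- function(regions, pred,
                             call_column = "call_sensitive",
                             threshold = 0.60) {
  if (nrow(regions) == 0) stop("no regions supplied")
  frac <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    if (e < s) stop("zero-length region at row ", i)
    sub <- pred[pred$protein_id == regions$protein_id[i] &
                  pred$position >= s & pred$position <= e, ]
    if (nrow(sub) != e - s + 1L)
      stop("region ", regions$protein_id[i], ":", s, "-", e,
           " not fully covered by predictions")
    frac[i] <- mean(sub[[call_column]])
  }
  regions$fraction <- frac
  regions$detected <- frac >= threshold
  list(regions = regions, rate = mean(regions$detected))
}

#' Evaluate predictions against labelled proteins
#'
#' Builds the fragment-restricted evaluation set and reports, for each
#' output mode, confusion-based metrics on the binary calls and AUC on
#' the smoothed (pre-rescale) scores.
#'
#' @param pred Combined prediction frame ([predict_disorder()] rows for
#'   one or more proteins).
#' @param fragments Evaluation fragments (e.g. the test split).
#' @return List with `n`, and per mode the metric vector and AUC.
#' @export
evaluate_predictions <- function(pred, fragments) {
  ev <- restrict_to_fragments(pred, fragments)
  if (nrow(ev) == 0) stop("no labelled residues overlap the predictions")
  modes <- list(
    specific = list(call = "call_specific", score = "smoothed_specific"),
    sensitive = list(call = "call_sensitive",
                     score = "smoothed_sensitive"))
  out <- list(n = nrow(ev))
  for (m in names(modes)) {
    cc <- confusion_counts(ev[[modes[[m]]$call]], ev$label)
    out[[m]] <- list(counts = cc, metrics = residue_metrics(cc),
                     auc = auc_score(ev[[modes[[m]]$score]], ev$label))
  }
  out
}
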