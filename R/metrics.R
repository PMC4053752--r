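#' Confusion counts for binary indel classification
#'
#' Tallies true/false positives and negatives, with the disease class as the
#' positive class throughout the package.
#'
#' @param labels Character or factor vector of true labels, values
#'   `"disease"` or `"neutral"`.
#' @param predictions Predicted labels, same encoding and length.
#' @return A tibble with one row and integer columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c("disease", "neutral"), c("disease", "disease"))
#' @export
confusion <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) {
    stop("`labels` and `predictions` must have equal length (",
         length(labels), " vs ", length(predictions), ").", call. = FALSE)
  }
  bad <- setdiff(unique(c(labels, predictions)), c("disease", "neutral"))
  if (length(bad) > 0) {
    stop("Labels must be 'disease' or 'neutral'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    tp = sum(labels == "disease" & predictions == "disease"),
    fp = sum(labels == "neutral" & predictions == "disease"),
    tn = sum(labels == "neutral" & predictions == "neutral"),
    fn = sum(labels == "disease" & predictions == "neutral")
  )
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the balanced
#' measure used to rank features and tune the classifier: 1 for perfect
#' prediction, 0 for random. When any factor of the denominator is zero the
#' coefficient is defined as 0.
#'
#' @param counts One-row data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (as produced by [confusion()]).
#' @return A single numeric value in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Precision, recall and accuracy
#'
#' Recall (sensitivity) = TP/(TP+FN); precision = TP/(TP+FP);
#' accuracy = (TP+TN)/n. A zero denominator is an error rather than NaN,
#' since it signals a degenerate prediction set.
#'
#' @inheritParams mcc
#' @return A single numeric value in \[0, 1\].
#' @name classification_rates
NULL

#' @rdname classification_rates
#' @export
precision <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) stop("precision undefined: no positive predictions (TP+FP = 0).",
                   call. = FALSE)
  counts$tp / d
}

#' @rdname classification_rates
#' @export
recall <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) stop("recall undefined: no positive labels (TP+FN = 0).",
                   call. = FALSE)
  counts$tp / d
}

#' @rdname classification_rates
#' @export
accuracy <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop("accuracy undefined: empty confusion table.", call. = FALSE)
  (counts$tp + counts$tn) / n
}

#' ROC curve and area under the curve
#'
#' Builds the ROC curve by a descending-score threshold sweep with ties
#' collapsed to single thresholds, and integrates the area by the trapezoid
#' rule. The AUC equals the Mann-Whitney U normalisation U/(n+ * n-).
#'
#' @param scores Numeric vector of decision values or probabilities (higher
#'   means more disease-like).
#' @param labels True labels, `"disease"`/`"neutral"`.
#' @return A list with `curve` (tibble of `threshold`, `fpr`, `tpr`) and
#'   `auc` (numeric scalar).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "disease"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present (got ", n_pos, " disease, ",
         n_neg, " neutral).", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse ties: cumulative counts evaluated only at the last index of
  # each distinct score
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  curve <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Precision-recall curve
#'
#' Threshold sweep over descending scores; recall is non-decreasing along
#' the returned curve and the final point (all records called positive) has
#' precision equal to the disease prevalence.
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "disease"
  n_pos <- sum(pos)
  if (n_pos == 0) stop("PR curve requires at least one disease record.",
                       call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(p)[last_of_tie]
  called <- seq_along(s)[last_of_tie]
  tibble::tibble(
    threshold = s[last_of_tie],
    recall = tp / n_pos,
    precision = tp / called
  )
}

#' Minor-allele-frequency bin analysis
#'
#' Groups records into 20 fixed MAF bins of width 0.05 tiling \[0, 1\] (the
#' final bin is closed at 1), and relates the mean predicted disease
#' probability to the mean MAF per bin by Pearson correlation and a
#' least-squares line over the non-empty bins. A strong negative correlation
#' is the population-genetic signature of a well-calibrated classifier:
#' variants predicted deleterious should segregate at low frequency.
#'
#' @param probabilities Predicted disease probabilities in \[0, 1\].
#' @param mafs Minor allele frequencies in \[0, 1\], same length.
#' @return An object of class `nfs_maf_bins`: a list with `bins` (tibble of
#'   `bin`, `maf_lo`, `maf_hi`, `mean_maf`, `mean_prob`, `n`), `r`, `slope`,
#'   `intercept`.
#' @export
maf_bin_analysis <- function(probabilities, mafs) {
  stopifnot(length(probabilities) == length(mafs))
  if (any(mafs < 0 | mafs > 1, na.rm = TRUE)) {
    stop("MAF values must lie in [0, 1].", call. = FALSE)
  }
  lo <- seq(0, 0.95, by = 0.05)
  hi <- lo + 0.05
  idx <- pmin(floor(mafs / 0.05) + 1L, 20L)  # maf = 1 falls in the last bin
  bins <- tibble::tibble(
    bin = seq_len(20L),
    maf_lo = lo,
    maf_hi = hi,
    mean_maf = vapply(seq_len(20L), function(b) mean(mafs[idx == b]), 0),
    mean_prob = vapply(seq_len(20L),
                       function(b) mean(probabilities[idx == b]), 0),
    n = vapply(seq_len(20L), function(b) sum(idx == b), 0L)
  )
  filled <- dplyr::filter(bins, .data$n > 0)
  if (nrow(filled) < 2) {
    stop("Fewer than 2 non-empty MAF bins; correlation undefined.",
         call. = FALSE)
  }
  fit <- stats::lm(mean_prob ~ mean_maf, data = filled)
  structure(
    list(
      bins = bins,
      r = stats::cor(filled$mean_maf, filled$mean_prob),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1])
    ),
    class = "nfs_maf_bins"
  )
}

#' @export
print.nfs_maf_bins <- function(x, ...) {
  filled <- sum(x$bins$n > 0)
  cat("MAF bin analysis: 20 bins (width 0.05), ", filled, " non-empty\n",
      "Pearson r = ", format(x$r, digits = 3),
      ";  fit: prob = ", format(x$intercept, digits = 3), " + ",
      format(x$slope, digits = 3), " * maf\n", sep = "")
  invisible(x)
}
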