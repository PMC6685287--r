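#' Classification accuracy of the true-type score
#'
#' The fraction of samples whose predicted score for their true DDI type is
#' at least 0.5. This is the multi-label analogue of top-1 accuracy used
#' throughout the evaluation: a sample counts as correct iff the sigmoid
#' output of its annotated type clears the decision threshold.
#'
#' @param scores Matrix (samples x types) of scores in `[0,1]`, columns
#'   named by type.
#' @param truth Vector of true type labels, one per sample.
#' @return Accuracy in `[0,1]`.
#' @export
ddi_accuracy <- function(scores, truth) {
  check_scores(scores, truth)
  y <- scores[cbind(seq_len(nrow(scores)),
                    match(as.character(truth), colnames(scores)))]
  mean(y >= 0.5)
}

check_scores <- function(scores, truth) {
  if (is.null(dim(scores)) || nrow(scores) == 0) abort("empty score matrix.")
  if (length(truth) != nrow(scores)) {
    abort("`truth` length must match the score rows.")
  }
  if (is.null(colnames(scores))) abort("score columns must be named by type.")
  if (any(!as.character(truth) %in% colnames(scores))) {
    abort("every true type must have a score column.")
  }
  invisible(TRUE)
}

#' Per-type confusion counts from thresholded scores
#'
#' Binarizes each type's score at `threshold` (predicted positive iff score
#' is greater than or equal to it) and tallies TP/FP/FN/TN against the
#' one-hot truth.
#'
#' @inheritParams ddi_accuracy
#' @param threshold Decision threshold in (0, 1).
#' @return Tibble with columns `type`, `tp`, `fp`, `fn`, `tn`, `support`.
#' @export
counts_from_scores <- function(scores, truth, threshold = 0.5) {
  check_scores(scores, truth)
  stopifnot(threshold > 0, threshold < 1)
  types <- colnames(scores)
  pred <- scores >= threshold
  isit <- outer(as.character(truth), types, "==")
  tibble(
    type = types,
    tp = unname(colSums(pred & isit)),
    fp = unname(colSums(pred & !isit)),
    fn = unname(colSums(!pred & isit)),
    tn = unname(colSums(!pred & !isit)),
    support = unname(colSums(isit))
  )
}

ratio0 <- function(num, den, what) {
  bad <- den == 0
  if (any(bad)) {
    warn(paste0(sum(bad), " type(s) with zero ", what,
                " denominator contribute 0."))
  }
  ifelse(bad, 0, num / den)
}

#' Macro- and micro-averaged recall and precision
#'
#' Macro averages the per-type ratio (each type weighted equally; a type
#' with a zero denominator contributes 0, with a warning); micro pools the
#' counts across types before taking the ratio.
#'
#' @param counts Per-type counts from [counts_from_scores()].
#' @return A single value in `[0,1]`.
#' @export
macro_recall <- function(counts) {
  mean(ratio0(counts$tp, counts$tp + counts$fn, "recall"))
}

#' @rdname macro_recall
#' @export
macro_precision <- function(counts) {
  mean(ratio0(counts$tp, counts$tp + counts$fp, "precision"))
}

#' @rdname macro_recall
#' @export
micro_recall <- function(counts) {
  den <- sum(counts$tp) + sum(counts$fn)
  if (den == 0) abort("zero pooled recall denominator.")
  sum(counts$tp) / den
}

#' @rdname macro_recall
#' @export
micro_precision <- function(counts) {
  den <- sum(counts$tp) + sum(counts$fp)
  if (den == 0) abort("zero pooled precision denominator.")
  sum(counts$tp) / den
}

#' Precision/recall curve and AUPRC
#'
#' Ranks scores descending and traces precision/recall over all score
#' thresholds; the area uses step-wise interpolation (each recall increment
#' weighted by the precision at that threshold), avoiding the optimism of
#' trapezoidal interpolation. `pr_curve()` works on one binary problem;
#' [pr_auprc()] applies it per type and micro-averaged (all type/sample
#' scores pooled against one-hot truth).
#'
#' @param score Numeric score vector.
#' @param positive Logical vector, `TRUE` for positives.
#' @return `pr_curve()`: tibble `threshold`, `recall`, `precision` of class
#'   `pr_curve` with attribute `auprc`.
#' @export
pr_curve <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  if (!any(positive)) abort("no positive sample.")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- positive[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  # evaluate at each distinct threshold (last index of each tied block)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]; thr <- s[keep]
  recall <- tp / sum(positive)
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(
    tibble(threshold = thr, recall = recall, precision = precision),
    auprc = auprc, class = c("pr_curve", class(tibble())))
}

#' @rdname pr_curve
#' @inheritParams ddi_accuracy
#' @return `pr_auprc()`: list with `micro` (AUPRC of the pooled curve),
#'   `per_type` (tibble `type`, `auprc`), and the pooled `curve`.
#' @export
pr_auprc <- function(scores, truth) {
  check_scores(scores, truth)
  types <- colnames(scores)
  isit <- outer(as.character(truth), types, "==")
  support <- colSums(isit)
  if (any(support == 0)) {
    warn(paste0(sum(support == 0),
                " type(s) without positives excluded from per-type AUPRC."))
  }
  per_type <- tibble(
    type = types[support > 0],
    auprc = map_dbl(which(support > 0), function(j) {
      attr(pr_curve(scores[, j], isit[, j]), "auprc")
    })
  )
  micro_curve <- pr_curve(as.vector(scores), as.vector(isit))
  list(micro = attr(micro_curve, "auprc"), per_type = per_type,
       curve = micro_curve)
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' All evaluation metrics in one tidy row
#'
#' Computes accuracy, macro/micro recall and precision (at threshold 0.5)
#' and the micro-averaged AUPRC for a score matrix.
#'
#' @inheritParams ddi_accuracy
#' @return One-row tibble with columns `accuracy`, `macro_recall`,
#'   `macro_precision`, `micro_recall`, `micro_precision`, `auprc`.
#' @export
ddi_metrics <- function(scores, truth) {
  cts <- counts_from_scores(scores, truth)
  # a run with no predicted positive at all has an undefined micro precision
  mp <- tryCatch(micro_precision(cts), error = function(e) NA_real_)
  suppressWarnings(tibble(
    accuracy = ddi_accuracy(scores, truth),
    macro_recall = macro_recall(cts),
    macro_precision = macro_precision(cts),
    micro_recall = micro_recall(cts),
    micro_precision = mp,
    auprc = pr_auprc(scores, truth)$micro
  ))
}
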