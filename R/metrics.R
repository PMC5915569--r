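## Evaluation: confusion-matrix measures, ROC/AUC, precision-recall/auPRC,
## and the per-position / per-feature class-discrimination tests.

#' Confusion-matrix performance measures
#'
#' Computes the six standard measures from the four confusion counts:
#' sensitivity `Sn = TP/(TP+FN)` (recall), specificity `Sp = TN/(TN+FP)`,
#' precision `Pr = TP/(TP+FP)`, accuracy `Acc = (TP+TN)/total`,
#' `F1 = 2*TP/(2*TP+FP+FN)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any measure with a zero denominator is reported as `NA` (undefined), not 0.
#'
#' @param tp,tn,fp,fn non-negative integer confusion counts (not all zero)
#' @return named list with `sn`, `sp`, `pr`, `acc`, `f1`, `mcc`
#' @examples
#' computeMetrics(tp = 72, tn = 95, fp = 5, fn = 28)  # acc 0.835, mcc ~0.688
#' @export
computeMetrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(
    sn = ratio(tp, tp + fn),
    sp = ratio(tn, tn + fp),
    pr = ratio(tp, tp + fp),
    acc = ratio(tp + tn, sum(counts)),
    f1 = ratio(2 * tp, 2 * tp + fp + fn),
    mcc = if (mccDen == 0) NA_real_ else (tp * tn - fp * fn) / mccDen
  )
}

#' Confusion counts from predicted and actual labels
#' @param predicted,actual logical/binary vectors (TRUE/1 = positive)
#' @return named list `tp`, `tn`, `fp`, `fn`
#' @export
confusionCounts <- function(predicted, actual) {
  predicted <- as.logical(predicted %in% c(TRUE, 1, "1", "pos", "positive"))
  actual <- as.logical(actual %in% c(TRUE, 1, "1", "pos", "positive"))
  list(tp = sum(predicted & actual), tn = sum(!predicted & !actual),
       fp = sum(predicted & !actual), fn = sum(!predicted & actual))
}

#' Area under the ROC curve
#'
#' Computed in the rank (Mann-Whitney) form, which equals the trapezoidal
#' area over all thresholds: `AUC = P(score+ > score-) + P(tie)/2`.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (TRUE/1/"pos" = positive)
#' @return AUC in `[0, 1]`
#' @export
rocAUC <- function(scores, labels) {
  isPos <- labels %in% c(TRUE, 1, "1", "pos", "positive")
  n1 <- sum(isPos); n0 <- sum(!isPos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)  # midranks handle ties as half-credit
  (sum(r[isPos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Threshold enumeration over distinct scores (descending), accumulating
#' right-continuous precision steps: `sum over thresholds of
#' (recall_i - recall_{i-1}) * precision_i`. No linear interpolation of
#' precision is applied.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (TRUE/1/"pos" = positive)
#' @return auPRC in `[0, 1]`
#' @export
prAUC <- function(scores, labels) {
  isPos <- labels %in% c(TRUE, 1, "1", "pos", "positive")
  nPos <- sum(isPos)
  if (nPos == 0L) stop("no positive samples: auPRC undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- isPos[ord]
  newThreshold <- c(diff(s) != 0, TRUE)  # last index of each distinct score
  tp <- cumsum(y)[newThreshold]
  np <- seq_along(y)[newThreshold]       # predicted positives at threshold
  recall <- tp / nPos
  precision <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' ROC and precision-recall curve coordinates
#'
#' Threshold enumeration over the distinct scores (descending; "predict
#' positive at score >= threshold"). `rocCurve()` returns FPR/TPR pairs
#' including the (0,0) and (1,1) endpoints; `prCurve()` returns
#' recall/precision pairs. These are the coordinate tables behind
#' [rocAUC()] and [prAUC()], emitted for external plotting.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (TRUE/1/"pos" = positive)
#' @return data.frame of curve coordinates with the threshold at each step
#' @export
rocCurve <- function(scores, labels) {
  isPos <- labels %in% c(TRUE, 1, "1", "pos", "positive")
  n1 <- sum(isPos); n0 <- sum(!isPos)
  if (n1 == 0L || n0 == 0L) stop("both classes required")
  ord <- order(scores, decreasing = TRUE)
  y <- isPos[ord]; s <- scores[ord]
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last]; np <- seq_along(y)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, (np - tp) / n0),
             tpr = c(0, tp / n1))
}

#' @rdname rocCurve
#' @export
prCurve <- function(scores, labels) {
  isPos <- labels %in% c(TRUE, 1, "1", "pos", "positive")
  nPos <- sum(isPos)
  if (nPos == 0L) stop("no positive samples")
  ord <- order(scores, decreasing = TRUE)
  y <- isPos[ord]; s <- scores[ord]
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last]; np <- seq_along(y)[last]
  data.frame(threshold = s[last], recall = tp / nPos, precision = tp / np)
}

#' Position-specific base-usage test between classes
#'
#' For every (position, base) pair, compares the 0/1 indicator of that base
#' at that position between positive and negative windows with a two-sided
#' Wilcoxon rank-sum test (equivalent to a two-proportion comparison), and
#' flags pairs with `p <= alpha`.
#'
#' @param posWindows,negWindows character vectors of equal-length windows
#' @param alpha significance level (default 1e-10)
#' @return data.frame `offset` (position relative to the central site),
#'   `base`, `p_value`, `significant`
#' @export
positionalBaseTest <- function(posWindows, negWindows, alpha = 1e-10) {
  if (!length(posWindows) || !length(negWindows))
    stop("both classes must be non-empty")
  L <- nchar(posWindows[1])
  if (any(nchar(c(posWindows, negWindows)) != L))
    stop("all windows must have equal length")
  center <- (L + 1L) %/% 2L
  posM <- do.call(rbind, strsplit(posWindows, ""))
  negM <- do.call(rbind, strsplit(negWindows, ""))
  rows <- list()
  for (i in seq_len(L)) {
    for (b in RNA_BASES) {
      x <- as.integer(posM[, i] == b)
      y <- as.integer(negM[, i] == b)
      p <- if (all(c(x, y) == x[1])) 1
           else suppressWarnings(
             wilcox.test(x, y, exact = FALSE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        offset = i - center, base = b, p_value = p,
        significant = p <= alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-feature Welch t-test between classes
#'
#' Two-sample unequal-variance t-test per feature column; features whose
#' values are constant in both classes get `p = NA` and are never flagged.
#'
#' @param posFeatures,negFeatures numeric matrices with identical columns
#' @param alpha significance level (default 1e-4)
#' @return data.frame `feature`, `t`, `p_value`, `significant`
#' @export
featureTTest <- function(posFeatures, negFeatures, alpha = 1e-4) {
  if (nrow(posFeatures) < 2L || nrow(negFeatures) < 2L)
    stop("need at least two samples per class")
  stopifnot(identical(colnames(posFeatures), colnames(negFeatures)))
  res <- lapply(colnames(posFeatures), function(f) {
    x <- posFeatures[, f]; y <- negFeatures[, f]
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    data.frame(feature = f,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  out
}

#' Evaluate a model on a labeled dataset across all confidence modes
#'
#' Scores the samples and reports the six confusion measures per confidence
#' mode plus threshold-free AUC and auPRC.
#'
#' @param model an [M5CEnsemble-class]
#' @param samples data.frame with `window` and `label` columns
#' @return data.frame, one row per mode, with threshold, counts, measures,
#'   and `auc`/`auprc` attributes
#' @export
evaluateModel <- function(model, samples) {
  geom <- windowGeometry(model)
  L0 <- nchar(samples$window[1])
  c0 <- (L0 + 1L) %/% 2L
  wins <- substr(samples$window, c0 - geom[["upstream"]],
                 c0 + geom[["downstream"]])
  feats <- encodeWindows(wins, cfg = encodingConfigOf(model),
                         center = geom[["upstream"]] + 1L)
  scores <- scoreSamples(model, feats)
  actual <- samples$label == "pos"
  th <- thresholds(model)
  rows <- lapply(names(th), function(mode) {
    pred <- scores > th[[mode]]
    cc <- confusionCounts(pred, actual)
    m <- computeMetrics(cc$tp, cc$tn, cc$fp, cc$fn)
    data.frame(mode = mode, threshold = th[[mode]],
               tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               sn = m$sn, sp = m$sp, pr = m$pr, acc = m$acc,
               f1 = m$f1, mcc = m$mcc)
  })
  out <- do.call(rbind, rows)
  attr(out, "auc") <- rocAUC(scores, actual)
  attr(out, "auprc") <- prAUC(scores, actual)
  attr(out, "scores") <- scores
  out
}
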