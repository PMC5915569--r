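## Hybrid optimization: information-gain feature ranking plus a grid search
## over window geometry and feature count, scored by 10-fold cross-validated
## AUC of the balanced random-forest ensemble.

entropyOf <- function(x) {
  p <- table(x)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# Equal-frequency discretization into at most `bins` intervals; features with
# <= `bins` distinct values (e.g. binary indicators) are used as-is.
discretizeFeature <- function(x, bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Rank features by information gain
#'
#' Information gain of each (discretized) feature with respect to the binary
#' label: `IG = H(label) - H(label | feature)`. Continuous features are
#' discretized into equal-frequency bins (default 10); binary features are
#' used as-is. Features are returned in decreasing gain order, ties broken by
#' canonical (column) order.
#'
#' @param features numeric matrix with named columns
#' @param labels binary label vector
#' @param bins equal-frequency bins for discretization
#' @return character vector of feature names, best first, with the gains in
#'   `attr(, "infoGain")`
#' @export
rankFeaturesInfoGain <- function(features, labels, bins = 10L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("labels must contain two classes")
  hy <- entropyOf(labels)
  n <- length(labels)
  gains <- vapply(seq_len(ncol(features)), function(j) {
    d <- discretizeFeature(features[, j], bins = bins)
    hcond <- 0
    for (lev in unique(d)) {
      sel <- d == lev
      hcond <- hcond + sum(sel) / n * entropyOf(labels[sel])
    }
    hy - hcond
  }, numeric(1))
  ord <- order(-gains)  # stable: ties keep canonical column order
  out <- colnames(features)[ord]
  attr(out, "infoGain") <- setNames(gains[ord], out)
  out
}

#' Stratified k-fold cross-validation of the ensemble
#'
#' Splits samples into `folds` stratified subsets; for each fold, trains the
#' balanced ensemble on the other folds and scores the held-out samples.
#' Reports the mean of the per-fold AUCs and the pooled out-of-fold scores
#' (each sample is scored exactly once), which are the calibration input for
#' [determineThresholds()].
#'
#' @param features numeric feature matrix
#' @param labels "pos"/"neg" labels
#' @param folds number of folds (default 10)
#' @param seed integer seed (fold assignment and forests)
#' @param nParts,numTrees ensemble parameters (see [trainEnsemble()])
#' @return list with `auc` (mean per-fold AUC), `foldAUCs`, `scores` (pooled
#'   out-of-fold scores aligned to input rows), `labels`
#' @export
crossValidate <- function(features, labels, folds = 10L, seed = 1L,
                          nParts = 10L, numTrees = 100L) {
  if (folds < 2L) stop("folds must be >= 2")
  labels <- as.character(labels)
  posIdx <- which(labels == "pos"); negIdx <- which(labels != "pos")
  if (length(posIdx) < folds || length(negIdx) < folds)
    stop("need at least `folds` samples per class")
  set.seed(seed)
  foldOf <- integer(length(labels))
  foldOf[posIdx] <- sample(rep_len(seq_len(folds), length(posIdx)))
  foldOf[negIdx] <- sample(rep_len(seq_len(folds), length(negIdx)))
  scores <- rep(NA_real_, length(labels))
  foldAUCs <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- foldOf == f
    trainPos <- features[labels == "pos" & !test, , drop = FALSE]
    trainNeg <- features[labels != "pos" & !test, , drop = FALSE]
    forests <- trainEnsemble(trainPos, trainNeg, seed = deriveSeed(seed, f),
                             nParts = nParts, numTrees = numTrees)
    s <- scoreSamples(forests, features[test, , drop = FALSE])
    scores[test] <- s
    foldAUCs[f] <- rocAUC(s, labels[test] == "pos")
  }
  list(auc = mean(foldAUCs), foldAUCs = foldAUCs, scores = scores,
       labels = labels)
}

# Leakage-free variant: the information-gain ranking (hence the selected
# top-F subset) is recomputed on each fold's training portion.
crossValidateReranked <- function(features, labels, F, folds = 10L, seed = 1L,
                                  nParts = 10L, numTrees = 100L) {
  labels <- as.character(labels)
  posIdx <- which(labels == "pos"); negIdx <- which(labels != "pos")
  if (length(posIdx) < folds || length(negIdx) < folds)
    stop("need at least `folds` samples per class")
  set.seed(seed)
  foldOf <- integer(length(labels))
  foldOf[posIdx] <- sample(rep_len(seq_len(folds), length(posIdx)))
  foldOf[negIdx] <- sample(rep_len(seq_len(folds), length(negIdx)))
  scores <- rep(NA_real_, length(labels))
  foldAUCs <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- foldOf == f
    ranked <- rankFeaturesInfoGain(features[!test, , drop = FALSE],
                                   labels[!test])
    keep <- ranked[seq_len(min(F, length(ranked)))]
    forests <- trainEnsemble(
      features[labels == "pos" & !test, keep, drop = FALSE],
      features[labels != "pos" & !test, keep, drop = FALSE],
      seed = deriveSeed(seed, f), nParts = nParts, numTrees = numTrees)
    s <- scoreSamples(forests, features[test, keep, drop = FALSE])
    scores[test] <- s
    foldAUCs[f] <- rocAUC(s, labels[test] == "pos")
  }
  list(auc = mean(foldAUCs), foldAUCs = foldAUCs, scores = scores,
       labels = labels)
}

defaultFeatureGrid <- function(p) {
  g <- 2L
  while (g[length(g)] < p) g <- c(g, min(p, g[length(g)] * 2L))
  unique(g)
}

#' Optimize window geometry and feature count
#'
#' For every window length L in `LValues` and every upstream flank Lu in
#' 1..(L-2) (downstream Ld = L - 1 - Lu), the dataset windows are trimmed and
#' encoded, features are ranked by information gain, and the feature count F
#' is swept over a grid (geometric by default, `2, 4, 8, ..., all`;
#' `exhaustive = TRUE` sweeps every integer 2..4L+106). Each grid point is
#' scored by `folds`-fold cross-validated AUC; the best AUC and feature
#' subset per geometry are recorded and the overall argmax returned.
#'
#' @param samples data.frame with `window` (centered, length >= max(LValues))
#'   and `label` columns
#' @param LValues window lengths to examine (default odd 5..43)
#' @param symmetricOnly if TRUE, only Lu = Ld geometries are examined
#'   (odd L); the full Lu sweep otherwise
#' @param encoding an [EncodingConfig-class]
#' @param FGrid explicit feature-count grid, or NULL for the default
#' @param exhaustive sweep every feature count 2..p instead of the geometric
#'   grid
#' @param folds,nParts,numTrees cross-validation / ensemble parameters
#' @param leakageFree re-rank features inside every training fold instead of
#'   once per geometry (slower; avoids selection leakage)
#' @param seed integer seed
#' @return list of class `m5cOptimization`: `aucMatrix` (data.frame L, Lu,
#'   Ld, F, auc per geometry, best over the F sweep), `featureSets`,
#'   `bestGeometry`, `bestFeatures`, `bestAUC`
#' @export
optimizeModel <- function(samples, LValues = seq(5L, 43L, by = 2L),
                          symmetricOnly = FALSE,
                          encoding = encodingConfig(), FGrid = NULL,
                          exhaustive = FALSE, folds = 10L, nParts = 10L,
                          numTrees = 100L, leakageFree = FALSE, seed = 1L) {
  L0 <- nchar(samples$window[1])
  c0 <- (L0 + 1L) %/% 2L
  labels <- samples$label
  rows <- list(); featureSets <- list()
  for (L in LValues) {
    if (L < 3L || L > L0) stop("window length ", L, " not extractable")
    lus <- if (symmetricOnly) {
      if ((L - 1L) %% 2L != 0L) stop("symmetric geometry needs odd L")
      (L - 1L) %/% 2L
    } else seq_len(L - 2L)
    for (lu in lus) {
      ld <- L - 1L - lu
      if (lu > c0 - 1L || ld > L0 - c0) next
      wins <- substr(samples$window, c0 - lu, c0 + ld)
      feats <- encodeWindows(wins, cfg = encoding, center = lu + 1L)
      p <- ncol(feats)
      grid <- if (!is.null(FGrid)) FGrid[FGrid <= p]
              else if (exhaustive) 2:p
              else defaultFeatureGrid(p)
      ranked <- rankFeaturesInfoGain(feats, labels)
      bestAUC <- -Inf; bestF <- NA_integer_; bestFeats <- character()
      for (F in grid) {
        keep <- ranked[seq_len(F)]
        cv <- if (leakageFree)
          crossValidateReranked(feats, labels, F, folds = folds, seed = seed,
                                nParts = nParts, numTrees = numTrees)
        else
          crossValidate(feats[, keep, drop = FALSE], labels,
                        folds = folds, seed = seed, nParts = nParts,
                        numTrees = numTrees)
        if (cv$auc > bestAUC) {
          bestAUC <- cv$auc; bestF <- F; bestFeats <- keep
        }
      }
      key <- sprintf("Lu%d_Ld%d", lu, ld)
      rows[[key]] <- data.frame(L = L, Lu = lu, Ld = ld, F = bestF,
                                auc = bestAUC)
      featureSets[[key]] <- bestFeats
    }
  }
  if (!length(rows)) stop("empty optimization grid")
  aucMatrix <- do.call(rbind, rows)
  rownames(aucMatrix) <- NULL
  best <- which.max(aucMatrix$auc)
  out <- list(aucMatrix = aucMatrix, featureSets = featureSets,
              bestGeometry = c(Lu = aucMatrix$Lu[best],
                               Ld = aucMatrix$Ld[best]),
              bestFeatures = featureSets[[sprintf("Lu%d_Ld%d",
                                                  aucMatrix$Lu[best],
                                                  aucMatrix$Ld[best])]],
              bestAUC = aucMatrix$auc[best],
              leakageFree = leakageFree)
  class(out) <- "m5cOptimization"
  out
}

#' @export
print.m5cOptimization <- function(x, ...) {
  cat("m5C model optimization over", nrow(x$aucMatrix), "geometries\n")
  cat("  best: Lu =", x$bestGeometry[["Lu"]], "Ld =", x$bestGeometry[["Ld"]],
      "F =", length(x$bestFeatures), "AUC =", round(x$bestAUC, 3), "\n")
  invisible(x)
}
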