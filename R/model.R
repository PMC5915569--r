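## The ensemble learner: ten random forests, each trained on all positives
## plus one tenth of the (shuffled) negatives, scores averaged; confidence
## thresholds anchored at fixed specificities of the out-of-fold negative
## score distribution.

MODEL_VERSION <- 1L
SPECIFICITY_LEVELS <- c(VHmode = 0.99, HMode = 0.95, NMode = 0.90, LMode = 0.85)

# Near-equal partition of n items into k parts: sizes differ by at most one,
# larger parts first. Returns a list of index vectors over a shuffled order.
partitionIndices <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  split(seq_len(n), rep(seq_len(k), sizes))
}

#' Train the balanced random-forest ensemble
#'
#' Negatives are shuffled (seeded) and split into `nParts` near-equal parts;
#' forest i is trained on all positives plus negative part i. Each forest has
#' `numTrees` trees with bootstrap resampling and random feature subsetting
#' (`mtry` = sqrt(#features) by default).
#'
#' @param positives,negatives numeric feature matrices (named columns,
#'   identical column sets)
#' @param seed integer seed controlling the shuffle and every forest
#' @param nParts number of negative parts / forests (default 10)
#' @param numTrees trees per forest (default 100)
#' @param mtry features tried per split (default floor(sqrt(p)))
#' @return list of fitted `ranger` forests, with the negative partition sizes
#'   in `attr(, "partSizes")`
#' @export
trainEnsemble <- function(positives, negatives, seed = 1L, nParts = 10L,
                          numTrees = 100L, mtry = NULL) {
  stopifnot(is.matrix(positives), is.matrix(negatives))
  if (!identical(colnames(positives), colnames(negatives)))
    stop("positive and negative feature matrices must share columns")
  nPos <- nrow(positives); nNeg <- nrow(negatives)
  if (nPos < 1L || nNeg < nParts)
    stop("need at least one positive and ", nParts, " negatives")
  ratio <- nNeg / nPos
  if (ratio < 0.5 * nParts || ratio > 2 * nParts)
    warning("negative:positive ratio ", round(ratio, 1),
            " far from the intended ", nParts, ":1 design")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(positives))))
  set.seed(seed)
  parts <- partitionIndices(nNeg, nParts)
  shuffled <- sample(nNeg)
  forests <- vector("list", nParts)
  for (i in seq_len(nParts)) {
    negIdx <- shuffled[parts[[i]]]
    x <- rbind(positives, negatives[negIdx, , drop = FALSE])
    yi <- factor(c(rep("pos", nPos), rep("neg", length(negIdx))),
                 levels = c("neg", "pos"))
    if (nlevels(droplevels(yi)) < 2L)
      stop("degenerate training split: fewer than two classes")
    forests[[i]] <- ranger::ranger(
      x = x, y = yi, num.trees = numTrees, mtry = min(mtry, ncol(x)),
      probability = TRUE, seed = deriveSeed(seed, i), num.threads = 1L)
  }
  attr(forests, "partSizes") <- lengths(parts)
  forests
}

forestList <- function(model) {
  if (is(model, "M5CEnsemble")) model@forests else model
}

#' Score samples with an ensemble
#'
#' Each sample's score is the arithmetic mean of the positive-class
#' probabilities of the ensemble's forests (invariant to forest order).
#'
#' @param model an [M5CEnsemble-class] or a forest list from [trainEnsemble()]
#' @param features numeric feature matrix; when `model` is an `M5CEnsemble`
#'   the columns are checked/subset against its selected features
#' @param perModel if TRUE, return the per-forest score matrix instead of the
#'   averaged vector
#' @return numeric vector of scores in `[0, 1]` (or an n-by-forests matrix)
#' @export
scoreSamples <- function(model, features, perModel = FALSE) {
  forests <- forestList(model)
  if (is(model, "M5CEnsemble")) {
    need <- model@selectedFeatures
    if (!all(need %in% colnames(features)))
      stop("feature matrix lacks model features: ",
           paste(head(setdiff(need, colnames(features)), 3), collapse = ", "))
    features <- features[, need, drop = FALSE]
  }
  per <- vapply(forests, function(f) {
    predict(f, data = features, num.threads = 1L)$predictions[, "pos"]
  }, numeric(nrow(features)))
  if (nrow(features) == 1L) per <- matrix(per, nrow = 1L)
  if (perModel) per else rowMeans(per)
}

#' Specificity-anchored confidence thresholds
#'
#' For each target specificity s in 99/95/90/85%, the threshold is the
#' smallest observed negative score t such that the fraction of negatives
#' scoring strictly below t is at least s (the empirical quantile with
#' higher interpolation); if no observed score satisfies s, the maximum
#' negative score is used. With the strict "score > threshold" positive rule
#' this guarantees specificity >= s on the calibration scores. Scores should
#' come from out-of-fold cross-validation predictions, not a training fit.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (1/"pos" = positive)
#' @return named numeric `c(VHmode=, HMode=, NMode=, LMode=)`, monotone
#'   non-increasing
#' @export
determineThresholds <- function(scores, labels) {
  isPos <- labels %in% c(1, "1", "pos", "positive", TRUE)
  neg <- sort(scores[!isPos])
  n <- length(neg)
  if (n == 0L) stop("no negative scores: thresholds undefined")
  uniq <- !duplicated(neg)
  vapply(SPECIFICITY_LEVELS, function(s) {
    # fraction strictly below neg[i] is (i - 1)/n at the first occurrence
    # of each distinct value; take the smallest such value meeting s
    cand <- which(uniq & (seq_len(n) - 1L) / n >= s)
    if (length(cand)) neg[cand[1]] else neg[n]
  }, numeric(1))
}

#' Classify scores under a confidence mode
#'
#' A site is called positive iff its score is strictly higher than the
#' mode's threshold.
#'
#' @param score numeric score(s)
#' @param model an [M5CEnsemble-class] (or a named threshold vector)
#' @param mode one of `"VHmode"`, `"HMode"`, `"NMode"`, `"LMode"`
#' @return character vector, `"positive"`/`"negative"`
#' @export
classifyWithMode <- function(score, model, mode = "VHmode") {
  th <- if (is(model, "M5CEnsemble")) thresholds(model) else model
  if (!mode %in% names(th)) stop("unknown confidence mode: ", mode)
  ifelse(score > th[[mode]], "positive", "negative")
}

#' Build a complete ensemble model from a labeled dataset
#'
#' The end-to-end trainer: trims windows to the requested geometry, encodes,
#' optionally selects the top features by information gain, derives the four
#' confidence thresholds from pooled out-of-fold cross-validation scores,
#' then fits the final ensemble on the full dataset.
#'
#' @param samples data.frame with `window` and `label` columns (labels
#'   "pos"/"neg"), windows centered on the site
#' @param upstream,downstream scoring-window flanks (default 5/5: L = 11)
#' @param encoding an [EncodingConfig-class]
#' @param nFeatures keep this many top information-gain features
#'   (NULL = all features)
#' @param folds cross-validation folds for threshold calibration (default 10)
#' @param nParts forests in the ensemble (default 10)
#' @param numTrees trees per forest (default 100)
#' @param seed integer seed
#' @return an [M5CEnsemble-class]
#' @export
buildEnsembleModel <- function(samples, upstream = 5L, downstream = 5L,
                               encoding = encodingConfig(), nFeatures = NULL,
                               folds = 10L, nParts = 10L, numTrees = 100L,
                               seed = 1L) {
  L0 <- nchar(samples$window[1])
  c0 <- (L0 + 1L) %/% 2L
  if (upstream > c0 - 1L || downstream > L0 - c0)
    stop("requested geometry exceeds available window flanks")
  wins <- substr(samples$window, c0 - upstream, c0 + downstream)
  feats <- encodeWindows(wins, cfg = encoding, center = upstream + 1L)
  labels <- samples$label
  if (!is.null(nFeatures)) {
    ranked <- rankFeaturesInfoGain(feats, labels)
    keep <- ranked[seq_len(min(nFeatures, length(ranked)))]
    feats <- feats[, keep, drop = FALSE]
  }
  cv <- crossValidate(feats, labels, folds = folds, seed = seed,
                      nParts = nParts, numTrees = numTrees)
  th <- determineThresholds(cv$scores, labels)
  forests <- trainEnsemble(feats[labels == "pos", , drop = FALSE],
                           feats[labels == "neg", , drop = FALSE],
                           seed = deriveSeed(seed, 999L), nParts = nParts,
                           numTrees = numTrees)
  new("M5CEnsemble",
      forests = forests,
      selectedFeatures = colnames(feats),
      upstream = as.integer(upstream), downstream = as.integer(downstream),
      thresholds = th,
      encoding = encoding,
      metadata = list(seed = seed, cvAUC = cv$auc,
                      nPos = sum(labels == "pos"), nNeg = sum(labels == "neg"),
                      version = MODEL_VERSION))
}

#' Persist / restore an ensemble model
#'
#' The archive is a single versioned file holding the encoding configuration,
#' feature list, thresholds, geometry and the fitted forests. Loading a file
#' with a different archive version fails loudly.
#'
#' @param model an [M5CEnsemble-class]
#' @param path archive path
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "M5CEnsemble"))
  saveRDS(list(format = "m5Cforest-model", version = MODEL_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @return `loadModel()` returns the restored [M5CEnsemble-class]
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "m5Cforest-model"))
    stop("not an m5Cforest model archive: ", path)
  if (!identical(obj$version, MODEL_VERSION))
    stop("model archive version ", obj$version,
         " does not match supported version ", MODEL_VERSION)
  validObject(obj$model)
  obj$model
}
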