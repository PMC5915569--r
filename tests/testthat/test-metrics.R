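# Confusion rows reconstructed from balanced 100/100 (Sn, Sp) pairs; the
# expected Pr/Acc/MCC/F1 are the published three-decimal values for these
# counts, re-derived by hand from the formulas.
TABLE1 <- list(
  list(tp = 33, fp = 0, pr = 1.000, acc = 0.665, mcc = 0.445, f1 = 0.496),
  list(tp = 72, fp = 5, pr = 0.935, acc = 0.835, mcc = 0.688, f1 = 0.814),
  list(tp = 86, fp = 10, pr = 0.896, acc = 0.880, mcc = 0.761, f1 = 0.878),
  list(tp = 90, fp = 14, pr = 0.865, acc = 0.880, mcc = 0.761, f1 = 0.882),
  list(tp = 1, fp = 2, pr = 0.333, acc = 0.495, mcc = -0.041, f1 = 0.019),
  list(tp = 61, fp = 28, pr = 0.685, acc = 0.665, mcc = 0.332, f1 = 0.646)
)

test_that("confusion measures reproduce the balanced hold-out reference rows", {
  for (row in TABLE1) {
    m <- computeMetrics(tp = row$tp, tn = 100 - row$fp, fp = row$fp,
                        fn = 100 - row$tp)
    expect_equal(round(m$pr, 3), row$pr)
    expect_equal(round(m$acc, 3), row$acc)
    expect_equal(round(m$mcc, 3), row$mcc)
    expect_equal(round(m$f1, 3), row$f1)
    expect_equal(m$sn, row$tp / 100)
    expect_equal(m$sp, (100 - row$fp) / 100)
  }
})

test_that("metric identities, degenerate denominators and MCC symmetry hold", {
  perfect <- computeMetrics(tp = 100, tn = 100, fp = 0, fn = 0)
  expect_true(all(unlist(perfect) == 1))
  # undefined, not zero
  expect_true(is.na(computeMetrics(tp = 0, tn = 10, fp = 0, fn = 0)$pr))
  expect_true(is.na(computeMetrics(tp = 0, tn = 10, fp = 0, fn = 0)$sn))
  expect_error(computeMetrics(0, 0, 0, 0), "zero")
  set.seed(1)
  for (i in 1:20) {
    cc <- as.list(rpois(4, 30) + 1)
    names(cc) <- c("tp", "tn", "fp", "fn")
    m <- do.call(computeMetrics, cc)
    # balanced identity: acc = (sn + sp)/2 when class sizes match
    if (cc$tp + cc$fn == cc$tn + cc$fp)
      expect_equal(m$acc, (m$sn + m$sp) / 2)
    expect_equal(m$f1, 2 * m$pr * m$sn / (m$pr + m$sn), tolerance = 1e-12)
    swapped <- computeMetrics(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
    expect_equal(abs(swapped$mcc), abs(m$mcc), tolerance = 1e-12)
  }
})

test_that("ROC AUC equals the pairwise Mann-Whitney oracle and pROC", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  set.seed(2)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    scores <- round(runif(n), 1)          # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAUC(scores, labels), aucOracle(scores, labels),
                 tolerance = 1e-12)
    expect_equal(rocAUC(scores, labels),
                 as.numeric(suppressMessages(
                   pROC::auc(labels, scores, direction = "<"))),
                 tolerance = 1e-9)
  }
  expect_error(rocAUC(runif(5), rep(1, 5)), "both classes")
})

test_that("PR AUC matches an exhaustive threshold-enumeration oracle", {
  prOracle <- function(scores, labels) {
    nPos <- sum(labels == 1)
    ths <- sort(unique(scores), decreasing = TRUE)
    lastRecall <- 0; area <- 0
    for (t in ths) {
      sel <- scores >= t
      prec <- sum(labels[sel] == 1) / sum(sel)
      rec <- sum(labels[sel] == 1) / nPos
      area <- area + (rec - lastRecall) * prec
      lastRecall <- rec
    }
    area
  }
  expect_equal(prAUC(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    scores <- round(runif(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) next
    expect_equal(prAUC(scores, labels), prOracle(scores, labels),
                 tolerance = 1e-12)
  }
  # near the prevalence baseline for random scores on balanced classes
  set.seed(4)
  expect_equal(prAUC(runif(4000), rep(c(1, 0), 2000)), 0.5, tolerance = 0.05)
  expect_error(prAUC(runif(5), rep(0, 5)), "no positive")
})

test_that("curve coordinates are consistent with their scalar areas", {
  set.seed(11)
  scores <- round(runif(60), 1)
  labels <- rbinom(60, 1, 0.5)
  roc <- rocCurve(scores, labels)
  # trapezoid over the coordinates reproduces the rank-form AUC exactly
  # (midrank tie handling corresponds to the diagonal tie segments)
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, rocAUC(scores, labels), tolerance = 1e-12)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
  pr <- prCurve(scores, labels)
  steps <- sum(diff(c(0, pr$recall)) * pr$precision)
  expect_equal(steps, prAUC(scores, labels), tolerance = 1e-12)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})

test_that("position-specific base test flags only real compositional shifts", {
  wins <- randomSiteWindows(200, 11, seed = 5)
  same <- positionalBaseTest(wins[1:100], wins[101:200])
  expect_false(any(same$significant))
  expect_equal(nrow(same), 44L)
  # maximal separation at one position
  pos <- randomSiteWindows(200, 11, seed = 6)
  neg <- randomSiteWindows(200, 11, seed = 7)
  substr(pos, 4, 4) <- "G"
  substr(neg, 4, 4) <- "A"
  res <- positionalBaseTest(pos, neg)
  hit <- res[res$offset == -2 & res$base == "G", ]
  expect_true(hit$significant)
  expect_lt(hit$p_value, 1e-10)
  expect_error(positionalBaseTest(character(), wins), "non-empty")
})

test_that("rank-sum p-values agree with a permutation oracle at moderate effect", {
  set.seed(8)
  n <- 50
  pos <- ifelse(runif(n) < 0.62, "G", "A")
  neg <- ifelse(runif(n) < 0.38, "G", "A")
  posWins <- paste0(pos, "C", "A")
  negWins <- paste0(neg, "C", "A")
  res <- positionalBaseTest(posWins, negWins, alpha = 0.05)
  p <- res$p_value[res$offset == -1 & res$base == "G"]
  x <- as.integer(pos == "G"); y <- as.integer(neg == "G")
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  perm <- replicate(10000, {
    idx <- sample(2 * n, n)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  pPerm <- mean(perm >= obs - 1e-12)
  # slack covers the normal approximation of the rank-sum null at n = 50
  expect_lt(abs(p - pPerm), 0.03)
})

test_that("per-feature Welch t-test matches hand arithmetic and flags shifts", {
  pos <- matrix(c(1, 2, 5, 5), 2, dimnames = list(NULL, c("a", "b")))
  neg <- matrix(c(4, 6, 5, 5), 2, dimnames = list(NULL, c("a", "b")))
  res <- featureTTest(pos, neg, alpha = 0.5)
  # Welch t for a: means 1.5 vs 5, vars 0.5 and 2 -> t = -3.5/sqrt(1.25)
  expect_equal(res$t[res$feature == "a"], -3.5 / sqrt(1.25), tolerance = 1e-9)
  expect_true(is.na(res$p_value[res$feature == "b"]))  # constant in both
  expect_false(res$significant[res$feature == "b"])

  set.seed(9)
  posBig <- cbind(sig = rnorm(100, 5), noise = rnorm(100))
  negBig <- cbind(sig = rnorm(100, 0), noise = rnorm(100))
  res2 <- featureTTest(posBig, negBig)
  expect_true(res2$significant[res2$feature == "sig"])
  expect_false(res2$significant[res2$feature == "noise"])
  expect_error(featureTTest(posBig[1, , drop = FALSE], negBig), "two samples")
})
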