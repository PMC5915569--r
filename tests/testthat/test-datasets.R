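test_that("methylation level follows the pseudo-count proportion statistic", {
  expect_equal(computeMethylationLevel(0, 100), 0.00125)
  expect_equal(computeMethylationLevel(7, 93), 0.07125)
  expect_equal(computeMethylationLevel(100, 0, pseudo = 0), 1.0)
  expect_error(computeMethylationLevel(0, 0), "coverage")
  expect_error(computeMethylationLevel(-1, 5), "non-negative")
  expect_equal(computeMethylationLevel(c(0, 7), c(100, 93)),
               c(0.00125, 0.07125))
})

test_that("positive calling is boundary-inclusive, order-preserving, idempotent", {
  calls <- data.frame(transcript_id = "t", position = 1:5,
                      level = c(0.01, 0.009, 0.5, 0.02, 0.8),
                      fdr = c(0.30, 0.0, 0.31, 0.1, 0.3))
  kept <- callPositives(calls)
  expect_equal(kept$position, c(1L, 4L, 5L))  # boundaries retained, order kept
  expect_equal(callPositives(kept), kept)     # idempotent
  expect_error(callPositives(data.frame(level = 0.5)), "fdr")
})

test_that("binomial p-value / BH route populates fdr and flags real signal", {
  calls <- data.frame(transcript_id = "t", position = 1:3,
                      c_count = c(30, 1, 0), t_count = c(70, 99, 100))
  out <- addSiteFDR(calls, errorRate = 0.005)
  # independent arithmetic for the first site: P(X >= 30), X ~ Bin(100, .005)
  pOracle <- 1 - sum(dbinom(0:29, 100, 0.005))
  expect_equal(out$p_value[1], pOracle, tolerance = 1e-12)
  expect_true(out$fdr[1] < 1e-10)
  expect_true(out$fdr[3] > 0.3)  # zero C reads cannot be called
  expect_equal(out$level, computeMethylationLevel(calls$c_count, calls$t_count))
})

test_that("window extraction pads borders with N and normalizes DNA to RNA", {
  expect_equal(extractWindow("ACGUA", 2, 2, 2), "ACGUA")
  expect_equal(extractWindow("CGU", 0, 2, 2), "NNCGU")
  expect_equal(extractWindow("ACGT", 1, 1, 1), "ACG")
  expect_equal(extractWindow("ACGT", 3, 1, 1), "GUN")
  expect_equal(nchar(extractWindow("ACGUA", 0, 21, 21)), 43L)
  expect_error(extractWindow("ACGUA", 2, -1, 2), "non-negative")
  expect_error(extractWindow("ACGUA", 7, 1, 1), "outside")
})

test_that("GC-matched negative sampling honours distance, GC and count limits", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "U"), 500, TRUE), collapse = "")
  pos <- 250L
  substr(seq, pos + 1L, pos + 1L) <- "C"
  posGC <- gc <- NULL
  negs <- sampleGCMatchedNegatives(seq, pos, knownPositives = pos)
  expect_lte(nrow(negs), 10L)
  posWin <- extractWindow(seq, pos, 21, 21)
  posGC <- mean(strsplit(posWin, "")[[1]] %in% c("G", "C"))
  for (i in seq_len(nrow(negs))) {
    expect_lte(abs(negs$position[i] - pos), 100L)
    expect_false(negs$position[i] %in% pos)
    expect_identical(substr(seq, negs$position[i] + 1L, negs$position[i] + 1L), "C")
    expect_lte(abs(negs$gc[i] - posGC), 0.05 + 1e-12)
  }
  # no other cytosines in range -> empty result plus a shortfall warning
  lonely <- paste(c(rep("A", 100), "C", rep("A", 100)), collapse = "")
  expect_warning(out <- sampleGCMatchedNegatives(lonely, 100L, integer()),
                 "eligible")
  expect_equal(nrow(out), 0L)
})

test_that("negative sampling and the full dataset build are seed-deterministic", {
  sim <- simulateDataset(simConfig(nTranscripts = 6L, nPositives = 12L,
                                   effectStrength = 0, seed = 11L))
  counts <- simulateBisulfiteCounts(sim$truth, sim$transcripts,
                                    simConfig(seed = 11L, minCoverage = 50L))
  ds1 <- suppressWarnings(buildTrainingSet(counts, sim$transcripts, seed = 5L))
  ds2 <- suppressWarnings(buildTrainingSet(counts, sim$transcripts, seed = 5L))
  expect_identical(ds1, ds2)
  ds3 <- suppressWarnings(buildTrainingSet(counts, sim$transcripts, seed = 6L))
  expect_false(identical(ds1, ds3))
})

test_that("every emitted sample window has configured length and central C", {
  sim <- simulateDataset(simConfig(nTranscripts = 6L, nPositives = 15L,
                                   seed = 21L))
  counts <- simulateBisulfiteCounts(sim$truth, sim$transcripts,
                                    simConfig(seed = 21L, minCoverage = 50L))
  ds <- suppressWarnings(buildTrainingSet(counts, sim$transcripts, seed = 1L))
  expect_true(all(nchar(ds$window) == 43L))
  expect_true(all(substr(ds$window, 22, 22) == "C"))
  expect_true(all(ds$label %in% c("pos", "neg")))
  # per positive, at most 10 negatives
  negPerPos <- table(ds$transcript_id[ds$label == "neg"])
  nPos <- table(ds$transcript_id[ds$label == "pos"])
  for (tx in names(nPos))
    expect_lte(negPerPos[tx], 10L * nPos[tx])
})

test_that("dataset FASTA round-trips with labels and 1-based sidecar", {
  samples <- data.frame(transcript_id = c("t1", "t1", "t2"),
                        position = c(21L, 60L, 30L),
                        label = c("pos", "neg", "pos"),
                        window = randomSiteWindows(3, 43, seed = 3),
                        gc = c(0.5, 0.51, 0.4))
  path <- tempfile(fileext = ".fa")
  writeDatasetFasta(samples, path)
  back <- readDatasetFasta(path)
  expect_equal(back$transcript_id, samples$transcript_id)
  expect_equal(back$position, samples$position)
  expect_equal(back$label, samples$label)
  expect_equal(back$window, samples$window)
  side <- read.delim(paste0(path, ".tsv"))
  expect_equal(side$position, samples$position + 1L)
})

test_that("count tables convert between 1-based disk and 0-based memory", {
  tab <- data.frame(transcript_id = "t", position = c(5L, 9L),
                    c_count = c(3L, 0L), t_count = c(7L, 10L))
  path <- tempfile(fileext = ".tsv")
  writeCountTable(tab, path)
  back <- readCountTable(path)
  expect_equal(back$position, tab$position)
  raw <- read.delim(path)
  expect_equal(raw$position, tab$position + 1L)
})
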