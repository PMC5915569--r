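# Fixtures built in code: random windows, labeled sets derived from the
# synthetic generator, and a lazily built shared model reused across files.

randomWindows <- function(n, L, seed, alphabet = c("A", "C", "G", "U")) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

# Centered windows (central C) with optional N padding mixed in
randomSiteWindows <- function(n, L, seed, nRate = 0) {
  wins <- randomWindows(n, L, seed, alphabet = c("A", "C", "G", "U"))
  c0 <- (L + 1L) %/% 2L
  substr(wins, c0, c0) <- "C"
  if (nRate > 0) {
    set.seed(seed + 1L)
    for (i in seq_len(n)) {
      k <- rbinom(1, L, nRate)
      if (k > 0) {
        pos <- sample(setdiff(seq_len(L), c0), min(k, L - 1L))
        for (p in pos) substr(wins[i], p, p) <- "N"
      }
    }
  }
  wins
}

# Labeled samples from a simulated transcriptome: truth sites as positives,
# GC-matched nearby cytosines as negatives.
labeledFromSim <- function(sim, negPerPos = 10L, upstream = 21L,
                           downstream = 21L, seed = 1L) {
  seqs <- as.character(sim$transcripts)
  names(seqs) <- names(sim$transcripts)
  set.seed(seed)
  rows <- list()
  byTx <- split(sim$truth$position, sim$truth$transcript_id)
  for (tx in names(byTx)) {
    seq <- seqs[[tx]]
    known <- byTx[[tx]]
    for (p in known) {
      w <- extractWindow(seq, p, upstream, downstream)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, position = p, label = "pos", window = w,
        stringsAsFactors = FALSE)
      negs <- suppressWarnings(sampleGCMatchedNegatives(
        seq, p, known, negPerPos = negPerPos,
        upstream = upstream, downstream = downstream))
      if (nrow(negs))
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx, position = negs$position, label = "neg",
          window = negs$window, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared small trained model (strong planted signal), built once per run.
.shared <- new.env(parent = emptyenv())
sharedSimAndModel <- function() {
  if (is.null(.shared$model)) {
    sim <- simulateDataset(simConfig(nTranscripts = 30L, nPositives = 80L,
                                     effectStrength = 1, seed = 42L))
    samples <- labeledFromSim(sim, seed = 43L)
    model <- buildEnsembleModel(samples, upstream = 5L, downstream = 5L,
                                folds = 5L, numTrees = 50L, seed = 44L)
    .shared$sim <- sim
    .shared$model <- model
  }
  list(sim = .shared$sim, model = .shared$model)
}
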