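## Synthetic transcriptome generator: random transcripts, planted m5C
## positives whose flanks are redrawn from a G-enriched positional weight
## model (effect strength epsilon interpolates background -> enriched), and
## simulated bisulfite count tables. Every other module is testable against
## the truth tables this produces; the signal model is a testing artifact,
## not a biological claim.

#' Simulation configuration
#'
#' @param nTranscripts number of transcripts (default 50)
#' @param lengthRange min/max transcript length in nt (default 500-2000)
#' @param baseComposition named background probabilities for A/C/G/U
#'   (default uniform)
#' @param nPositives number of planted m5C sites (default 100)
#' @param effectStrength epsilon in `[0, 1]`: 0 leaves flanks at background,
#'   1 draws them fully from the enriched weights
#' @param signalUpstream,signalDownstream flank extent (nt) over which the
#'   signal weights apply (default 5/5)
#' @param gWeight probability of G at signal positions when epsilon = 1
#'   (default 0.9; the remainder is split evenly over A/C/U)
#' @param contextMix optional named CG/CHG/CHH fractions; when set, the two
#'   bases 3' of each planted site are forced to the sampled context
#' @param methylationLevel true methylation level of planted sites
#'   (default 0.3)
#' @param coverageMean,coverageDispersion negative-binomial read-coverage
#'   model (mean 100, size 5)
#' @param minCoverage floor applied to drawn coverages (default 0)
#' @param conversionError bisulfite non-conversion error rate (default 0.005)
#' @param seed integer seed
#' @return a list of class `SimConfig`
#' @export
simConfig <- function(nTranscripts = 50L, lengthRange = c(500L, 2000L),
                      baseComposition = c(A = 0.25, C = 0.25,
                                          G = 0.25, U = 0.25),
                      nPositives = 100L, effectStrength = 1,
                      signalUpstream = 5L, signalDownstream = 5L,
                      gWeight = 0.9, contextMix = NULL,
                      methylationLevel = 0.3, coverageMean = 100,
                      coverageDispersion = 5, minCoverage = 0L,
                      conversionError = 0.005, seed = 1L) {
  stopifnot(abs(sum(baseComposition) - 1) < 1e-9,
            effectStrength >= 0, effectStrength <= 1,
            gWeight >= 0, gWeight <= 1,
            methylationLevel >= 0, methylationLevel <= 1)
  if (!is.null(contextMix))
    stopifnot(abs(sum(contextMix) - 1) < 1e-9,
              all(c("CG", "CHG", "CHH") %in% names(contextMix)))
  cfg <- list(nTranscripts = as.integer(nTranscripts),
              lengthRange = as.integer(lengthRange),
              baseComposition = baseComposition[RNA_BASES],
              nPositives = as.integer(nPositives),
              effectStrength = effectStrength,
              signalUpstream = as.integer(signalUpstream),
              signalDownstream = as.integer(signalDownstream),
              gWeight = gWeight, contextMix = contextMix,
              methylationLevel = methylationLevel,
              coverageMean = coverageMean,
              coverageDispersion = coverageDispersion,
              minCoverage = as.integer(minCoverage),
              conversionError = conversionError, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# Per-position base probabilities at a signal offset: epsilon-interpolation
# between the background composition and the G-enriched target.
signalProbs <- function(cfg) {
  target <- setNames(rep((1 - cfg$gWeight) / 3, 4), RNA_BASES)
  target["G"] <- cfg$gWeight
  (1 - cfg$effectStrength) * cfg$baseComposition + cfg$effectStrength * target
}

#' Simulate a synthetic transcriptome with planted m5C sites
#'
#' Transcripts are drawn i.i.d. from the background composition; each gets a
#' CDS interval (roughly the middle 60%, opened with a planted AUG) so
#' downstream annotation is exercised. Positives are planted at randomly
#' chosen cytosines with sufficient flanks; their signal-range flank bases
#' are redrawn from the epsilon-interpolated weights (and, when `contextMix`
#' is set, the two downstream bases are forced to a sampled context). Byte
#' identical across runs with the same config.
#'
#' @param cfg a [simConfig()] list
#' @return list with `transcripts` (an `RNAStringSet` with CDS metadata, see
#'   [transcriptModels()]) and `truth` (data.frame `transcript_id`,
#'   `position` 0-based, `level`)
#' @export
simulateDataset <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  lens <- sample(cfg$lengthRange[1]:cfg$lengthRange[2], cfg$nTranscripts,
                 replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(RNA_BASES, n, replace = TRUE, prob = cfg$baseComposition),
          collapse = ""), character(1))
  # CDS spanning the middle of each transcript, start codon planted
  cdsStart <- pmax(3L, as.integer(lens * 0.2))
  cdsEnd <- pmin(lens, as.integer(lens * 0.8))
  for (i in seq_along(seqs)) {
    substr(seqs[i], cdsStart[i] + 1L, cdsStart[i] + 3L) <- "AUG"
  }
  names(seqs) <- sprintf("synthetic_tx_%03d", seq_along(seqs))

  up <- cfg$signalUpstream; down <- cfg$signalDownstream
  probs <- signalProbs(cfg)
  # candidate cytosines with full signal flanks inside the transcript
  candidates <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    ch <- windowChars(seqs[i])
    pos <- which(ch == "C") - 1L
    pos <- pos[pos >= up & pos <= lens[i] - 1L - down]
    # keep the planted start codon intact: no mutation footprint may touch it
    pos <- pos[pos + down < cdsStart[i] | pos - up > cdsStart[i] + 2L]
    if (!length(pos)) return(NULL)
    data.frame(tx = i, pos = pos)
  }))
  if (is.null(candidates) || nrow(candidates) < cfg$nPositives)
    stop("requested ", cfg$nPositives, " positives but only ",
         if (is.null(candidates)) 0L else nrow(candidates),
         " eligible cytosines exist")
  pick <- candidates[sample(nrow(candidates), cfg$nPositives), ]
  pick <- pick[order(pick$tx, pick$pos), ]

  ctxLevels <- c("CG", "CHG", "CHH")
  hBases <- c("A", "C", "U")
  plantedByTx <- split(pick$pos, pick$tx)
  for (k in seq_len(nrow(pick))) {
    i <- pick$tx[k]; p <- pick$pos[k]
    planted <- plantedByTx[[as.character(i)]]
    # never overwrite another planted site's central C
    offs <- setdiff(seq.int(p - up, p + down), planted)
    flank <- sample(RNA_BASES, length(offs), replace = TRUE, prob = probs)
    s <- seqs[i]
    for (j in seq_along(offs))
      substr(s, offs[j] + 1L, offs[j] + 1L) <- flank[j]
    if (!is.null(cfg$contextMix) && p + 2L <= nchar(s) - 1L &&
        !any(c(p + 1L, p + 2L) %in% planted)) {
      ctx <- sample(ctxLevels, 1L, prob = cfg$contextMix[ctxLevels])
      d <- switch(ctx,
                  CG = c("G", sample(RNA_BASES, 1L)),
                  CHG = c(sample(hBases, 1L), "G"),
                  CHH = sample(hBases, 2L, replace = TRUE))
      substr(s, p + 2L, p + 2L) <- d[1]
      substr(s, p + 3L, p + 3L) <- d[2]
    }
    seqs[i] <- s
  }
  truth <- data.frame(transcript_id = names(seqs)[pick$tx],
                      position = pick$pos,
                      level = cfg$methylationLevel,
                      stringsAsFactors = FALSE)
  tx <- transcriptModels(seqs, rnaClass = "mRNA",
                         cdsStart = cdsStart, cdsEnd = cdsEnd)
  list(transcripts = tx, truth = truth)
}

#' Simulate a bisulfite count table over all cytosines
#'
#' Per cytosine, coverage is drawn from the configured negative-binomial
#' model (floored at `minCoverage`); the C count is binomial with success
#' probability equal to the planted methylation level at truth sites and the
#' non-conversion error rate elsewhere. Zero-coverage rows are emitted with
#' zero counts.
#'
#' @param truth truth table from [simulateDataset()]
#' @param transcripts the matching transcript set
#' @param cfg the [simConfig()] used (coverage/error/level fields)
#' @return data.frame `transcript_id`, `position` (0-based), `c_count`,
#'   `t_count`
#' @export
simulateBisulfiteCounts <- function(truth, transcripts, cfg = simConfig()) {
  seqs <- asSequenceVector(transcripts)
  set.seed(deriveSeed(cfg$seed, 17L))
  truthKey <- paste(truth$transcript_id, truth$position)
  rows <- lapply(seq_along(seqs), function(i) {
    ch <- windowChars(normalizeRNA(seqs[[i]]))
    cpos <- which(ch == "C") - 1L
    if (!length(cpos)) return(NULL)
    data.frame(transcript_id = names(seqs)[i], position = cpos,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("transcripts contain no cytosines")
  n <- nrow(tab)
  coverage <- pmax(cfg$minCoverage,
                   rnbinom(n, size = cfg$coverageDispersion,
                           mu = cfg$coverageMean))
  m <- ifelse(paste(tab$transcript_id, tab$position) %in% truthKey,
              cfg$methylationLevel, cfg$conversionError)
  tab$c_count <- rbinom(n, coverage, m)
  tab$t_count <- coverage - tab$c_count
  tab
}
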