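## Dataset construction from bisulfite-derived per-cytosine counts:
## methylation-level calling, positive filtering, GC-matched negative
## sampling, and fixed-width window extraction.

#' Methylation level from bisulfite C/T counts
#'
#' The proportion statistic `P = (C + psi) / (T + C)` with pseudo-count
#' `psi` (default 1/8) stabilizing low-coverage sites.
#'
#' @param cCount,tCount non-negative read counts supporting C (methylated)
#'   and T (converted); vectorized
#' @param pseudo pseudo-count added to the numerator (default 1/8)
#' @return numeric methylation level(s)
#' @examples
#' computeMethylationLevel(0, 100)   # 0.00125
#' computeMethylationLevel(7, 93)    # 0.07125
#' @export
computeMethylationLevel <- function(cCount, tCount, pseudo = 1 / 8) {
  if (any(cCount < 0) || any(tCount < 0))
    stop("counts must be non-negative")
  total <- cCount + tCount
  if (any(total == 0))
    stop("zero total coverage: methylation level undefined")
  (cCount + pseudo) / total
}

#' One-sided binomial p-values for methylation calls
#'
#' Tests, per site, whether the observed C count exceeds what the bisulfite
#' non-conversion error rate alone would produce: `P(X >= c)` with
#' `X ~ Binomial(c + t, errorRate)`. Intended as a self-contained stand-in
#' p-value generator when the count table lacks one; combine with
#' Benjamini-Hochberg via [addSiteFDR()].
#'
#' @param cCount,tCount read counts (vectorized)
#' @param errorRate assumed non-conversion error rate (default 0.005)
#' @return numeric p-values
#' @export
binomialSitePValues <- function(cCount, tCount, errorRate = 0.005) {
  n <- cCount + tCount
  pbinom(cCount - 1, n, errorRate, lower.tail = FALSE)
}

#' Attach p-values and BH-adjusted FDR to a count table
#'
#' Fills the `p_value` column (binomial test against `errorRate`) where
#' missing, then sets `fdr` by Benjamini-Hochberg across all rows.
#'
#' @param calls data.frame with `c_count`, `t_count` (and optionally `p_value`)
#' @param errorRate non-conversion error rate for the binomial test
#' @return `calls` with `level`, `p_value` and `fdr` columns populated
#' @export
addSiteFDR <- function(calls, errorRate = 0.005) {
  calls$level <- computeMethylationLevel(calls$c_count, calls$t_count)
  if (is.null(calls$p_value) || all(is.na(calls$p_value)))
    calls$p_value <- binomialSitePValues(calls$c_count, calls$t_count, errorRate)
  calls$fdr <- p.adjust(calls$p_value, method = "BH")
  calls
}

#' Filter cytosine calls to positive (methylated) sites
#'
#' Retains calls with methylation level >= `levelMin` and FDR <= `fdrMax`;
#' both boundaries inclusive. Order-preserving and idempotent.
#'
#' @param calls data.frame with `level` and `fdr` columns
#' @param levelMin minimal methylation level (default 0.01, i.e. 1%)
#' @param fdrMax maximal FDR (default 0.3)
#' @return the retained rows of `calls`
#' @export
callPositives <- function(calls, levelMin = 0.01, fdrMax = 0.3) {
  if (is.null(calls$level)) stop("calls must carry a 'level' column")
  if (is.null(calls$fdr) || any(is.na(calls$fdr)))
    stop("calls must carry a populated 'fdr' column (see addSiteFDR)")
  calls[calls$level >= levelMin & calls$fdr <= fdrMax, , drop = FALSE]
}

#' Extract a fixed-width RNA window around a transcript position
#'
#' Returns `upstream + 1 + downstream` characters centered on `position`
#' (0-based). Positions falling outside the transcript are filled with `N`;
#' DNA input is normalized to RNA (T to U).
#'
#' @param transcriptSeq transcript sequence (string, RNA or DNA alphabet)
#' @param position 0-based index of the site within the transcript
#' @param upstream,downstream non-negative flank lengths
#' @return window string over {A,C,G,U,N}
#' @examples
#' extractWindow("CGU", 0, 2, 2)  # "NNCGU"
#' @export
extractWindow <- function(transcriptSeq, position, upstream, downstream) {
  if (upstream < 0 || downstream < 0)
    stop("upstream/downstream must be non-negative")
  seq <- normalizeRNA(as.character(transcriptSeq))
  n <- nchar(seq)
  if (position < 0 || position >= n)
    stop("position ", position, " outside transcript of length ", n)
  lo <- position - upstream          # 0-based inclusive
  hi <- position + downstream
  core <- substr(seq, max(lo, 0) + 1L, min(hi, n - 1L) + 1L)
  paste0(strrep("N", max(0L, -lo)), core, strrep("N", max(0L, hi - (n - 1L))))
}

#' Sample GC-matched negative cytosines around a positive site
#'
#' Picks up to `negPerPos` cytosines within `regionHalfwidth` nt of the
#' positive (a 200-nt region under defaults) that are not themselves known
#' positives and whose window GC content differs from the positive's window
#' by at most `gcTolerance`. Selection among eligible candidates is uniform
#' at random; a shortfall is reported with a warning.
#'
#' @param transcriptSeq transcript sequence string
#' @param position 0-based position of the positive cytosine
#' @param knownPositives integer vector of 0-based positive positions in this
#'   transcript (excluded from candidacy)
#' @param negPerPos negatives per positive (default 10)
#' @param regionHalfwidth search radius in nt (default 100)
#' @param gcTolerance maximal window-GC difference (default 0.05)
#' @param upstream,downstream window geometry used for GC and emitted windows
#' @return data.frame with `position`, `window`, `gc` for each negative
#' @export
sampleGCMatchedNegatives <- function(transcriptSeq, position, knownPositives,
                                     negPerPos = 10L, regionHalfwidth = 100L,
                                     gcTolerance = 0.05,
                                     upstream = 21L, downstream = 21L) {
  seq <- normalizeRNA(as.character(transcriptSeq))
  n <- nchar(seq)
  posWindow <- extractWindow(seq, position, upstream, downstream)
  posGC <- gcContent(posWindow)
  lo <- max(0L, position - regionHalfwidth)
  hi <- min(n - 1L, position + regionHalfwidth)
  ch <- windowChars(substr(seq, lo + 1L, hi + 1L))
  cand <- (lo:hi)[ch == "C"]
  cand <- setdiff(cand, c(position, knownPositives))
  if (length(cand)) {
    wins <- vapply(cand, function(p) extractWindow(seq, p, upstream, downstream),
                   character(1))
    gcs <- vapply(wins, gcContent, numeric(1))
    ok <- !is.na(gcs) & abs(gcs - posGC) <= gcTolerance
    cand <- cand[ok]; wins <- wins[ok]; gcs <- gcs[ok]
  } else {
    wins <- character(0); gcs <- numeric(0)
  }
  if (length(cand) < negPerPos)
    warning("only ", length(cand), " eligible GC-matched negatives (requested ",
            negPerPos, ") around position ", position)
  take <- if (length(cand) > negPerPos) sample(length(cand), negPerPos)
          else seq_along(cand)
  take <- sort(take)
  data.frame(position = cand[take], window = wins[take], gc = gcs[take],
             stringsAsFactors = FALSE)
}

#' Build a labeled training set from calls and transcripts
#'
#' Runs the full dataset construction: filters positive cytosines
#' (level/FDR criteria), verifies each addresses a `C`, extracts fixed-width
#' windows (flanks N-padded; sites whose own base would be padded are
#' rejected), and draws GC-matched negatives around every positive.
#'
#' @param calls data.frame (`transcript_id`, `position` 0-based, `c_count`,
#'   `t_count`, optional `p_value`/`fdr`) — see [readCountTable()]
#' @param transcripts named character vector or `XStringSet` of transcript
#'   sequences (IDs matched up to first whitespace)
#' @param negPerPos,regionHalfwidth,gcTolerance negative-sampling parameters
#' @param levelMin,fdrMax positive-call criteria
#' @param upstream,downstream window geometry (defaults 21/21: 43-nt windows)
#' @param errorRate non-conversion error rate for the fallback binomial FDR
#' @param seed integer seed; the whole build is reproducible under it
#' @return data.frame with `transcript_id`, `position` (0-based),
#'   `label` ("pos"/"neg"), `window`, `gc`
#' @export
buildTrainingSet <- function(calls, transcripts, negPerPos = 10L,
                             regionHalfwidth = 100L, gcTolerance = 0.05,
                             levelMin = 0.01, fdrMax = 0.3,
                             upstream = 21L, downstream = 21L,
                             errorRate = 0.005, seed = 1L) {
  seqs <- asSequenceVector(transcripts)
  if (is.null(calls$fdr) || all(is.na(calls$fdr)))
    calls <- addSiteFDR(calls, errorRate = errorRate)
  if (is.null(calls$level))
    calls$level <- computeMethylationLevel(calls$c_count, calls$t_count)
  pos <- callPositives(calls, levelMin = levelMin, fdrMax = fdrMax)
  if (nrow(pos) == 0L) stop("no positive sites pass the filter")
  set.seed(seed)
  byTx <- split(seq_len(nrow(pos)), pos$transcript_id)
  rows <- list()
  shortfalls <- 0L
  for (tx in names(byTx)) {
    if (!tx %in% names(seqs)) {
      warning("transcript ", tx, " not found in FASTA; skipped")
      next
    }
    seq <- normalizeRNA(seqs[[tx]])
    idx <- byTx[[tx]]
    known <- pos$position[idx]
    for (i in idx) {
      p <- pos$position[i]
      if (p < 0 || p >= nchar(seq)) {
        warning("position ", p, " outside transcript ", tx, "; skipped")
        next
      }
      if (substr(seq, p + 1L, p + 1L) != "C") {
        warning("site ", tx, ":", p, " does not address a C; skipped")
        next
      }
      w <- extractWindow(seq, p, upstream, downstream)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, position = p, label = "pos",
        window = w, gc = gcContent(w), stringsAsFactors = FALSE)
      negs <- withCallingHandlers(
        sampleGCMatchedNegatives(seq, p, known, negPerPos = negPerPos,
                                 regionHalfwidth = regionHalfwidth,
                                 gcTolerance = gcTolerance,
                                 upstream = upstream, downstream = downstream),
        warning = function(w_) {
          shortfalls <<- shortfalls + 1L
          invokeRestart("muffleWarning")
        })
      if (nrow(negs))
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx, position = negs$position, label = "neg",
          window = negs$window, gc = negs$gc, stringsAsFactors = FALSE)
    }
  }
  if (shortfalls > 0L)
    warning(shortfalls, " positive site(s) had fewer than ", negPerPos,
            " eligible GC-matched negatives")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

asSequenceVector <- function(transcripts) {
  if (methods::is(transcripts, "XStringSet")) {
    seqs <- as.character(transcripts)
  } else {
    seqs <- as.character(transcripts)
    names(seqs) <- names(transcripts)
  }
  if (is.null(names(seqs))) stop("transcripts must be named")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a per-cytosine bisulfite count table
#'
#' TSV with header `transcript_id position c_count t_count [p_value] [fdr]`;
#' positions are 1-based on disk and converted to 0-based internally.
#'
#' @param path TSV path
#' @return data.frame with 0-based `position`
#' @export
readCountTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "c_count", "t_count")
  if (!all(need %in% names(tab)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  tab$position <- as.integer(tab$position) - 1L
  tab
}

#' Write a count table (1-based positions on disk)
#' @param calls data.frame with 0-based `position`
#' @param path output TSV path
#' @export
writeCountTable <- function(calls, path) {
  out <- calls
  out$position <- out$position + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA path (DNA or RNA alphabet; normalized to RNA)
#' @return named character vector of RNA sequences, IDs truncated at first
#'   whitespace
#' @export
readTranscripts <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalizeRNA(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a labeled dataset as FASTA plus sidecar TSV
#'
#' FASTA headers carry `|label=pos|` / `|label=neg|` tokens; the sidecar TSV
#' (`<path>.tsv`) holds `transcript_id position label gc` with 1-based
#' positions.
#'
#' @param samples data.frame from [buildTrainingSet()]
#' @param path output FASTA path
#' @return invisibly, the FASTA path
#' @export
writeDatasetFasta <- function(samples, path) {
  headers <- sprintf("%s:%d|label=%s|", samples$transcript_id,
                     samples$position + 1L, samples$label)
  lines <- as.vector(rbind(paste0(">", headers), samples$window))
  writeLines(lines, path)
  side <- data.frame(transcript_id = samples$transcript_id,
                     position = samples$position + 1L,
                     label = samples$label, gc = samples$gc)
  write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a labeled dataset FASTA written by [writeDatasetFasta()]
#' @param path FASTA path
#' @return data.frame with `transcript_id`, `position` (0-based), `label`,
#'   `window`
#' @export
readDatasetFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  label <- sub("^.*\\|label=([a-z]+)\\|.*$", "\\1", hdr)
  loc <- sub("\\|.*$", "", hdr)
  tx <- sub(":[0-9]+$", "", loc)
  posn <- as.integer(sub("^.*:", "", loc)) - 1L
  data.frame(transcript_id = tx, position = posn, label = label,
             window = normalizeRNA(as.character(set)), stringsAsFactors = FALSE)
}
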