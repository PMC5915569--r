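## Transcriptome-wide scanning and downstream annotation: sequence context
## (CG/CHG/CHH), mRNA region (5'UTR/CDS/3'UTR), distance to the translational
## start site, metagene profiles and context proportions.
##
## Transcript models are carried as an RNAStringSet whose mcols() hold
## `rnaClass` and the 0-based half-open CDS interval `cdsStart`/`cdsEnd`
## (NA for noncoding classes).

RNA_CLASSES <- c("mRNA", "lncRNA", "miRNA", "pri-miRNA", "rRNA", "snoRNA",
                 "snRNA", "tRNA", "other")

#' Assemble transcript models from sequences and CDS annotation
#'
#' @param seqs named character vector or `XStringSet` of transcript sequences
#' @param rnaClass character vector of RNA classes (recycled; unknown values
#'   map to "other")
#' @param cdsStart,cdsEnd 0-based half-open CDS interval per transcript
#'   (NA for noncoding). A warning is emitted when an annotated start codon
#'   is not AUG.
#' @return `RNAStringSet` with `rnaClass`, `cdsStart`, `cdsEnd` in `mcols()`
#' @export
transcriptModels <- function(seqs, rnaClass = "mRNA",
                             cdsStart = NA_integer_, cdsEnd = NA_integer_) {
  v <- asSequenceVector(seqs)
  v[] <- normalizeRNA(v)
  n <- length(v)
  rnaClass <- rep_len(ifelse(rnaClass %in% RNA_CLASSES, rnaClass, "other"), n)
  cdsStart <- rep_len(as.integer(cdsStart), n)
  cdsEnd <- rep_len(as.integer(cdsEnd), n)
  for (i in seq_len(n)) {
    if (!is.na(cdsStart[i])) {
      if (cdsStart[i] < 0 || is.na(cdsEnd[i]) || cdsStart[i] >= cdsEnd[i] ||
          cdsEnd[i] > nchar(v[i]))
        stop("invalid CDS interval for transcript ", names(v)[i])
      codon <- substr(v[i], cdsStart[i] + 1L, cdsStart[i] + 3L)
      if (nchar(codon) == 3L && codon != "AUG")
        warning("annotated start codon of ", names(v)[i], " is ", codon,
                ", not AUG")
    }
  }
  set <- Biostrings::RNAStringSet(v)
  S4Vectors::mcols(set) <- S4Vectors::DataFrame(
    rnaClass = rnaClass, cdsStart = cdsStart, cdsEnd = cdsEnd)
  set
}

GFF_CLASS_MAP <- c(
  mRNA = "mRNA", lnc_RNA = "lncRNA", lncRNA = "lncRNA",
  antisense_lncRNA = "lncRNA", miRNA = "miRNA",
  miRNA_primary_transcript = "pri-miRNA", pri_miRNA = "pri-miRNA",
  rRNA = "rRNA", snoRNA = "snoRNA", snRNA = "snRNA", tRNA = "tRNA")

#' Reconstruct transcript models from a genome FASTA and GFF3
#'
#' Transcript sequences are rebuilt as spliced exon concatenations (exons
#' grouped by their `Parent` transcript, ordered along the genome;
#' minus-strand transcripts are reverse-complemented). CDS features are
#' mapped into transcript coordinates (0-based half-open). Transcripts with
#' no exon children use their own genomic range as a single exon. GFF3 is
#' read as 1-based inclusive via `rtracklayer`.
#'
#' @param genome named character vector / `XStringSet` of chromosome
#'   sequences, or a FASTA path
#' @param gff path to a GFF3 file
#' @return `RNAStringSet` with `rnaClass`, `cdsStart`, `cdsEnd` in `mcols()`
#' @export
readTranscriptModels <- function(genome, gff) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readBStringSet(genome)
  gseqs <- asSequenceVector(genome)
  feats <- rtracklayer::import(gff, format = "gff3")
  type <- as.character(feats$type)
  isTx <- type %in% names(GFF_CLASS_MAP) |
    type %in% c("transcript", "ncRNA", "ncRNA_gene")
  txFeats <- feats[isTx]
  ids <- as.character(txFeats$ID)
  if (anyNA(ids)) stop("transcript features must carry ID attributes")
  firstParent <- function(x) vapply(as.list(x), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  exonParent <- firstParent(feats$Parent[type == "exon"])
  exons <- feats[type == "exon"]
  cds <- feats[type == "CDS"]
  cdsParent <- firstParent(cds$Parent)

  out <- character(length(txFeats))
  cls <- character(length(txFeats))
  cdsStart <- rep(NA_integer_, length(txFeats))
  cdsEnd <- rep(NA_integer_, length(txFeats))
  for (i in seq_along(txFeats)) {
    id <- ids[i]
    ex <- exons[!is.na(exonParent) & exonParent == id]
    if (length(ex) == 0L) ex <- txFeats[i]
    ex <- ex[order(GenomicRanges::start(ex))]
    chrom <- as.character(GenomicRanges::seqnames(txFeats[i]))
    if (!chrom %in% names(gseqs))
      stop("chromosome ", chrom, " absent from genome FASTA")
    minus <- as.character(GenomicRanges::strand(txFeats[i])) == "-"
    pieces <- substring(gseqs[[chrom]], GenomicRanges::start(ex),
                        GenomicRanges::end(ex))
    seq <- normalizeRNA(paste(pieces, collapse = ""))
    if (minus)
      seq <- chartr("ACGU", "UGCA",
                    paste(rev(windowChars(seq)), collapse = ""))
    out[i] <- seq
    cls[i] <- if (type[which(isTx)[i]] %in% names(GFF_CLASS_MAP))
      GFF_CLASS_MAP[[type[which(isTx)[i]]]] else "other"

    myCds <- cds[!is.na(cdsParent) & cdsParent == id]
    if (length(myCds)) {
      gStarts <- GenomicRanges::start(ex); gEnds <- GenomicRanges::end(ex)
      cumOff <- cumsum(c(0L, gEnds - gStarts + 1L))
      toTx <- function(gpos) {  # genomic (1-based) -> transcript 0-based
        j <- which(gpos >= gStarts & gpos <= gEnds)[1]
        if (is.na(j)) stop("CDS coordinate outside exons of ", id)
        cumOff[j] + (gpos - gStarts[j])
      }
      gmin <- min(GenomicRanges::start(myCds))
      gmax <- max(GenomicRanges::end(myCds))
      txLen <- cumOff[length(cumOff)]
      if (minus) {
        s <- txLen - 1L - toTx(gmax)
        e <- txLen - 1L - toTx(gmin)
      } else {
        s <- toTx(gmin)
        e <- toTx(gmax)
      }
      cdsStart[i] <- s
      cdsEnd[i] <- e + 1L  # half-open
    }
  }
  names(out) <- ids
  transcriptModels(out, rnaClass = cls, cdsStart = cdsStart, cdsEnd = cdsEnd)
}

#' Classify the sequence context of a cytosine
#'
#' `CG` if the next base is G; else `CHG` if the base after next is G; else
#' `CHH` (H = A, C or U). `NA` when the needed downstream bases are missing
#' or N.
#'
#' @param sequence RNA sequence string
#' @param position 0-based position of the cytosine
#' @return one of `"CG"`, `"CHG"`, `"CHH"`, `NA`
#' @export
classifyContext <- function(sequence, position) {
  seq <- normalizeRNA(as.character(sequence))
  n <- nchar(seq)
  if (position < 0 || position >= n) stop("position outside sequence")
  if (substr(seq, position + 1L, position + 1L) != "C")
    stop("position ", position, " is not a C")
  b1 <- if (position + 1L < n) substr(seq, position + 2L, position + 2L) else ""
  if (b1 == "") return(NA_character_)
  if (b1 == "G") return("CG")
  if (b1 == "N") return(NA_character_)
  b2 <- if (position + 2L < n) substr(seq, position + 3L, position + 3L) else ""
  if (b2 == "" || b2 == "N") return(NA_character_)
  if (b2 == "G") "CHG" else "CHH"
}

#' mRNA region of a transcript position
#'
#' Under the 0-based half-open CDS convention: positions before `cdsStart`
#' are 5'UTR, positions in `[cdsStart, cdsEnd)` are CDS, and positions at or
#' after `cdsEnd` are 3'UTR. Noncoding classes return "noncoding"; an mRNA
#' without CDS annotation returns `NA` with a warning.
#'
#' @param position 0-based transcript position
#' @param cdsStart,cdsEnd 0-based half-open CDS interval (NA if none)
#' @param rnaClass the transcript's RNA class
#' @return one of `"5UTR"`, `"CDS"`, `"3UTR"`, `"noncoding"`, `NA`
#' @export
regionOf <- function(position, cdsStart, cdsEnd, rnaClass = "mRNA") {
  if (rnaClass != "mRNA") return("noncoding")
  if (is.na(cdsStart) || is.na(cdsEnd)) {
    warning("mRNA without CDS annotation: region undefined")
    return(NA_character_)
  }
  if (position < cdsStart) "5UTR"
  else if (position < cdsEnd) "CDS"
  else "3UTR"
}

#' Distance from a site to the translational start
#'
#' Returns `position - cdsStart + 1`: the A of the AUG start codon is nt 1,
#' so the C of `AUGC` is 4 nt downstream; upstream positions are negative.
#'
#' @param position 0-based transcript position of the site
#' @param cdsStart 0-based CDS start (NA yields NA)
#' @return signed integer distance, or NA
#' @export
distanceToStart <- function(position, cdsStart) {
  d <- position - rep_len(cdsStart, length(position)) + 1L
  d[is.na(rep_len(cdsStart, length(position)))] <- NA_integer_
  d
}

#' Scan transcripts for candidate m5C sites
#'
#' Every cytosine of every transcript is windowed with the model's geometry
#' (flanks N-padded at borders), encoded, scored by the ensemble, and
#' annotated with the confidence modes it passes, its sequence context, mRNA
#' region and distance to the translational start. Transcripts are processed
#' one at a time, so memory is bounded in transcript count.
#'
#' @param model an [M5CEnsemble-class]
#' @param transcripts an `RNAStringSet` from [transcriptModels()] /
#'   [readTranscriptModels()], or a named character vector (treated as
#'   noncoding "other")
#' @return data.frame with one row per cytosine: `transcript_id`, `position`
#'   (0-based), `score`, `VH`/`H`/`N`/`L` logical mode columns, `context`,
#'   `region`, `dist_to_start`
#' @export
scanTranscripts <- function(model, transcripts) {
  stopifnot(is(model, "M5CEnsemble"))
  if (methods::is(transcripts, "XStringSet") &&
      !is.null(S4Vectors::mcols(transcripts)) &&
      "rnaClass" %in% names(S4Vectors::mcols(transcripts))) {
    meta <- as.data.frame(S4Vectors::mcols(transcripts))
    seqs <- asSequenceVector(transcripts)
  } else {
    seqs <- asSequenceVector(transcripts)
    meta <- data.frame(rnaClass = rep("other", length(seqs)),
                       cdsStart = NA_integer_, cdsEnd = NA_integer_)
  }
  if (length(seqs) == 0L) stop("no transcripts to scan")
  geom <- windowGeometry(model)
  th <- thresholds(model)
  out <- vector("list", length(seqs))
  for (t in seq_along(seqs)) {
    seq <- normalizeRNA(seqs[[t]])
    if (nchar(seq) == 0L) {
      warning("empty sequence for transcript ", names(seqs)[t], "; skipped")
      next
    }
    cpos <- which(windowChars(seq) == "C") - 1L  # 0-based
    if (length(cpos) == 0L) next
    wins <- vapply(cpos, function(p)
      extractWindow(seq, p, geom[["upstream"]], geom[["downstream"]]),
      character(1))
    feats <- encodeWindows(wins, cfg = encodingConfigOf(model),
                           center = geom[["upstream"]] + 1L)
    scores <- scoreSamples(model, feats)
    ctx <- vapply(cpos, function(p) {
      v <- classifyContext(seq, p)
      if (is.na(v)) NA_character_ else v
    }, character(1))
    reg <- vapply(cpos, function(p)
      regionOf(p, meta$cdsStart[t], meta$cdsEnd[t], meta$rnaClass[t]),
      character(1))
    out[[t]] <- data.frame(
      transcript_id = names(seqs)[t], position = cpos, score = scores,
      VH = scores > th[["VHmode"]], H = scores > th[["HMode"]],
      N = scores > th[["NMode"]], L = scores > th[["LMode"]],
      context = ctx, region = reg,
      dist_to_start = distanceToStart(cpos, meta$cdsStart[t]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(transcript_id = character(), position = integer(),
                      score = numeric(), VH = logical(), H = logical(),
                      N = logical(), L = logical(), context = character(),
                      region = character(), dist_to_start = integer()))
  rownames(res) <- NULL
  res
}

#' Context proportions of candidate sites versus background
#'
#' Fractions of CG/CHG/CHH over classifiable sites, for the candidate set
#' and for all cytosines of the transcripts (the background); each triple
#' sums to 1.
#'
#' @param annotations data.frame from [scanTranscripts()] (already filtered
#'   to the candidate set of interest, e.g. `annotations[annotations$VH, ]`)
#' @param transcripts the transcript set scanned
#' @return list with numeric triples `candidate` and `background`
#' @export
contextProportions <- function(annotations, transcripts) {
  seqs <- asSequenceVector(transcripts)
  tabulate3 <- function(ctx) {
    ctx <- ctx[!is.na(ctx)]
    if (!length(ctx)) stop("no classifiable sites")
    tab <- table(factor(ctx, levels = c("CG", "CHG", "CHH")))
    as.numeric(tab) / sum(tab)
  }
  cand <- tabulate3(annotations$context)
  bg <- unlist(lapply(seqs, function(s) {
    s <- normalizeRNA(s)
    cpos <- which(windowChars(s) == "C") - 1L
    vapply(cpos, function(p) classifyContext(s, p), character(1))
  }))
  list(candidate = setNames(cand, c("CG", "CHG", "CHH")),
       background = setNames(tabulate3(bg), c("CG", "CHG", "CHH")))
}

#' Metagene profile of sites across 5'UTR, CDS and 3'UTR
#'
#' Maps each site of a coding transcript to its fractional position within
#' its region, aggregates into `binsPerRegion` equal-width bins per region,
#' and reports alongside the background density of all cytosines. Sites in
#' zero-length regions are skipped with a warning.
#'
#' @param annotations data.frame from [scanTranscripts()] (pre-filtered to
#'   the candidate set)
#' @param transcripts transcript set with CDS annotation in `mcols()`
#' @param binsPerRegion bins per region (default 20)
#' @return data.frame `region`, `bin`, `count`, `density`, `bg_count`,
#'   `bg_density`
#' @export
metageneProfile <- function(annotations, transcripts, binsPerRegion = 20L) {
  meta <- as.data.frame(S4Vectors::mcols(transcripts))
  seqs <- asSequenceVector(transcripts)
  meta$id <- names(seqs)
  regions <- c("5UTR", "CDS", "3UTR")

  fracOf <- function(pos, cdsStart, cdsEnd, len) {
    if (pos < cdsStart) {
      if (cdsStart == 0L) return(NULL)
      c("5UTR", (pos + 0.5) / cdsStart)
    } else if (pos < cdsEnd) {
      c("CDS", (pos - cdsStart + 0.5) / (cdsEnd - cdsStart))
    } else {
      if (len == cdsEnd) return(NULL)
      c("3UTR", (pos - cdsEnd + 0.5) / (len - cdsEnd))
    }
  }
  binOf <- function(frac) pmin(binsPerRegion, floor(frac * binsPerRegion) + 1L)

  tally <- function(posList) {
    counts <- matrix(0L, nrow = 3L, ncol = binsPerRegion,
                     dimnames = list(regions, NULL))
    skipped <- 0L
    for (k in seq_len(nrow(posList))) {
      tx <- posList$transcript_id[k]
      i <- match(tx, meta$id)
      if (is.na(i) || is.na(meta$cdsStart[i])) next
      rf <- fracOf(posList$position[k], meta$cdsStart[i], meta$cdsEnd[i],
                   nchar(seqs[[i]]))
      if (is.null(rf)) { skipped <- skipped + 1L; next }
      counts[rf[1], binOf(as.numeric(rf[2]))] <-
        counts[rf[1], binOf(as.numeric(rf[2]))] + 1L
    }
    if (skipped > 0L)
      warning(skipped, " site(s) in zero-length regions skipped")
    counts
  }

  siteCounts <- tally(annotations)
  allC <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    s <- normalizeRNA(seqs[[i]])
    cpos <- which(windowChars(s) == "C") - 1L
    if (!length(cpos)) return(NULL)
    data.frame(transcript_id = names(seqs)[i], position = cpos)
  }))
  bgCounts <- suppressWarnings(tally(allC))

  dens <- function(m) if (sum(m) == 0) m else m / sum(m)
  siteDens <- dens(siteCounts); bgDens <- dens(bgCounts)
  do.call(rbind, lapply(regions, function(r) {
    data.frame(region = r, bin = seq_len(binsPerRegion),
               count = siteCounts[r, ], density = siteDens[r, ],
               bg_count = bgCounts[r, ], bg_density = bgDens[r, ])
  }))
}

#' Count sites falling inside peak intervals
#'
#' Interval-overlap counter for validating predictions against enrichment
#' peaks: peaks are transcript-space intervals (BED: 0-based half-open).
#'
#' @param annotations data.frame with `transcript_id` and 0-based `position`
#' @param peaks `GRanges` (e.g. from [readPeakBED()]) whose seqnames are
#'   transcript IDs
#' @return list `sites_in_peaks` (count of annotation rows inside any peak)
#'   and `peaks_covered` (count of peaks containing at least one site)
#' @export
sitesInPeaks <- function(annotations, peaks) {
  sites <- GenomicRanges::GRanges(
    seqnames = annotations$transcript_id,
    ranges = IRanges::IRanges(start = annotations$position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(sites, peaks)
  list(sites_in_peaks = length(unique(S4Vectors::queryHits(hits))),
       peaks_covered = length(unique(S4Vectors::subjectHits(hits))))
}

#' Read peak intervals from BED
#' @param path BED file path (transcript-space intervals)
#' @return `GRanges`
#' @export
readPeakBED <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Tally candidate sites per RNA class
#'
#' Reporting view over scan output: per RNA class, the number of
#' transcripts, cytosines scanned, methylated cytosines (passing `mode`) and
#' transcripts containing at least one candidate.
#'
#' @param annotations data.frame from [scanTranscripts()]
#' @param transcripts the scanned transcript set
#' @param mode which mode column to count as methylated (default "VH")
#' @return data.frame, one row per RNA class present
#' @export
rnaClassSummary <- function(annotations, transcripts, mode = "VH") {
  meta <- as.data.frame(S4Vectors::mcols(transcripts))
  seqs <- asSequenceVector(transcripts)
  meta$id <- names(seqs)
  called <- annotations[annotations[[mode]], , drop = FALSE]
  do.call(rbind, lapply(split(meta, meta$rnaClass), function(g) {
    ann <- annotations[annotations$transcript_id %in% g$id, , drop = FALSE]
    hit <- called[called$transcript_id %in% g$id, , drop = FALSE]
    data.frame(rna_class = g$rnaClass[1],
               n_transcripts = nrow(g),
               n_cytosines = nrow(ann),
               n_methylated = nrow(hit),
               n_transcripts_with_m5c = length(unique(hit$transcript_id)))
  }))
}

#' Write scan annotations as TSV (1-based positions)
#' @param annotations data.frame from [scanTranscripts()]
#' @param path output TSV path
#' @export
writeAnnotations <- function(annotations, path) {
  out <- annotations
  out$position <- out$position + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
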