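test_that("sequence context classification follows the CG/CHG/CHH definition", {
  expect_equal(classifyContext("ACGA", 1), "CG")
  expect_equal(classifyContext("CAG", 0), "CHG")
  expect_equal(classifyContext("CAU", 0), "CHH")
  expect_equal(classifyContext("CCG", 0), "CHG")
  expect_true(is.na(classifyContext("AC", 1)))    # no downstream base
  expect_equal(classifyContext("CG", 0), "CG")    # one base suffices for CG
  expect_true(is.na(classifyContext("CA", 0)))    # H then nothing
  expect_true(is.na(classifyContext("CNA", 0)))   # N is unclassifiable
  expect_error(classifyContext("ACGU", 0), "not a C")
})

test_that("region assignment respects the half-open CDS convention", {
  expect_equal(regionOf(5, 10, 100), "5UTR")
  expect_equal(regionOf(10, 10, 100), "CDS")
  expect_equal(regionOf(99, 10, 100), "CDS")
  expect_equal(regionOf(100, 10, 100), "3UTR")
  expect_equal(regionOf(50, 10, 100, rnaClass = "tRNA"), "noncoding")
  expect_warning(r <- regionOf(5, NA, NA, rnaClass = "mRNA"), "without CDS")
  expect_true(is.na(r))
})

test_that("distance to start anchors the A of AUG at 1 with no sign flip", {
  expect_equal(distanceToStart(10, 10), 1)   # the A itself
  expect_equal(distanceToStart(13, 10), 4)   # the C of AUGC
  expect_equal(distanceToStart(7, 10), -2)   # 3 nt upstream of the A
  expect_true(is.na(distanceToStart(5, NA)))
  expect_equal(distanceToStart(c(10, 13), 10), c(1, 4))
})

test_that("scanning emits exactly one annotation per cytosine", {
  shared <- sharedSimAndModel()
  model <- shared$model
  # no cytosines -> no annotations
  none <- scanTranscripts(model, c(t0 = "AGUAGUAGUA"))
  expect_equal(nrow(none), 0L)
  # a CCC transcript: three annotations from N-padded windows
  three <- scanTranscripts(model, c(t1 = "CCC"))
  expect_equal(nrow(three), 3L)
  expect_equal(three$position, 0:2)
  # conservation on simulated transcripts
  tx <- shared$sim$transcripts[1:3]
  ann <- scanTranscripts(model, tx)
  nC <- sum(vapply(as.character(tx), function(s)
    sum(strsplit(s, "")[[1]] == "C"), numeric(1)))
  expect_equal(nrow(ann), nC)
  # passed modes are downward-closed: VH implies H implies N implies L
  expect_true(all(!ann$VH | ann$H))
  expect_true(all(!ann$H | ann$N))
  expect_true(all(!ann$N | ann$L))
  expect_warning(scanTranscripts(model, c(bad = "", ok = "ACA")), "empty")
})

test_that("a strongly planted site outscores the rest of its transcript", {
  shared <- sharedSimAndModel()
  truth <- shared$sim$truth
  onePos <- names(which(table(truth$transcript_id) == 1))
  tx <- onePos[1]
  ann <- scanTranscripts(shared$model, shared$sim$transcripts[tx])
  planted <- truth$position[truth$transcript_id == tx][1]
  best <- ann$position[which.max(ann$score)]
  expect_equal(best, planted)
})

test_that("context proportions sum to one for candidates and background", {
  shared <- sharedSimAndModel()
  tx <- shared$sim$transcripts[1:5]
  ann <- scanTranscripts(shared$model, tx)
  props <- contextProportions(ann, tx)
  expect_equal(sum(props$candidate), 1, tolerance = 1e-9)
  expect_equal(sum(props$background), 1, tolerance = 1e-9)
  allCG <- data.frame(context = rep("CG", 5))
  expect_equal(unname(contextProportions(allCG, tx)$candidate), c(1, 0, 0))
  expect_error(contextProportions(data.frame(context = NA_character_), tx),
               "classifiable")
})

test_that("programmed context mix is recovered by the generator round-trip", {
  mix <- c(CG = 0.5, CHG = 0.3, CHH = 0.2)
  sim <- simulateDataset(simConfig(nTranscripts = 80L, nPositives = 1000L,
                                   effectStrength = 0, contextMix = mix,
                                   seed = 31L))
  seqs <- as.character(sim$transcripts)
  names(seqs) <- names(sim$transcripts)
  ctx <- mapply(function(tx, p) classifyContext(seqs[[tx]], p),
                sim$truth$transcript_id, sim$truth$position)
  freq <- table(factor(ctx, levels = names(mix))) / length(ctx)
  # absolute tolerance: nearby planted sites can overwrite forced contexts
  expect_lt(max(abs(as.numeric(freq) - unname(mix))), 0.05)
})

test_that("metagene profile localizes sites and normalizes per region", {
  seqs <- c(tx1 = paste(rep("ACGU", 100), collapse = ""))  # length 400
  # start-codon warning expected: this synthetic sequence has no planted AUG
  suppressWarnings(tm <- transcriptModels(seqs, cdsStart = 100L, cdsEnd = 300L))
  sites <- data.frame(transcript_id = "tx1", position = c(199L, 200L, 201L))
  prof <- suppressWarnings(metageneProfile(sites, tm, binsPerRegion = 10L))
  cdsRows <- prof[prof$region == "CDS", ]
  expect_equal(sum(cdsRows$count), 3L)
  expect_equal(cdsRows$count[cdsRows$bin == 5], 1L)  # position 199 -> bin 5
  expect_equal(cdsRows$count[cdsRows$bin == 6], 2L)  # 200, 201 -> bin 6
  expect_equal(sum(prof$density), 1)
  expect_equal(sum(prof$bg_density), 1)
  # uniform background: all cytosines fall where cytosines are available
  expect_equal(sum(prof$bg_count), 100L)
})

test_that("CDS-enriched placement yields CDS enrichment over the UTRs", {
  shared <- sharedSimAndModel()
  sim <- shared$sim
  meta <- as.data.frame(S4Vectors::mcols(sim$transcripts))
  meta$id <- names(sim$transcripts)
  truth <- sim$truth
  i <- match(truth$transcript_id, meta$id)
  inCDS <- truth$position >= meta$cdsStart[i] & truth$position < meta$cdsEnd[i]
  cdsSites <- truth[inCDS, ]
  skip_if(nrow(cdsSites) < 10, "too few CDS truth sites in this simulation")
  prof <- suppressWarnings(
    metageneProfile(cdsSites, sim$transcripts, binsPerRegion = 5L))
  expect_equal(sum(prof$count[prof$region == "CDS"]), nrow(cdsSites))
  expect_equal(sum(prof$count[prof$region != "CDS"]), 0L)
})

test_that("GFF3 transcript reconstruction splices exons and maps the CDS", {
  gff <- tempfile(fileext = ".gff3")
  # chr1: 60 nt; plus-strand two-exon mRNA and a minus-strand single-exon mRNA
  chr1 <- paste0("AATGCCGTAC", "GGATCCATGA", "CCGTTGACGT", "ACCGGTTAAC",
                 "GGCCATTGCA", "ACGGTTACGG")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tmRNA\t1\t40\t.\t+\t.\tID=txA",
    "chr1\ttest\texon\t1\t10\t.\t+\t.\tParent=txA",
    "chr1\ttest\texon\t21\t40\t.\t+\t.\tParent=txA",
    "chr1\ttest\tCDS\t5\t10\t.\t+\t.\tParent=txA",
    "chr1\ttest\tCDS\t21\t28\t.\t+\t.\tParent=txA",
    "chr1\ttest\tmRNA\t41\t60\t.\t-\t.\tID=txB",
    "chr1\ttest\texon\t41\t60\t.\t-\t.\tParent=txB",
    "chr1\ttest\tCDS\t47\t58\t.\t-\t.\tParent=txB"
  ), gff)
  tms <- suppressWarnings(readTranscriptModels(c(chr1 = chr1), gff))
  expect_equal(length(tms), 2L)
  seqs <- as.character(tms)
  names(seqs) <- names(tms)
  # txA: exon1 (1-10) + exon2 (21-40), T -> U
  expA <- chartr("T", "U", paste0(substr(chr1, 1, 10), substr(chr1, 21, 40)))
  expect_equal(seqs[["txA"]], expA)
  meta <- as.data.frame(S4Vectors::mcols(tms))
  # CDS 5..10 and 21..28 -> transcript 0-based [4, 18)
  expect_equal(meta$cdsStart[1], 4L)
  expect_equal(meta$cdsEnd[1], 18L)
  # txB: reverse complement of genomic 41..60
  expB <- chartr("ACGU", "UGCA",
                 paste(rev(strsplit(chartr("T", "U", substr(chr1, 41, 60)),
                                    "")[[1]]), collapse = ""))
  expect_equal(seqs[["txB"]], expB)
  # genomic 47..58 on minus strand -> transcript 0-based [2, 14)
  expect_equal(meta$cdsStart[2], 2L)
  expect_equal(meta$cdsEnd[2], 14L)
  expect_true(all(meta$rnaClass == "mRNA"))
})

test_that("interval overlap counting matches a direct comparison", {
  ann <- data.frame(transcript_id = c("t1", "t1", "t2", "t3"),
                    position = c(5L, 50L, 10L, 3L))
  peaks <- GenomicRanges::GRanges(
    seqnames = c("t1", "t2"),
    ranges = IRanges::IRanges(start = c(1, 100), end = c(10, 120)))
  res <- sitesInPeaks(ann, peaks)
  expect_equal(res$sites_in_peaks, 1L)   # only t1:5 falls in t1:1-10
  expect_equal(res$peaks_covered, 1L)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("t1\t0\t10", "t2\t5\t20"), bed)
  gr <- readPeakBED(bed)
  expect_equal(length(gr), 2L)
  res2 <- sitesInPeaks(ann, gr)
  expect_equal(res2$sites_in_peaks, 2L)  # t1:5 and t2:10
})

test_that("per-class summaries and annotation export keep 1-based positions", {
  shared <- sharedSimAndModel()
  tx <- shared$sim$transcripts[1:3]
  ann <- scanTranscripts(shared$model, tx)
  summ <- rnaClassSummary(ann, tx, mode = "L")
  expect_equal(sum(summ$n_cytosines), nrow(ann))
  expect_equal(summ$rna_class, "mRNA")
  path <- tempfile(fileext = ".tsv")
  writeAnnotations(ann, path)
  back <- read.delim(path)
  expect_equal(back$position, ann$position + 1L)
})
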