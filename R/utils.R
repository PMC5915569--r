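#' @import methods
#' @importFrom stats p.adjust pbinom quantile rbinom rnbinom runif t.test
#'   wilcox.test setNames predict
#' @importFrom utils read.delim write.table head
#' @importFrom ranger ranger
NULL

RNA_BASES <- c("A", "C", "G", "U")

# Uppercase, DNA->RNA (T->U). Errors on characters outside {A,C,G,U,N}.
normalizeRNA <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(x)))
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,U,T,N}: ",
         paste(head(unique(unlist(strsplit(gsub("[ACGUN]", "", x[bad]), ""))), 5),
               collapse = ", "))
  }
  x
}

# Split a window into a character vector of single bases.
windowChars <- function(window) {
  strsplit(window, "", fixed = TRUE)[[1]]
}

# GC fraction over non-N bases of a window; NA if the window is all N.
gcContent <- function(window) {
  ch <- windowChars(window)
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) return(NA_real_)
  mean(ch %in% c("G", "C"))
}

# Integer seed derived from a base seed and a stream index, kept in 32-bit range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% .Machine$integer.max)
}
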