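## Window encoders: binary, k-mer, PseDNC.
## A window of length L with all three blocks on (defaults) yields
## 4L (binary) + 84 (k-mer, k = 1..3) + 16 + lambda (PseDNC, lambda = 6)
## = 4L + 106 named features, in a fixed, reproducible order.

#' The 16 RNA dinucleotides in lexicographic order (AA, AC, ..., UU)
#' @return character vector of length 16
#' @export
dinucleotides <- function() {
  as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))
}

#' Default dinucleotide physicochemical property table
#'
#' RNA nearest-neighbour thermodynamic parameters (Turner rules; Xia et al.
#' 1998): stacking free energy at 37C (kcal/mol), enthalpy (kcal/mol) and
#' entropy (cal/mol/K). Each dinucleotide takes the value of its Watson-Crick
#' stack, so reverse-complement pairs share values. Values are returned raw;
#' [encodingConfig()] standardizes each property to mean 0, sd 1 across the 16
#' dinucleotides before use in PseDNC.
#'
#' @return numeric matrix, 16 dinucleotide rows by 3 property columns.
#' @export
defaultPropertyTable <- function() {
  dG <- c(AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08, CA = -2.11,
          GU = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  dH <- c(AA = -6.82, AU = -9.38, UA = -7.69, CU = -10.48, CA = -10.44,
          GU = -11.40, GA = -12.44, CG = -10.64, GG = -13.39, GC = -14.88)
  revcomp <- function(d) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  dinucs <- dinucleotides()
  expand <- function(v) {
    out <- setNames(numeric(16), dinucs)
    for (d in dinucs) out[d] <- if (d %in% names(v)) v[d] else v[revcomp(d)]
    out
  }
  g <- expand(dG)
  h <- expand(dH)
  s <- (h - g) / 310.15 * 1000  # dS at 37C implied by dG = dH - T dS
  cbind(dG = g, dH = h, dS = s)
}

#' Read a dinucleotide property table from TSV
#'
#' Expects 16 rows (one per dinucleotide, first column `dinucleotide`, RNA or
#' DNA alphabet) and one named numeric column per property.
#'
#' @param path TSV file path
#' @return numeric matrix suitable for [encodingConfig()]
#' @export
readPropertyTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  dn <- normalizeRNA(tab[[1]])
  if (!setequal(dn, dinucleotides()))
    stop("property table must contain exactly the 16 dinucleotides")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- dn
  m[dinucleotides(), , drop = FALSE]
}

#' Construct an encoding configuration
#'
#' @param kValues k-mer sizes (default `1:3`: 4 + 16 + 64 = 84 features)
#' @param lambda maximal dinucleotide separation for PseDNC pseudo components
#' @param weight PseDNC weight w in (0, 1]
#' @param propertyTable dinucleotide-by-property numeric matrix (raw scale;
#'   standardized here per property across the 16 dinucleotides)
#' @param includeBinary,includeKmer,includePseDNC block switches
#' @return an [EncodingConfig-class]
#' @examples
#' cfg <- encodingConfig()
#' length(featureNames(11L, cfg))  # 4*11 + 106
#' @export
encodingConfig <- function(kValues = 1:3, lambda = 6L, weight = 0.1,
                           propertyTable = defaultPropertyTable(),
                           includeBinary = TRUE, includeKmer = TRUE,
                           includePseDNC = TRUE) {
  std <- apply(propertyTable, 2, function(x) (x - mean(x)) / stats::sd(x))
  rownames(std) <- rownames(propertyTable)
  new("EncodingConfig",
      kValues = as.integer(kValues), lambda = as.integer(lambda),
      weight = as.numeric(weight),
      propertyTable = std[dinucleotides(), , drop = FALSE],
      includeBinary = isTRUE(includeBinary), includeKmer = isTRUE(includeKmer),
      includePseDNC = isTRUE(includePseDNC))
}

kmerNames <- function(kValues) {
  unlist(lapply(kValues, function(k) {
    mers <- Reduce(function(acc, i) as.vector(t(outer(acc, RNA_BASES, paste0))),
                   seq_len(k - 1), RNA_BASES)
    paste0("kmer_", mers)
  }))
}

binaryNames <- function(L, center) {
  offs <- seq_len(L) - center
  as.vector(t(outer(offs, RNA_BASES, function(o, b) paste0("bin_pos", o, "_", b))))
}

#' Feature names of the full encoding for a given window length
#'
#' @param L window length in nt
#' @param cfg an [EncodingConfig-class]
#' @param center 1-based index of the site within the window (default midpoint)
#' @return character vector of feature names in encoding order: binary block
#'   (5' to 3', A/C/G/U within each position), k-mer block (k ascending,
#'   lexicographic), PseDNC block (`psednc_1` .. `psednc_(16+lambda)`).
#' @export
featureNames <- function(L, cfg = encodingConfig(), center = (L + 1L) %/% 2L) {
  nm <- character()
  if (cfg@includeBinary) nm <- c(nm, binaryNames(L, center))
  if (cfg@includeKmer) nm <- c(nm, kmerNames(cfg@kValues))
  if (cfg@includePseDNC) nm <- c(nm, paste0("psednc_", seq_len(16L + cfg@lambda)))
  nm
}

#' Binary (one-hot) encoding of an RNA window
#'
#' Each position contributes four indicators: A (1,0,0,0), C (0,1,0,0),
#' G (0,0,1,0), U (0,0,0,1); the padding symbol N maps to (0,0,0,0).
#'
#' @param window string over {A,C,G,U,N}
#' @param center 1-based index of the site (used only for feature naming,
#'   so that positions are labeled by offset from the central cytosine)
#' @return named numeric vector of length 4·L
#' @export
encodeBinary <- function(window, center = (nchar(window) + 1L) %/% 2L) {
  ch <- windowChars(normalizeRNA(window))
  L <- length(ch)
  m <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, RNA_BASES))
  idx <- match(ch, RNA_BASES)  # N -> NA -> row of zeros
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  setNames(as.vector(t(m)), binaryNames(L, center))
}

#' k-mer frequency encoding of an RNA window
#'
#' For each k, the frequency of every canonical k-mer: count divided by the
#' number of k-length substrings containing no N. With the default k = 1, 2, 3
#' this yields 4 + 16 + 64 = 84 features. If every substring at some k
#' contains an N, that block is all zero.
#'
#' @param window string over {A,C,G,U,N}
#' @param kValues integer k-mer sizes
#' @return named numeric vector (`kmer_A` .. `kmer_UUU` under defaults)
#' @export
encodeKmer <- function(window, kValues = 1:3) {
  window <- normalizeRNA(window)
  L <- nchar(window)
  if (L == 0L) stop("empty window")
  out <- numeric(0)
  for (k in kValues) {
    nm <- kmerNames(k)
    mers <- sub("^kmer_", "", nm)
    block <- setNames(numeric(length(mers)), nm)
    if (L >= k) {
      subs <- substring(window, seq_len(L - k + 1L), k:L)
      subs <- subs[!grepl("N", subs, fixed = TRUE)]
      if (length(subs)) {
        tab <- table(factor(subs, levels = mers))
        block[] <- as.numeric(tab) / length(subs)
      }
    }
    out <- c(out, block)
  }
  out
}

#' Pseudo dinucleotide composition (PseDNC) encoding
#'
#' Type-I pseudo composition over the 16 adjacent dinucleotide frequencies
#' plus lambda pseudo components. Component `u <= 16` is
#' `f_u / (1 + w * sum(theta))`; component `16 + j` is
#' `w * theta_j / (1 + w * sum(theta))`, where `theta_j` is the mean squared
#' difference of the standardized property vectors between dinucleotides
#' `j` positions apart. All features are non-negative and sum to 1.
#' Dinucleotides containing N are skipped in both the frequency and the
#' correlation sums; if no valid adjacent dinucleotide remains the whole
#' vector is zero.
#'
#' @param window string over {A,C,G,U,N}, length >= 2; windows shorter than
#'   `lambda + 2` leave the infeasible pseudo components at zero
#' @param cfg an [EncodingConfig-class]
#' @return named numeric vector of length 16 + lambda
#' @export
encodePseDNC <- function(window, cfg = encodingConfig()) {
  window <- normalizeRNA(window)
  lambda <- cfg@lambda
  L <- nchar(window)
  if (L < 2L)
    stop("window of length ", L, " has no dinucleotides")
  ch <- windowChars(window)
  dn <- paste0(ch[-L], ch[-1])                      # adjacent dinucleotides
  valid <- !grepl("N", dn, fixed = TRUE)
  nm <- paste0("psednc_", seq_len(16L + lambda))
  out <- setNames(numeric(16L + lambda), nm)
  if (!any(valid)) return(out)

  f <- as.numeric(table(factor(dn[valid], levels = dinucleotides())))
  f <- f / sum(f)

  prop <- cfg@propertyTable
  di_idx <- match(dn, rownames(prop))               # NA for N-containing
  theta <- numeric(lambda)
  n_dn <- length(dn)
  for (j in seq_len(lambda)) {
    i <- seq_len(max(0L, n_dn - j))
    ok <- i[valid[i] & valid[i + j]]
    if (length(ok)) {
      d2 <- (prop[di_idx[ok], , drop = FALSE] -
             prop[di_idx[ok + j], , drop = FALSE])^2
      theta[j] <- mean(rowMeans(d2))
    }
  }
  denom <- 1 + cfg@weight * sum(theta)
  out[seq_len(16L)] <- f / denom
  out[16L + seq_len(lambda)] <- cfg@weight * theta / denom
  out
}

#' Encode one window with all configured feature blocks
#'
#' @param window RNA window string
#' @param cfg an [EncodingConfig-class]
#' @param center 1-based site index within the window (naming of the binary
#'   block; default midpoint)
#' @return named numeric vector; with all defaults, length 4·L + 106
#' @export
encodeWindow <- function(window, cfg = encodingConfig(),
                         center = (nchar(window) + 1L) %/% 2L) {
  v <- numeric(0)
  if (cfg@includeBinary) v <- c(v, encodeBinary(window, center = center))
  if (cfg@includeKmer) v <- c(v, encodeKmer(window, kValues = cfg@kValues))
  if (cfg@includePseDNC) v <- c(v, encodePseDNC(window, cfg = cfg))
  v
}

#' Encode a set of equal-length windows into a feature matrix
#'
#' @param windows character vector of RNA windows, all the same length
#' @param cfg an [EncodingConfig-class]
#' @param center 1-based site index within the windows
#' @return numeric matrix, one row per window, named feature columns
#' @export
encodeWindows <- function(windows, cfg = encodingConfig(),
                          center = (nchar(windows[1]) + 1L) %/% 2L) {
  if (length(windows) == 0L) stop("no windows to encode")
  if (length(unique(nchar(windows))) != 1L)
    stop("all windows must have equal length")
  nm <- featureNames(nchar(windows[1]), cfg, center = center)
  m <- matrix(0, nrow = length(windows), ncol = length(nm),
              dimnames = list(NULL, nm))
  for (i in seq_along(windows))
    m[i, ] <- encodeWindow(windows[i], cfg = cfg, center = center)
  m
}

#' Write a feature matrix with labels as TSV
#'
#' Header row of feature names, one sample per row, label column last.
#'
#' @param features numeric matrix with named columns
#' @param labels vector recycled/checked against rows ("pos"/"neg")
#' @param path output TSV path
#' @export
writeFeatureMatrix <- function(features, labels, path) {
  stopifnot(nrow(features) == length(labels))
  df <- as.data.frame(features, check.names = FALSE)
  df$label <- labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
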