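# Independent oracles used for dual-route checks. These deliberately share
# no code with the package: literal loops over the defining formulas.

# Type-I pseudo dinucleotide composition by direct summation.
psedncOracle <- function(window, lambda, w, propRaw) {
  prop <- apply(propRaw, 2, function(x) (x - mean(x)) / sd(x))
  rownames(prop) <- rownames(propRaw)
  ch <- strsplit(window, "")[[1]]
  L <- length(ch)
  dn <- character(0)
  for (i in 1:(L - 1)) dn <- c(dn, paste0(ch[i], ch[i + 1]))
  ok <- !grepl("N", dn)
  dinucs <- rownames(prop)
  f <- numeric(16)
  names(f) <- dinucs
  for (d in dn[ok]) f[d] <- f[d] + 1
  if (sum(f) == 0) return(numeric(16 + lambda))
  f <- f / sum(f)
  bigTheta <- function(a, b) mean((prop[a, ] - prop[b, ])^2)
  theta <- numeric(lambda)
  for (j in 1:lambda) {
    vals <- c()
    for (i in seq_len(max(0, L - 1 - j))) {
      if (ok[i] && ok[i + j]) vals <- c(vals, bigTheta(dn[i], dn[i + j]))
    }
    theta[j] <- if (length(vals)) mean(vals) else 0
  }
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# Mann-Whitney AUC by exhaustive pairwise comparison, ties half-credited.
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
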