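# Small fixtures built in code, shared across test files.

# two-precursor annotation set with explicit arms
tinyAnnotations <- function() {
  hp <- Biostrings::DNAStringSet(c(
    "mir-x" = paste(rep("ACGT", 18), collapse = ""),  # 72 nt
    "mir-y" = paste(rep("GGCA", 18), collapse = "")))
  matures <- data.frame(
    precursor_id = c("mir-x", "mir-x", "mir-y", "mir-y"),
    mature_id = c("miR-x-5p", "miR-x-3p", "miR-y-5p", "miR-y-3p"),
    arm = c("5p", "3p", "5p", "3p"),
    start = c(5, 45, 5, 45), end = c(26, 66, 26, 66),
    stringsAsFactors = FALSE)
  PrecursorAnnotations(hp, matures)
}

# read table: mir-x major at 5 (5p), minor at 45; mir-y mirrored
tinyReads <- function() {
  ReadMappingTable(data.frame(
    precursor_id = rep(c("mir-x", "mir-y"), each = 6),
    start = c(5, 5, 6, 45, 45, 45, 45, 45, 5, 5, 5, 6),
    count = c(100, 80, 3, 10, 8, 2, 200, 150, 20, 15, 1, 2),
    tissue = rep(c("liver", "kidney", "liver", "liver", "kidney", "brain"), 2),
    stringsAsFactors = FALSE),
    tissues = c("liver", "kidney", "brain"))
}

# independent brute-force Fisher two-sided p by full table enumeration
enumFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  pObs <- probs[support == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# brute-force top-decile oracle: sort, slice, expand ties, exclude zeros
bruteTopDecile <- function(scores, fraction = 0.1) {
  k <- ceiling(fraction * length(scores))
  cutoff <- sort(scores, decreasing = TRUE)[k]
  scores >= cutoff & scores > 0
}

# textbook Pearson R (covariance over sd product)
bruteR <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}
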