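# Shared fixtures, built in code.

# 4-position toy model with hand-tabulated weights (offsets -1..+2):
#   -1: A .5  C .25 G .125 T .125  -> w = 1, 0, -1, -1
#    0: uniform                    -> w = 0 everywhere
#   +1: A .125 C .125 G .25 T .5   -> w = -1, -1, 0, 1
#   +2: A .5  C .5  G 0   T 0      -> w = 1, 1, floor, floor
toyFrequencyMatrix <- function() {
  m <- cbind(
    `-1` = c(0.5, 0.25, 0.125, 0.125),
    `0`  = c(0.25, 0.25, 0.25, 0.25),
    `1`  = c(0.125, 0.125, 0.25, 0.5),
    `2`  = c(0.5, 0.5, 0, 0))
  rownames(m) <- c("A", "C", "G", "T")
  m
}

toyModel <- function(floorBits = -20) {
  infoModelFromFrequencies(toyFrequencyMatrix(), -1L, name = "toy",
                           siteKind = "donor", floorBits = floorBits)
}

# independent brute-force scorer: plain dot product per offset, no reuse of
# the package's sliding scan
bruteForceScan <- function(model, sequence) {
  w <- modelWeights(model)
  L <- ncol(w)
  codes <- match(strsplit(sequence, "")[[1]], rownames(w))
  n <- nchar(sequence)
  vapply(seq_len(n - L + 1L), function(s) {
    idx <- codes[s:(s + L - 1L)]
    sum(w[cbind(idx, seq_len(L))])
  }, 0)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random frequency matrix with all entries bounded away from 0
randomFreqMatrix <- function(L, minFreq = 0.02) {
  m <- matrix(stats::runif(4 * L, min = minFreq), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  colnames(m) <- as.character(seq_len(L) - 1L)
  m
}
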