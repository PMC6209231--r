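# Internal helpers shared across modules.

# Coerce to a base integer-ish matrix with gene/sample names, validating
# non-negativity.
asCountMatrix <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  counts
}

# Round half away from zero (documented convention for "percent of genes").
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Fix the sign of each column so its largest-magnitude entry is positive.
signFix <- function(m) {
  if (ncol(m) == 0L) return(m)
  for (j in seq_len(ncol(m))) {
    i <- which.max(abs(m[, j]))
    if (m[i, j] < 0) m[, j] <- -m[, j]
  }
  m
}

# log2(count + 1): the transform feeding all latent-factor estimation and
# linear-model testing. Pseudocount 1 pinned.
logTransform <- function(counts, effectiveSizes = NULL) {
  counts <- asCountMatrix(counts)
  if (!is.null(effectiveSizes)) {
    if (is(effectiveSizes, "ScaleFactors"))
      effectiveSizes <- effectiveSizes@effectiveSizes
    stopifnot(length(effectiveSizes) == ncol(counts))
    counts <- sweep(counts, 2L, effectiveSizes / mean(effectiveSizes), "/")
  }
  log2p1(counts)
}

# Deterministic child-seed derivation: a polynomial hash of the cell key
# string mixed with the master seed and replicate counter, mod 2^31 - 2.
# Keyed by the cell's parameter string (not its grid position), so adding
# scenarios never perturbs existing streams.
childSeed <- function(masterSeed, cellKey, replicate) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(cellKey)) h <- (h * 31 + ch) %% m
  h <- (h + (masterSeed %% m) * 69621) %% m
  h <- (h + replicate * 48271) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Transform counts to log2 scale
#'
#' Applies the pinned `log2(x + 1)` transform, optionally after rescaling
#' columns by effective library sizes (relative to their mean) so the result
#' stays on the raw-count magnitude.
#'
#' @param counts gene-by-sample count matrix or [SimBatchExperiment-class].
#' @param effectiveSizes optional per-sample effective library sizes or a
#'   [ScaleFactors-class].
#' @return numeric matrix of log2-transformed values.
#' @examples
#' logCounts(matrix(0:5, 2))
#' @export
logCounts <- function(counts, effectiveSizes = NULL) {
  logTransform(counts, effectiveSizes)
}
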