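# Library-size scale factors (UQ, TMM, RLE), CPM, and gene-length
# normalizations.

geomMean <- function(x) exp(mean(log(x)))

#' Upper-quartile scale factors
#'
#' After dropping genes with zero counts in every sample, each sample's
#' factor is its 75th percentile of counts divided by the mean 75th
#' percentile across samples; normalized counts are `counts / factor`.
#' Quantiles use linear interpolation between order statistics at position
#' `0.75 * (n - 1) + 1` (R's type-7 default), pinned for reproducibility.
#'
#' @param counts gene-by-sample count matrix.
#' @param nonzeroOnly if `TRUE`, compute each sample's quartile over its own
#'   nonzero counts instead of over genes retained by the global
#'   all-zero-row filter.
#' @return A [ScaleFactors-class] with method `"UQ"`. Effective library
#'   sizes are `factor * mean(libSizes)`.
#' @examples
#' a <- c(10, 20, 30, 40, 100)
#' uqFactors(cbind(A = a, B = 2 * a))
#' @export
uqFactors <- function(counts, nonzeroOnly = FALSE) {
  counts <- asCountMatrix(counts)
  lib <- colSums(counts)
  kept <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no gene has a nonzero count")
  uq <- if (nonzeroOnly) {
    vapply(seq_len(ncol(kept)), function(j) {
      x <- kept[, j][kept[, j] > 0]
      if (length(x) == 0L) 0 else quantile(x, 0.75, names = FALSE, type = 7)
    }, numeric(1))
  } else {
    apply(kept, 2L, quantile, probs = 0.75, names = FALSE, type = 7)
  }
  zero <- uq == 0
  if (any(zero))
    stop("upper quartile is zero for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  f <- uq / mean(uq)
  new("ScaleFactors", method = "UQ", factors = unname(f),
      libSizes = lib, effectiveSizes = unname(f * mean(lib)))
}

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' Weighted mean of doubly trimmed (30% on log-ratios M, 5% on average
#' log-abundance A, two-sided) gene-wise log2 ratios between each sample and
#' a reference, with inverse asymptotic-variance precision weights; computed
#' by `edgeR::calcNormFactors`. Factors are rescaled to geometric mean 1 and
#' multiply raw library sizes to give effective sizes. The default reference
#' is the sample whose 75th percentile of depth-scaled counts is closest to
#' the mean of those percentiles.
#'
#' @param counts gene-by-sample count matrix (>= 2 samples).
#' @param referenceSample optional sample name or index to use as reference.
#' @return A [ScaleFactors-class] with method `"TMM"`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnbinom(400, mu = 50, size = 2), 100)
#' sizeFactors(tmmFactors(m))
#' @export
tmmFactors <- function(counts, referenceSample = NULL) {
  counts <- asCountMatrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  ref <- NULL
  if (!is.null(referenceSample)) {
    ref <- if (is.character(referenceSample))
      match(referenceSample, colnames(counts)) else as.integer(referenceSample)
    if (is.na(ref) || ref < 1L || ref > ncol(counts))
      stop("reference sample not found: ", referenceSample)
  }
  f <- suppressWarnings(
    edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                           logratioTrim = 0.3, sumTrim = 0.05))
  if (any(!is.finite(f) | f <= 0)) {
    warning("too few genes survive the trims; affected factors set to 1")
    f[!is.finite(f) | f <= 0] <- 1
    f <- f / geomMean(f)
  }
  lib <- colSums(counts)
  new("ScaleFactors", method = "TMM", factors = unname(f), libSizes = lib,
      effectiveSizes = unname(lib * f))
}

#' Relative-log-expression (RLE) scale factors
#'
#' Median, across genes positive in every sample, of the ratio of a sample's
#' count to the gene's geometric mean across samples (the median-ratio
#' size factor of the DESeq family). Normalized counts are
#' `counts / factor`.
#'
#' @param counts gene-by-sample count matrix.
#' @return A [ScaleFactors-class] with method `"RLE"`. Effective library
#'   sizes are `factor * geometric mean(libSizes)`.
#' @examples
#' a <- c(10, 20, 30, 40)
#' sizeFactors(rleFactors(cbind(A = a, B = 2 * a)))
#' @export
rleFactors <- function(counts) {
  counts <- asCountMatrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene is positive in all samples; filter low-count genes first")
  k <- counts[pos, , drop = FALSE]
  ref <- apply(k, 1L, geomMean)
  f <- apply(k / ref, 2L, median)
  lib <- colSums(counts)
  new("ScaleFactors", method = "RLE", factors = unname(f), libSizes = lib,
      effectiveSizes = unname(f * geomMean(lib)))
}

#' Counts per million
#'
#' `cpm_gj = x_gj / effectiveLibSize_j * 1e6`, using raw library sizes when
#' no scale factors are supplied.
#'
#' @param counts gene-by-sample count matrix.
#' @param factors optional [ScaleFactors-class] providing effective library
#'   sizes.
#' @return numeric matrix of CPM values.
#' @examples
#' m <- matrix(c(1, 999999), 2, dimnames = list(c("a", "b"), "s1"))
#' cpm(m)  # gene "a": 1 count in a library of 1e6 reads -> CPM 1
#' @export
cpm <- function(counts, factors = NULL) {
  counts <- asCountMatrix(counts)
  eff <- if (is.null(factors)) colSums(counts)
         else {
           stopifnot(is(factors, "ScaleFactors"),
                     length(factors@effectiveSizes) == ncol(counts))
           factors@effectiveSizes
         }
  if (any(eff <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Filter genes on CPM
#'
#' Keeps genes whose CPM exceeds `threshold` in at least `minSamples`
#' samples (defaults 1 and 3, the conventional low-expression filter). The
#' operation is idempotent: effective sizes are fixed by the input matrix
#' and reused, so filtering a filtered matrix changes nothing.
#'
#' @inheritParams cpm
#' @param threshold CPM threshold (default 1).
#' @param minSamples minimum number of samples above threshold (default 3).
#' @return the filtered count matrix.
#' @examples
#' m <- matrix(c(0, 0, 0, 5, 6, 7), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), NULL))
#' rownames(cpmFilter(m, 1, 2))
#' @export
cpmFilter <- function(counts, threshold = 1, minSamples = 3L,
                      factors = NULL) {
  counts <- asCountMatrix(counts)
  keep <- rowSums(cpm(counts, factors) > threshold) >= minSamples
  counts[keep, , drop = FALSE]
}

checkLengths <- function(counts, geneLengths) {
  stopifnot(length(geneLengths) == nrow(counts))
  if (any(!is.finite(geneLengths)) || any(geneLengths <= 0))
    stop("gene lengths must be finite and > 0")
  as.numeric(geneLengths)
}

#' Gene-length normalizations: RPKM/FPKM, TPM and ERPKM
#'
#' `rpkm_gj = x_gj * 1e9 / (lib_j * L_g)`;
#' `tpm_gj = (x_gj / L_g) / sum_g(x_gj / L_g) * 1e6` (columns sum to 1e6);
#' `erpkm` is RPKM with the effective length `L_g - readLength + 1` in place
#' of `L_g`, so `readLength = 1` reproduces RPKM exactly.
#'
#' @param counts gene-by-sample count matrix.
#' @param geneLengths per-gene lengths in base pairs.
#' @param readLength sequencing read length in bp (ERPKM only); must be
#'   smaller than every gene length.
#' @return numeric matrix of normalized values.
#' @examples
#' m <- matrix(c(100, 200), 2, dimnames = list(c("a", "b"), "s1"))
#' tpm(m, c(1000, 2000))
#' @export
rpkm <- function(counts, geneLengths) {
  counts <- asCountMatrix(counts)
  L <- checkLengths(counts, geneLengths)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be > 0")
  sweep(counts / L, 2L, lib, "/") * 1e9
}

#' @rdname rpkm
#' @export
tpm <- function(counts, geneLengths) {
  counts <- asCountMatrix(counts)
  L <- checkLengths(counts, geneLengths)
  r <- counts / L
  sweep(r, 2L, colSums(r), "/") * 1e6
}

#' @rdname rpkm
#' @export
erpkm <- function(counts, geneLengths, readLength) {
  counts <- asCountMatrix(counts)
  L <- checkLengths(counts, geneLengths)
  stopifnot(length(readLength) == 1L, readLength >= 1)
  if (any(readLength >= L))
    stop("readLength must be smaller than every gene length")
  rpkm(counts, L - readLength + 1)
}

#' Scale counts by per-sample factors
#'
#' Applies the method-native normalization: UQ and RLE factors divide raw
#' counts; TMM factors rescale counts to the common effective-depth scale
#' (`x / (libSize * factor) * geometric mean of effective sizes`).
#'
#' @param counts gene-by-sample count matrix.
#' @param factors a [ScaleFactors-class].
#' @return normalized numeric matrix.
#' @examples
#' a <- c(10, 20, 30, 40)
#' m <- cbind(A = a, B = 2 * a)
#' normalizeCounts(m, rleFactors(m))
#' @export
normalizeCounts <- function(counts, factors) {
  counts <- asCountMatrix(counts)
  stopifnot(is(factors, "ScaleFactors"),
            length(factors@factors) == ncol(counts))
  if (factors@method == "TMM") {
    eff <- factors@effectiveSizes
    sweep(counts, 2L, eff / geomMean(eff), "/")
  } else {
    sweep(counts, 2L, factors@factors, "/")
  }
}
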