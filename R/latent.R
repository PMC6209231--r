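# Latent-artifact estimation: residual projection, permutation (BE) and
# asymptotic (Leek) factor counting, two-step surrogate-variable
# construction, variance-threshold PCA, and residual RUV.

designRankCheck <- function(design) {
  design <- as.matrix(design)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    nm <- colnames(design)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(design)))
    bad <- nm[qx$pivot[-seq_len(qx$rank)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qx
}

#' Residuals of log-expression on a known design
#'
#' Per-gene least squares: returns `logExpr - logExpr %*% H`, where `H`
#' projects onto the design's column space (computed from a QR
#' decomposition, so rows are orthogonal to the design to numerical
#' precision).
#'
#' @param logExpr G x N matrix of log-transformed expression.
#' @param design N x p full-column-rank design matrix with p < N.
#' @return A [ResidualMatrix-class].
#' @examples
#' m <- matrix(rnorm(50), 5)
#' r <- residualMatrix(m, matrix(1, 10))
#' max(abs(rowMeans(residValues(r))))
#' @export
residualMatrix <- function(logExpr, design) {
  logExpr <- as.matrix(logExpr)
  design <- as.matrix(design)
  stopifnot(nrow(design) == ncol(logExpr))
  if (ncol(design) >= nrow(design))
    stop("design must have fewer columns than samples")
  qx <- designRankCheck(design)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  vals <- logExpr - (logExpr %*% Q) %*% t(Q)
  new("ResidualMatrix", values = vals, design = design)
}

#' Permutation (parallel-analysis) count of significant latent factors
#'
#' The observed residual spectrum (squared singular values scaled to
#' proportions over the first `min(G, N) - rank(design)` components) is
#' compared against spectra obtained by independently permuting every
#' residual row and re-projecting the design out. Component i receives
#' `p_i = (1 + #\{permuted proportion_i >= observed_i\}) / (1 + B)`, and the
#' estimate k counts the leading components significant at `alpha`,
#' stopping at the first non-significant one.
#'
#' Defaults (20 permutations, alpha 0.10, sequential stopping) follow the
#' reference implementation of this estimator in the sva package. Uses R's
#' RNG, so results are reproducible under `set.seed()`.
#'
#' @param resid a [ResidualMatrix-class].
#' @param nPermutations number of row-permutation null datasets (>= 1).
#' @param alpha per-component significance level.
#' @return integer count of significant components.
#' @examples
#' set.seed(1)
#' r <- residualMatrix(matrix(rnorm(2000), 100), matrix(1, 20))
#' numSVBE(r)
#' @export
numSVBE <- function(resid, nPermutations = 20L, alpha = 0.10) {
  stopifnot(is(resid, "ResidualMatrix"), nPermutations >= 1L,
            alpha > 0, alpha <= 1)
  vals <- resid@values
  qx <- qr(resid@design)
  N <- ncol(vals)
  ndf <- min(nrow(vals), N) - qx$rank
  if (ndf < 1L) return(0L)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  imh <- diag(N) - tcrossprod(Q)
  res <- be_exceed_counts(vals, imh, as.integer(nPermutations),
                          as.integer(ndf))
  pv <- (1 + res$exceed) / (1 + nPermutations)
  sig <- pv <= alpha
  k <- match(FALSE, sig, nomatch = ndf + 1L) - 1L
  as.integer(k)
}

#' Asymptotic (Leek) count of latent factors
#'
#' Interface to the asymptotic conditional-SVD criterion for the number of
#' latent factors when genes greatly outnumber samples, as implemented in
#' `sva::num.sv(method = "leek")`: eigenvalues of the scaled residual
#' cross-product are compared against a data-driven threshold over a
#' subsampling sequence of the gene rows. Deterministic (no RNG). This is
#' the estimator whose occasional large overestimates of k drive the
#' type-I-error inflation the benchmark measures.
#'
#' @param resid a [ResidualMatrix-class]; a warning is issued when
#'   G < 10 * N.
#' @return integer count of latent factors.
#' @examples
#' set.seed(1)
#' r <- residualMatrix(matrix(rnorm(20000), 1000), matrix(1, 20))
#' numSVLeek(r)
#' @export
numSVLeek <- function(resid) {
  stopifnot(is(resid, "ResidualMatrix"))
  vals <- resid@values
  if (nrow(vals) < 10 * ncol(vals))
    warning("Leek criterion assumes G >> N; G < 10 * N here")
  if (all(vals == 0)) return(0L)
  k <- sva::num.sv(vals, resid@design, method = "leek")
  max(0L, as.integer(round(k)))
}

#' Two-step surrogate-variable construction
#'
#' Step 1: SVD of the residuals of `logExpr` on `designPrimary`; the top-k
#' right singular vectors are the eigengenes. Step 2: for each eigengene,
#' every gene's log-expression is regressed on it; genes with BH q <
#' `significanceQ` are selected, the selected (row-centered) sub-matrix is
#' decomposed, and the right singular vector most correlated (absolute
#' Pearson) with the eigengene becomes the surrogate variable. When fewer
#' than `minGenes` genes are selected the step-1 eigengene is kept, with a
#' message. The collected surrogate variables are orthonormalized (QR, in
#' order) and sign-fixed.
#'
#' @param logExpr G x N log-expression matrix.
#' @param designPrimary N x p design of the primary factor(s).
#' @param k number of surrogate variables to construct (>= 1).
#' @param significanceQ BH q-value cutoff for step-2 gene selection.
#' @param minGenes minimum selected genes before falling back to the
#'   eigengene.
#' @return A [LatentEstimate-class] with method `"sva_be"` `k` factors.
#' @examples
#' set.seed(1)
#' r <- matrix(rnorm(2000), 100)
#' estimateSVA(r, matrix(1, 20), k = 1)
#' @export
estimateSVA <- function(logExpr, designPrimary, k, significanceQ = 0.10,
                        minGenes = 25L) {
  stopifnot(k >= 1L)
  logExpr <- as.matrix(logExpr)
  resid <- residualMatrix(logExpr, designPrimary)
  if (all(abs(resid@values) < 1e-12))
    stop("log-expression lies in the design span; no residual variation")
  k <- as.integer(k)
  maxK <- min(dim(logExpr)) - qr(designPrimary)$rank
  if (k > maxK) {
    warning("k = ", k, " exceeds available rank; truncated to ", maxK)
    k <- maxK
  }
  sv <- svd(resid@values, nu = 0, nv = k)
  eig <- sv$v[, seq_len(k), drop = FALSE]
  N <- ncol(logExpr)
  centered <- logExpr - rowMeans(logExpr)
  out <- matrix(0, N, k)
  for (i in seq_len(k)) {
    e <- eig[, i]
    # per-gene simple regression on the eigengene == correlation t-test
    r <- as.vector(centered %*% (e - mean(e))) /
      (sqrt(rowSums(centered^2)) * sqrt(sum((e - mean(e))^2)))
    r[!is.finite(r)] <- 0
    tstat <- r * sqrt((N - 2) / pmax(1 - r^2, 1e-12))
    pv <- 2 * pt(-abs(tstat), N - 2)
    sel <- which(bhAdjust(pv) < significanceQ)
    if (length(sel) < minGenes) {
      message("eigengene ", i, ": only ", length(sel),
              " genes selected; keeping the step-1 eigengene")
      out[, i] <- e
    } else {
      sub <- centered[sel, , drop = FALSE]
      subv <- svd(sub, nu = 0)$v
      cors <- abs(as.vector(cor(subv, e)))
      out[, i] <- subv[, which.max(cors)]
    }
  }
  qf <- qr(out)
  fac <- signFix(qr.Q(qf)[, seq_len(k), drop = FALSE])
  new("LatentEstimate", method = "sva_be", k = k, factors = fac,
      varExplained = numeric(0))
}

#' Variance-threshold PCA estimate of latent factors
#'
#' Gene rows of the residual matrix are centered and scaled to unit variance
#' (zero-variance rows dropped); the spectrum proportions
#' `p_i = d_i^2 / sum(d^2)` are computed, and k counts the leading
#' components with `p_i > varThreshold`. Factors are the corresponding
#' right singular vectors.
#'
#' @param resid a [ResidualMatrix-class].
#' @param varThreshold variance-proportion threshold in (0, 1].
#' @return A [LatentEstimate-class] with method `"pca_threshold"`.
#' @examples
#' set.seed(1)
#' r <- residualMatrix(matrix(rnorm(20000), 1000), matrix(1, 20))
#' nLatent(estimatePCA(r, 0.07))
#' @export
estimatePCA <- function(resid, varThreshold = 0.07) {
  stopifnot(is(resid, "ResidualMatrix"), varThreshold > 0, varThreshold <= 1)
  vals <- resid@values
  sds <- apply(vals, 1L, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all residual rows have zero variance")
  z <- (vals[keep, , drop = FALSE] - rowMeans(vals[keep, , drop = FALSE])) /
    sds[keep]
  sv <- svd(z, nu = 0)
  prop <- sv$d^2 / sum(sv$d^2)
  k <- as.integer(sum(prop > varThreshold))
  fac <- if (k > 0) signFix(sv$v[, seq_len(k), drop = FALSE])
         else matrix(0, ncol(vals), 0)
  new("LatentEstimate", method = "pca_threshold", k = k, factors = fac,
      varExplained = prop[seq_len(k)])
}

#' Residual RUV factors
#'
#' Latent factors taken directly as the first k right singular vectors of
#' the (row-centered) residuals of `logExpr` on the primary design — the
#' variant of remove-unwanted-variation that needs no control genes or
#' samples.
#'
#' @param logExpr G x N log-expression matrix.
#' @param designPrimary primary design matrix.
#' @param k number of factors (>= 1); truncated with a warning when it
#'   exceeds the residual rank.
#' @return A [LatentEstimate-class] with method `"ruv_r"`.
#' @examples
#' set.seed(1)
#' estimateRUVr(matrix(rnorm(2000), 100), matrix(1, 20), k = 2)
#' @export
estimateRUVr <- function(logExpr, designPrimary, k) {
  stopifnot(k >= 1L)
  logExpr <- as.matrix(logExpr)
  resid <- residualMatrix(logExpr, designPrimary)
  k <- as.integer(k)
  maxK <- min(dim(logExpr)) - qr(designPrimary)$rank
  if (k > maxK) {
    warning("k = ", k, " exceeds available rank; truncated to ", maxK)
    k <- maxK
  }
  centered <- resid@values - rowMeans(resid@values)
  sv <- svd(centered, nu = 0)
  prop <- sv$d^2 / sum(sv$d^2)
  fac <- signFix(sv$v[, seq_len(k), drop = FALSE])
  new("LatentEstimate", method = "ruv_r", k = k, factors = fac,
      varExplained = prop[seq_len(k)])
}

#' Export latent factors as tab-separated text
#'
#' Writes the N x k factor matrix with the method and k recorded in a
#' header comment line.
#'
#' @param estimate a [LatentEstimate-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @examples
#' est <- estimateRUVr(matrix(rnorm(200), 20), matrix(1, 10), 1)
#' exportLatent(est, tempfile())
#' @export
exportLatent <- function(estimate, path) {
  stopifnot(is(estimate, "LatentEstimate"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# method=%s k=%d", estimate@method, estimate@k), con)
  if (estimate@k > 0) {
    m <- estimate@factors
    colnames(m) <- paste0("SV", seq_len(ncol(m)))
    write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
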