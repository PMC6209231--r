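# Differential-expression workflows: batch removal, moderated t with an
# empirical variance prior, BH adjustment, and the two-mode workflow runner.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values, clipped at 1 and monotone in the p
#' ranks (via [stats::p.adjust]). Missing entries propagate as missing and
#' are excluded from the ranking.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return vector of BH-adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Remove fitted batch / surrogate-variable effects from log-expression
#'
#' Fits per-gene least squares on the combined design
#' `[designPrimary | designBatch]` and subtracts only the fitted batch / SV
#' contribution; the primary effect and intercept are retained. This is the
#' "post-normalization" adjustment whose consumed degrees of freedom the
#' downstream test does not see.
#'
#' @param logExpr G x N log-expression matrix.
#' @param designPrimary N x p primary design (include the intercept here).
#' @param designBatch N x q matrix of batch covariates and/or estimated
#'   latent factors; may have zero columns, in which case the input is
#'   returned unchanged.
#' @return adjusted G x N matrix.
#' @examples
#' m <- matrix(rnorm(40), 4)
#' b <- matrix(rbinom(10, 1, 0.5))
#' adj <- removeBatch(m, matrix(1, 10), b)
#' @export
removeBatch <- function(logExpr, designPrimary, designBatch) {
  logExpr <- as.matrix(logExpr)
  designPrimary <- as.matrix(designPrimary)
  if (is.null(designBatch) || NCOL(designBatch) == 0L) return(logExpr)
  designBatch <- as.matrix(designBatch)
  X <- cbind(designPrimary, designBatch)
  if (is.null(colnames(X)))
    colnames(X) <- c(paste0("primary", seq_len(ncol(designPrimary))),
                     paste0("batch", seq_len(ncol(designBatch))))
  designRankCheck(X)
  qx <- qr(X)
  beta <- qr.coef(qx, t(logExpr))            # p+q x G
  bIdx <- ncol(designPrimary) + seq_len(ncol(designBatch))
  logExpr - t(designBatch %*% beta[bIdx, , drop = FALSE])
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
trigammaInv <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  pmax(x, 1e-8)
}

#' Moment-matching estimate of the moderated-variance prior
#'
#' Fits the scaled inverse-chi-square prior underlying the moderated
#' t-statistic by matching the mean and spread of log sample variances to
#' their digamma/trigamma expressions under the scaled-F model. Returns
#' `d0 = Inf` when the observed spread does not exceed the chi-square
#' minimum (e.g. all variances equal), and for fewer than 2 genes returns
#' `d0 = Inf` with `s0sq` the mean variance.
#'
#' @param s2 per-gene residual variances (> 0).
#' @param df per-gene residual degrees of freedom (>= 1); recycled if
#'   scalar.
#' @return A [VariancePrior-class].
#' @examples
#' set.seed(1)
#' v <- 2 * 4 / rchisq(500, 4)  # scaled inverse-chi-square, d0 = 4, s0^2 = 2
#' estimateVariancePrior(v, 10)
#' @export
estimateVariancePrior <- function(s2, df) {
  s2 <- as.numeric(s2)
  df <- rep_len(as.numeric(df), length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L)
    return(variancePrior(Inf, if (length(s2)) mean(s2) else 1))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  eVar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(eVar) || eVar <= 0)
    return(variancePrior(Inf, exp(mean(e))))
  d0 <- 2 * trigammaInv(eVar)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  variancePrior(d0, s0sq)
}

#' Moderated t-test for one contrast across all genes
#'
#' Per-gene least squares on a shared design, followed by empirical-Bayes
#' variance shrinkage: the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, the statistic
#' `t = beta / (s_tilde * sqrt(v))` with `v` the unscaled covariance of the
#' contrast coefficient, and the two-sided p-value uses `d0 + d_g` degrees
#' of freedom. A prior with `d0 = 0` gives the ordinary per-gene t; with
#' `d0 = Inf` every gene is tested against the pooled `s0^2`.
#'
#' @param logExpr G x N matrix of (possibly adjusted) log-expression.
#' @param design N x p full-column-rank design matrix.
#' @param contrast column index (or name) of the coefficient to test.
#' @param prior optional [VariancePrior-class]; estimated from the data with
#'   [estimateVariancePrior()] when `NULL`.
#' @return A [S4Vectors::DataFrame-class] with columns `gene_id`,
#'   `estimate`, `t_stat`, `df`, `p_value`, `q_value`; the prior used is in
#'   `metadata()$prior`. Genes with non-positive residual df are flagged
#'   `NA` and excluded from prior estimation.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(200), 20)
#' res <- moderatedTTest(y, cbind(1, rep(0:1, each = 5)), 2)
#' head(res$p_value)
#' @export
moderatedTTest <- function(logExpr, design, contrast, prior = NULL) {
  logExpr <- as.matrix(logExpr)
  design <- as.matrix(design)
  N <- ncol(logExpr)
  stopifnot(nrow(design) == N)
  designRankCheck(design)
  if (is.character(contrast)) {
    nm <- contrast
    contrast <- match(contrast, colnames(design))
    if (is.na(contrast))
      stop("no design column named '", nm, "'")
  }
  stopifnot(length(contrast) == 1L, contrast >= 1, contrast <= ncol(design))
  p <- ncol(design)
  qx <- qr(design)
  beta <- qr.coef(qx, t(logExpr))
  fitted <- design %*% beta
  res <- t(logExpr) - fitted
  dg <- N - p
  v <- solve(crossprod(design))[contrast, contrast]
  if (dg <= 0) stop("saturated design: no residual degrees of freedom")
  s2 <- colSums(res^2) / dg
  usable <- is.finite(s2) & s2 > 0
  if (is.null(prior)) prior <- estimateVariancePrior(s2[usable], dg)
  d0 <- prior@d0; s0 <- prior@s0sq
  sTilde2 <- if (is.infinite(d0)) rep(s0, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0 + dg * s2) / (d0 + dg)
  tstat <- beta[contrast, ] / sqrt(sTilde2 * v)
  dfTot <- d0 + dg
  pv <- 2 * pt(-abs(tstat), dfTot)
  pv[!usable & d0 == 0] <- NA_real_
  gid <- rownames(logExpr)
  if (is.null(gid)) gid <- sprintf("gene%04d", seq_len(nrow(logExpr)))
  out <- S4Vectors::DataFrame(
    gene_id = gid,
    estimate = unname(beta[contrast, ]),
    t_stat = unname(tstat),
    df = rep(dfTot, length(tstat)),
    p_value = unname(pv),
    q_value = bhAdjust(unname(pv)))
  S4Vectors::metadata(out) <- list(prior = prior, residualDf = dg)
  out
}

#' Run the two differential-expression workflow modes on simulated data
#'
#' Log-transforms the counts (raw `log2(x+1)`; size-factor normalization is
#' deliberately not applied to simulated data), estimates latent factors
#' with the chosen method, and tests the primary (biological) factor per
#' gene in one of two modes:
#' \describe{
#'   \item{`"post_normalization"`}{the estimated factors are regressed out
#'     with [removeBatch()] and the test design contains only the primary
#'     factor — the residual df ignore the k factors consumed.}
#'   \item{`"design_matrix"`}{the factors enter the test design alongside
#'     the primary factor, correctly reducing the residual df by k.}
#' }
#'
#' Methods: `"sva_be"` (k from [numSVBE()], factors from [estimateSVA()]),
#' `"sva_leek"` (k from [numSVLeek()], factors from [estimateSVA()]),
#' `"pca"` (k and factors from [estimatePCA()] at `pcaThreshold`),
#' `"ruv_r"` (k from [numSVBE()] — the count estimator feeding residual RUV
#' — factors from [estimateRUVr()]), `"true_covariates"` (the simulated
#' batch covariates themselves; calibration control), `"none"` (no
#' adjustment). When the estimated k is 0 the two modes coincide (logged
#' via a message).
#'
#' @param sim a [SimBatchExperiment-class] whose `colData()` has a `group`
#'   column (scenario with a biological factor).
#' @param method latent-factor method, see above.
#' @param mode `"post_normalization"` or `"design_matrix"`.
#' @param pcaThreshold variance-proportion threshold for `"pca"`.
#' @param moderated use the moderated t (default) or the ordinary t
#'   (`FALSE`, i.e. a zero-weight prior).
#' @param nPermutations,alpha options passed to [numSVBE()].
#' @return list with elements `result` (the [moderatedTTest()] table),
#'   `latent` (a [LatentEstimate-class]), `mode`, and `df` (the residual df
#'   the test used — the df bookkeeping the two modes differ on).
#' @examples
#' set.seed(1)
#' cfg <- scenarioConfig("batch_plus_biology", "binary", nSamples = 20,
#'                       nGenes = 200, pctBatchAffected = 10, pctDE = 5)
#' sim <- simulateCounts(defaultBaseline(200), drawEffects(cfg), "none")
#' w <- runWorkflow3(sim, "ruv_r", "design_matrix")
#' w$df
#' @export
runWorkflow3 <- function(sim,
                         method = c("sva_be", "sva_leek", "pca", "ruv_r",
                                    "true_covariates", "none"),
                         mode = c("post_normalization", "design_matrix"),
                         pcaThreshold = 0.07, moderated = TRUE,
                         nPermutations = 20L, alpha = 0.10) {
  stopifnot(is(sim, "SimBatchExperiment"))
  method <- match.arg(method)
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(sim)
  if (!"group" %in% colnames(cd))
    stop("the dataset has no primary biological factor (colData 'group')")
  group <- as.numeric(cd$group)
  Xprim <- cbind(intercept = 1, group = group)
  y <- logTransform(counts(sim))

  covCols <- intersect(c("batch_binary", "batch_continuous"), colnames(cd))
  batchCov <- as.matrix(as.data.frame(cd[, covCols, drop = FALSE]))
  latent <- estimateLatent(y, Xprim, method, batchCov, pcaThreshold,
                           nPermutations, alpha)
  k <- latent@k
  if (k == 0L && !method %in% "none")
    message("estimated k = 0: the two workflow modes coincide")
  sv <- latent@factors

  if (mode == "post_normalization") {
    adj <- removeBatch(y, Xprim, sv)
    fit <- moderatedTTest(adj, Xprim, "group",
                          prior = if (moderated) NULL else variancePrior(0, 1))
  } else {
    X <- if (k > 0) cbind(Xprim, sv) else Xprim
    colnames(X) <- c(colnames(Xprim),
                     if (k > 0) paste0("SV", seq_len(k)))
    fit <- moderatedTTest(y, X, "group",
                          prior = if (moderated) NULL else variancePrior(0, 1))
  }
  list(result = fit, latent = latent, mode = mode,
       df = S4Vectors::metadata(fit)$residualDf)
}

# Dispatch table for latent-factor estimation inside the workflows.
# `batchCovariates` carries the true simulated batch columns (used only by
# method "true_covariates"); `cache` is an environment shared across methods
# within one dataset so the BE count feeding residual RUV is the same number
# the sva_be method used.
estimateLatent <- function(y, Xprim, method, batchCovariates, pcaThreshold,
                           nPermutations, alpha,
                           cache = new.env(parent = emptyenv())) {
  if (method == "none")
    return(new("LatentEstimate", method = "true_covariates", k = 0L,
               factors = matrix(0, ncol(y), 0), varExplained = numeric(0)))
  if (method == "true_covariates") {
    m <- batchCovariates
    if (is.null(m) || ncol(m) == 0)
      return(new("LatentEstimate", method = "true_covariates", k = 0L,
                 factors = matrix(0, ncol(y), 0),
                 varExplained = numeric(0)))
    qf <- qr(scale(m, scale = FALSE))
    fac <- signFix(qr.Q(qf)[, seq_len(qf$rank), drop = FALSE])
    return(new("LatentEstimate", method = "true_covariates",
               k = ncol(fac), factors = fac, varExplained = numeric(0)))
  }
  resid <- residualMatrix(y, Xprim)
  maxK <- ncol(y) - ncol(Xprim) - 1L   # keep the test design unsaturated
  clampK <- function(k) min(as.integer(k), maxK)
  kBE <- function() {
    if (is.null(cache$kBE))
      cache$kBE <- clampK(numSVBE(resid, nPermutations, alpha))
    cache$kBE
  }
  switch(method,
    sva_be = {
      k <- kBE()
      if (k == 0L) emptyLatent("sva_be", ncol(y))
      else estimateSVA(y, Xprim, k)
    },
    sva_leek = {
      k <- clampK(suppressWarnings(numSVLeek(resid)))
      if (k == 0L) emptyLatent("sva_leek", ncol(y))
      else {
        est <- estimateSVA(y, Xprim, k)
        est@method <- "sva_leek"
        est
      }
    },
    pca = {
      est <- estimatePCA(resid, pcaThreshold)
      if (est@k > maxK) {
        est@factors <- est@factors[, seq_len(maxK), drop = FALSE]
        est@varExplained <- est@varExplained[seq_len(maxK)]
        est@k <- maxK
      }
      est
    },
    ruv_r = {
      k <- kBE()
      if (k == 0L) emptyLatent("ruv_r", ncol(y))
      else estimateRUVr(y, Xprim, k)
    })
}

emptyLatent <- function(method, n) {
  new("LatentEstimate", method = method, k = 0L, factors = matrix(0, n, 0),
      varExplained = numeric(0))
}

#' Export a DE results table as tab-separated text
#'
#' @param result a results [S4Vectors::DataFrame-class] from
#'   [moderatedTTest()] or [nbDETest()].
#' @param path output file.
#' @return invisibly, `path`.
#' @examples
#' res <- moderatedTTest(matrix(rnorm(80), 8),
#'                       cbind(1, rep(0:1, each = 5)), 2)
#' exportDEResult(res, tempfile())
#' @export
exportDEResult <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
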