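# Per-gene NB2 maximum likelihood and a fixed-dispersion NB GLM
# likelihood-ratio test.

#' Per-gene NB2 maximum-likelihood fit
#'
#' @slot mu fitted mean (sample mean for the intercept-only model).
#' @slot phi fitted NB2 dispersion (0 at the Poisson boundary).
#' @slot logLik maximized log-likelihood.
#' @slot converged FALSE only for degenerate inputs (all-zero vectors).
#' @slot nObs number of observations.
#' @aliases NBFit
#' @exportClass NBFit
setClass("NBFit",
  slots = c(mu = "numeric", phi = "numeric", logLik = "numeric",
            converged = "logical", nObs = "integer"))

setMethod("show", "NBFit", function(object) {
  cat("NBFit: mu =", format(object@mu, digits = 5),
      " phi =", format(object@phi, digits = 5),
      " logLik =", format(object@logLik, digits = 6),
      if (!object@converged) " (degenerate)" else "", "\n")
})

# Bounds and tolerance for the 1-D dispersion search (on log phi).
.PHI_LO <- 1e-8
.PHI_HI <- 1e3
.PHI_TOL <- 1e-8

nbLogLik <- function(y, mu, phi) {
  if (phi <= 0) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit the intercept-only NB2 model to one gene
#'
#' The NB2 mean MLE with an intercept-only design is the arithmetic mean;
#' the dispersion is found by bounded 1-D optimization of the profile
#' log-likelihood on log(phi) over [1e-8, 1e3] (tolerance 1e-8), with the
#' Poisson boundary phi = 0 taken whenever it matches or beats the interior
#' optimum (underdispersed data).
#'
#' @param y vector of non-negative integer counts, length >= 2.
#' @return An [NBFit-class]. All-zero input gives a degenerate fit with
#'   `mu` floored at 1e-8 and `converged = FALSE`.
#' @examples
#' fitNB(c(3, 5, 7, 5))
#' @export
fitNB <- function(y) {
  y <- as.numeric(y)
  stopifnot(length(y) >= 2L, all(is.finite(y)), all(y >= 0))
  n <- length(y)
  if (all(y == 0))
    return(new("NBFit", mu = 1e-8, phi = 0, logLik = NA_real_,
               converged = FALSE, nObs = as.integer(n)))
  mu <- mean(y)
  negll <- function(lphi) -nbLogLik(y, mu, exp(lphi))
  opt <- optimize(negll, c(log(.PHI_LO), log(.PHI_HI)), tol = .PHI_TOL)
  llPois <- nbLogLik(y, mu, 0)
  if (llPois >= -opt$objective - 1e-10)
    new("NBFit", mu = mu, phi = 0, logLik = llPois, converged = TRUE,
        nObs = as.integer(n))
  else
    new("NBFit", mu = mu, phi = exp(opt$minimum), logLik = -opt$objective,
        converged = TRUE, nObs = as.integer(n))
}

# Fit an NB GLM (log link) at fixed dispersion, returning log-likelihood,
# coefficients and a convergence flag.
nbGlmFixedPhi <- function(y, X, phi, offsets) {
  fam <- if (phi <= 0) poisson(link = "log")
         else MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam, offset = offsets)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$fitted.values)))
    return(NULL)
  list(logLik = nbLogLik(y, fit$fitted.values, phi), coef = fit$coefficients)
}

#' NB GLM likelihood-ratio test for one gene
#'
#' Profiles the NB2 dispersion under the full design (bounded search on
#' log(phi)), then fits both nested designs at that shared dispersion and
#' compares twice the log-likelihood difference to a chi-square with
#' `ncol(designFull) - ncol(designNull)` degrees of freedom.
#'
#' @param y counts for one gene.
#' @param designFull N x p full design matrix.
#' @param designNull N x q nested null design (columns within the full
#'   design's column space).
#' @param offsets log effective library sizes (default 0).
#' @return A list with `stat`, `df`, `pValue`, `phi`, `coefFull` and
#'   `converged`; `pValue` is `NA` when either fit fails.
#' @examples
#' set.seed(1)
#' g <- rep(0:1, each = 10)
#' y <- rnbinom(20, mu = 50 * 2^g, size = 5)
#' nbGlmLRT(y, cbind(1, g), matrix(1, 20))$pValue
#' @export
nbGlmLRT <- function(y, designFull, designNull, offsets = NULL) {
  y <- as.numeric(y)
  designFull <- as.matrix(designFull); designNull <- as.matrix(designNull)
  N <- length(y)
  stopifnot(nrow(designFull) == N, nrow(designNull) == N)
  if (is.null(offsets)) offsets <- rep(0, N)
  p <- qr(designFull)$rank; q <- qr(designNull)$rank
  # nullity check: null columns must lie in the full column space
  aug <- qr(cbind(designFull, designNull))$rank
  if (aug > p) stop("designNull is not nested within designFull")
  if (p > N) stop("design has more parameters than samples")
  df <- p - q
  if (df == 0L)
    return(list(stat = 0, df = 0L, pValue = 1, phi = NA_real_,
                coefFull = NULL, converged = TRUE))
  prof <- function(lphi) {
    f <- nbGlmFixedPhi(y, designFull, exp(lphi), offsets)
    if (is.null(f)) 1e30 else -f$logLik
  }
  opt <- optimize(prof, c(log(.PHI_LO), log(.PHI_HI)), tol = .PHI_TOL)
  phi <- exp(opt$minimum)
  fullPois <- nbGlmFixedPhi(y, designFull, 0, offsets)
  if (!is.null(fullPois) && fullPois$logLik >= -opt$objective - 1e-10)
    phi <- 0
  full <- nbGlmFixedPhi(y, designFull, phi, offsets)
  null <- nbGlmFixedPhi(y, designNull, phi, offsets)
  if (is.null(full) || is.null(null))
    return(list(stat = NA_real_, df = df, pValue = NA_real_, phi = phi,
                coefFull = NULL, converged = FALSE))
  stat <- max(0, 2 * (full$logLik - null$logLik))
  list(stat = stat, df = df, pValue = pchisq(stat, df, lower.tail = FALSE),
       phi = phi, coefFull = full$coef, converged = TRUE)
}

#' Count-scale differential expression across a matrix
#'
#' Applies [nbGlmLRT()] gene by gene and collects a results table with
#' BH-adjusted p-values. Non-converged genes get missing p-values and are
#' counted in a message.
#'
#' @param counts gene-by-sample count matrix.
#' @param designFull,designNull nested design matrices.
#' @param offsets optional log effective library sizes.
#' @return A [S4Vectors::DataFrame-class] with columns `gene_id`,
#'   `estimate` (first non-shared full-design coefficient), `stat`, `df`,
#'   `p_value`, `q_value`.
#' @examples
#' set.seed(1)
#' g <- rep(0:1, each = 5)
#' m <- matrix(rnbinom(100, mu = 20, size = 5), 10)
#' res <- nbDETest(m, cbind(1, g), matrix(1, 10))
#' head(res$p_value)
#' @export
nbDETest <- function(counts, designFull, designNull, offsets = NULL) {
  counts <- asCountMatrix(counts)
  res <- apply(counts, 1L, nbGlmLRT, designFull = designFull,
               designNull = designNull, offsets = offsets,
               simplify = FALSE)
  nFail <- sum(!vapply(res, `[[`, logical(1), "converged"))
  if (nFail > 0) message(nFail, " gene(s) failed to converge")
  est <- vapply(res, function(r) {
    if (is.null(r$coefFull)) NA_real_ else r$coefFull[ncol(designNull) + 1L]
  }, numeric(1))
  p <- vapply(res, `[[`, numeric(1), "pValue")
  S4Vectors::DataFrame(
    gene_id = rownames(counts),
    estimate = est,
    stat = vapply(res, `[[`, numeric(1), "stat"),
    df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
    p_value = p,
    q_value = bhAdjust(p))
}
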