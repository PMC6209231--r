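#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom rnbinom qnbinom rpois
#'   qpois optimize pchisq pt pf var cor sd setNames dnbinom dpois coef
#'   p.adjust glm.fit poisson rchisq
#' @importFrom utils read.delim write.table modifyList
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib svbench, .registration = TRUE
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Per-gene negative binomial baseline parameters
#'
#' Holds the generative ("null") parameters of the simulator: for each gene a
#' mean \eqn{\mu_g > 0} and an NB2 dispersion \eqn{\phi_g \ge 0}, so that a
#' baseline count has mean \eqn{\mu_g} and variance
#' \eqn{\mu_g + \phi_g \mu_g^2}.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot mu numeric vector of per-gene expected counts, all positive.
#' @slot phi numeric vector of per-gene dispersions, all non-negative.
#' @aliases NBParams
#' @seealso [nbParams()], [defaultBaseline()], [fitBaseline()]
#' @exportClass NBParams
setClass("NBParams",
  slots = c(geneIds = "character", mu = "numeric", phi = "numeric"))

setValidity("NBParams", function(object) {
  msg <- NULL
  if (length(object@geneIds) != length(object@mu) ||
      length(object@mu) != length(object@phi))
    msg <- c(msg, "geneIds, mu and phi must have equal length")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene identifiers must be unique")
  if (!all(is.finite(object@mu)) || any(object@mu <= 0))
    msg <- c(msg, "all mu must be finite and > 0")
  if (!all(is.finite(object@phi)) || any(object@phi < 0))
    msg <- c(msg, "all phi must be finite and >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct an [NBParams-class] object
#'
#' @param geneIds character vector of gene identifiers.
#' @param mu per-gene positive means.
#' @param phi per-gene non-negative NB2 dispersions.
#' @return An [NBParams-class] object.
#' @examples
#' nbParams(paste0("g", 1:3), mu = c(10, 50, 200), phi = c(0.1, 0.2, 0.4))
#' @export
nbParams <- function(geneIds, mu, phi) {
  new("NBParams", geneIds = as.character(geneIds), mu = as.numeric(mu),
      phi = as.numeric(phi))
}

#' Simulation scenario configuration
#'
#' Describes one cell of the simulation design: which latent variables are
#' planted (binary batch, continuous batch, and optionally a binary
#' biological factor), the sample and gene counts, the percentage of genes
#' each variable touches, and the effect-size standard deviations.
#'
#' Two scenarios are supported: `"batch_only"` (batch variables only, no
#' biological signal) and `"batch_plus_biology"` (batch variables plus a
#' binary biological factor whose sample labels are drawn independently of
#' the batch covariates).
#'
#' @slot scenario `"batch_only"` or `"batch_plus_biology"`.
#' @slot batchKinds subset of `c("binary", "continuous")`.
#' @slot nSamples number of samples N (>= 4).
#' @slot nGenes number of genes G (>= 2).
#' @slot pctBatchAffected percent of genes affected per batch variable.
#' @slot pctDE percent of genes affected by the biological factor (must be 0
#'   under `"batch_only"`).
#' @slot sigmaBinaryBatch sd of gene loadings for the binary batch (default 2).
#' @slot sigmaContinuousBatch sd of loadings for the continuous batch
#'   (default 6).
#' @slot sigmaBiology sd of loadings for the biological factor (default 2).
#' @slot bernoulliP success probability for binary covariates (default 0.5).
#' @slot nReplicates replicate datasets to generate in benchmark runs.
#' @slot seed integer seed (may be NA when seeding is handled externally).
#' @aliases ScenarioConfig
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  slots = c(scenario = "character", batchKinds = "character",
            nSamples = "integer", nGenes = "integer",
            pctBatchAffected = "numeric", pctDE = "numeric",
            sigmaBinaryBatch = "numeric", sigmaContinuousBatch = "numeric",
            sigmaBiology = "numeric", bernoulliP = "numeric",
            nReplicates = "integer", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- NULL
  if (!object@scenario %in% c("batch_only", "batch_plus_biology"))
    msg <- c(msg, "scenario must be 'batch_only' or 'batch_plus_biology'")
  if (length(object@batchKinds) < 1 ||
      !all(object@batchKinds %in% c("binary", "continuous")))
    msg <- c(msg, "batchKinds must be a non-empty subset of {binary, continuous}")
  if (anyDuplicated(object@batchKinds))
    msg <- c(msg, "batchKinds must not repeat")
  if (object@nSamples < 4L) msg <- c(msg, "nSamples must be >= 4")
  if (object@nGenes < 2L) msg <- c(msg, "nGenes must be >= 2")
  pcts <- c(object@pctBatchAffected, object@pctDE)
  if (any(!is.finite(pcts)) || any(pcts < 0) || any(pcts > 100))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (object@scenario == "batch_only" && object@pctDE != 0)
    msg <- c(msg, "scenario 'batch_only' forces pctDE = 0")
  if (object@bernoulliP <= 0 || object@bernoulliP >= 1)
    msg <- c(msg, "bernoulliP must lie in (0, 1)")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a [ScenarioConfig-class]
#'
#' @param scenario `"batch_only"` or `"batch_plus_biology"`.
#' @param batchKinds character subset of `c("binary", "continuous")`.
#' @param nSamples,nGenes dataset dimensions.
#' @param pctBatchAffected,pctDE percentages of affected genes.
#' @param sigmaBinaryBatch,sigmaContinuousBatch,sigmaBiology loading sds.
#' @param bernoulliP success probability for binary covariates.
#' @param nReplicates number of replicate datasets for benchmark runs.
#' @param seed optional integer seed.
#' @return A [ScenarioConfig-class] object.
#' @examples
#' scenarioConfig("batch_only", batchKinds = "binary", nSamples = 20,
#'                pctBatchAffected = 10)
#' @export
scenarioConfig <- function(scenario = c("batch_only", "batch_plus_biology"),
                           batchKinds = "binary",
                           nSamples = 50L, nGenes = 1000L,
                           pctBatchAffected = 10, pctDE = 0,
                           sigmaBinaryBatch = 2, sigmaContinuousBatch = 6,
                           sigmaBiology = 2, bernoulliP = 0.5,
                           nReplicates = 1L, seed = NA_integer_) {
  new("ScenarioConfig", scenario = match.arg(scenario),
      batchKinds = batchKinds, nSamples = as.integer(nSamples),
      nGenes = as.integer(nGenes),
      pctBatchAffected = as.numeric(pctBatchAffected),
      pctDE = as.numeric(pctDE),
      sigmaBinaryBatch = as.numeric(sigmaBinaryBatch),
      sigmaContinuousBatch = as.numeric(sigmaContinuousBatch),
      sigmaBiology = as.numeric(sigmaBiology),
      bernoulliP = as.numeric(bernoulliP),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Simulated sample covariates and gene loadings
#'
#' One column per planted variable: sample-level covariates
#' \eqn{\gamma_{nj}} (binary in \{0,1\} or continuous in [0,1]) and
#' gene-level loadings \eqn{\omega_{gj}} that are exactly zero outside the
#' affected-gene mask. A gene's mean is shifted multiplicatively by
#' \eqn{\exp(\sum_j \omega_{gj}\gamma_{nj})}.
#'
#' @slot gamma N x J numeric matrix of sample covariates.
#' @slot omega G x J numeric matrix of gene loadings.
#' @slot kind length-J character, each `"binary_batch"`, `"continuous_batch"`
#'   or `"biology"`.
#' @slot sigma length-J numeric, the loading sd used per column.
#' @slot affected G x J logical mask of affected genes.
#' @aliases EffectSpec
#' @exportClass EffectSpec
setClass("EffectSpec",
  slots = c(gamma = "matrix", omega = "matrix", kind = "character",
            sigma = "numeric", affected = "matrix"))

setValidity("EffectSpec", function(object) {
  msg <- NULL
  J <- ncol(object@gamma)
  if (ncol(object@omega) != J || length(object@kind) != J ||
      length(object@sigma) != J || ncol(object@affected) != J)
    msg <- c(msg, "gamma, omega, kind, sigma and affected must agree on J")
  if (nrow(object@omega) != nrow(object@affected))
    msg <- c(msg, "omega and affected must agree on G")
  if (!all(object@kind %in% c("binary_batch", "continuous_batch", "biology")))
    msg <- c(msg, "unknown column kind")
  if (any(object@omega[!object@affected] != 0))
    msg <- c(msg, "omega must be zero outside the affected mask")
  for (j in seq_len(J)) {
    g <- object@gamma[, j]
    if (object@kind[j] %in% c("binary_batch", "biology")) {
      if (!all(g %in% c(0, 1)))
        msg <- c(msg, sprintf("binary column %d of gamma must be in {0,1}", j))
    } else if (any(g < 0 | g > 1)) {
      msg <- c(msg, sprintf("continuous column %d of gamma must lie in [0,1]", j))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulated batch-affected count experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding the simulated
#' counts (assay `"counts"`) and, when a baseline mode other than `"none"` is
#' requested, the batch-free baseline counts (assay `"baseline"`): the same
#' genes drawn with every batch loading zeroed, biological effects retained.
#' Per-gene truth labels (`"null"`, `"batch_affected"`, `"de"`, `"both"`)
#' live in `rowData()$truth`; the sample covariates are columns of
#' `colData()`; the full [EffectSpec-class] sits in `metadata()$effects`.
#'
#' @aliases SimBatchExperiment
#' @seealso [simulateCounts()], [baselineCounts()], [truthLabels()]
#' @exportClass SimBatchExperiment
setClass("SimBatchExperiment",
  contains = "SummarizedExperiment")

setValidity("SimBatchExperiment", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!"counts" %in% an) msg <- c(msg, "assay 'counts' is required")
  if (!"truth" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'truth' is required")
  if (!is(S4Vectors::metadata(object)$effects, "EffectSpec"))
    msg <- c(msg, "metadata()$effects must be an EffectSpec")
  if (is.null(msg)) TRUE else msg
})

#' Per-sample library-size scale factors
#'
#' @slot method `"UQ"`, `"TMM"` or `"RLE"`.
#' @slot factors per-sample positive scale factors in method-native units:
#'   UQ and RLE factors divide raw counts; TMM factors multiply raw library
#'   sizes (geometric mean 1).
#' @slot libSizes raw per-sample library sizes (column sums).
#' @slot effectiveSizes per-sample effective library sizes used by [cpm()].
#' @aliases ScaleFactors
#' @exportClass ScaleFactors
setClass("ScaleFactors",
  slots = c(method = "character", factors = "numeric", libSizes = "numeric",
            effectiveSizes = "numeric"))

setValidity("ScaleFactors", function(object) {
  msg <- NULL
  if (!object@method %in% c("UQ", "TMM", "RLE"))
    msg <- c(msg, "method must be UQ, TMM or RLE")
  n <- length(object@factors)
  if (length(object@libSizes) != n || length(object@effectiveSizes) != n)
    msg <- c(msg, "factors, libSizes and effectiveSizes must have equal length")
  if (!all(is.finite(object@factors)) || any(object@factors <= 0))
    msg <- c(msg, "all factors must be finite and > 0")
  if (!all(is.finite(object@effectiveSizes)) || any(object@effectiveSizes <= 0))
    msg <- c(msg, "all effective sizes must be finite and > 0")
  if (is.null(msg)) TRUE else msg
})

#' Residuals of log-expression on a known design
#'
#' Per-gene least-squares residuals after projecting the design's column
#' space out of every gene row; each row is orthogonal to every design
#' column.
#'
#' @slot values G x N residual matrix.
#' @slot design the N x p design whose column space was removed.
#' @aliases ResidualMatrix
#' @seealso [residualMatrix()]
#' @exportClass ResidualMatrix
setClass("ResidualMatrix",
  slots = c(values = "matrix", design = "matrix"))

setValidity("ResidualMatrix", function(object) {
  if (nrow(object@design) != ncol(object@values))
    return("design rows must equal residual columns (samples)")
  TRUE
})

#' Estimated latent artifacts
#'
#' The estimated number of latent factors and the N x k factor matrix
#' (orthonormal columns, sign-fixed so the largest-magnitude entry of each
#' column is positive).
#'
#' @slot method one of `"sva_be"`, `"sva_leek"`, `"pca_threshold"`, `"ruv_r"`.
#' @slot k non-negative integer count of latent factors.
#' @slot factors N x k numeric matrix (0 columns when k = 0).
#' @slot varExplained per-factor variance proportions when defined,
#'   otherwise length 0.
#' @aliases LatentEstimate
#' @exportClass LatentEstimate
setClass("LatentEstimate",
  slots = c(method = "character", k = "integer", factors = "matrix",
            varExplained = "numeric"))

setValidity("LatentEstimate", function(object) {
  msg <- NULL
  if (!object@method %in% c("sva_be", "sva_leek", "pca_threshold", "ruv_r",
                            "true_covariates"))
    msg <- c(msg, "unknown latent method")
  if (object@k < 0L) msg <- c(msg, "k must be >= 0")
  if (ncol(object@factors) != object@k)
    msg <- c(msg, "factors must have k columns")
  if (object@k > 1L) {
    cp <- crossprod(object@factors)
    if (max(abs(cp - diag(object@k))) > 1e-6)
      msg <- c(msg, "factor columns must be orthonormal")
  }
  if (is.null(msg)) TRUE else msg
})

#' Moderated-variance prior
#'
#' Scaled inverse-chi-square prior on per-gene residual variances, with
#' prior degrees of freedom `d0` (possibly `Inf`) and prior variance `s0sq`.
#'
#' @slot d0 prior degrees of freedom, >= 0 or Inf.
#' @slot s0sq prior variance, > 0 whenever d0 > 0.
#' @aliases VariancePrior
#' @seealso [estimateVariancePrior()], [moderatedTTest()]
#' @exportClass VariancePrior
setClass("VariancePrior", slots = c(d0 = "numeric", s0sq = "numeric"))

setValidity("VariancePrior", function(object) {
  msg <- NULL
  if (length(object@d0) != 1L || length(object@s0sq) != 1L)
    msg <- c(msg, "d0 and s0sq must be scalars")
  if (is.na(object@d0) || object@d0 < 0) msg <- c(msg, "d0 must be >= 0")
  if (object@d0 > 0 && (!is.finite(object@s0sq) || object@s0sq <= 0))
    msg <- c(msg, "s0sq must be > 0 when d0 > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a [VariancePrior-class]
#' @param d0 prior degrees of freedom (may be `Inf`; `0` disables moderation).
#' @param s0sq prior variance.
#' @return A [VariancePrior-class].
#' @examples variancePrior(4, 0.5)
#' @export
variancePrior <- function(d0, s0sq) new("VariancePrior", d0 = d0, s0sq = s0sq)

#' Benchmark configuration
#'
#' A grid of simulation scenarios crossed with latent-factor methods and
#' testing modes, plus replicate count and master seed. Kind labels
#' `"binary"`, `"continuous"` and `"both"` expand to the corresponding
#' `batchKinds` of each [ScenarioConfig-class] cell.
#'
#' @slot scenario `"batch_only"` or `"batch_plus_biology"`.
#' @slot batchKinds character vector from `c("binary","continuous","both")`.
#' @slot nSamples integer vector of sample sizes.
#' @slot nGenes single gene count.
#' @slot pctBatchAffected numeric vector of percentages.
#' @slot pctDE numeric vector of percentages.
#' @slot methods character vector of latent methods (see [runWorkflow3()]).
#' @slot modes subset of `c("post_normalization","design_matrix")`.
#' @slot pcaThreshold variance proportion threshold for the PCA method.
#' @slot nReplicates replicates per grid cell.
#' @slot masterSeed master seed; per-replicate seeds derive from it.
#' @slot outDir output directory or NA.
#' @aliases BenchmarkConfig
#' @exportClass BenchmarkConfig
setClass("BenchmarkConfig",
  slots = c(scenario = "character", batchKinds = "character",
            nSamples = "integer", nGenes = "integer",
            pctBatchAffected = "numeric", pctDE = "numeric",
            methods = "character", modes = "character",
            pcaThreshold = "numeric", nReplicates = "integer",
            masterSeed = "integer", outDir = "character"))

setValidity("BenchmarkConfig", function(object) {
  msg <- NULL
  if (!all(object@batchKinds %in% c("binary", "continuous", "both")))
    msg <- c(msg, "batchKinds entries must be binary, continuous or both")
  if (length(object@nSamples) < 1 || length(object@pctBatchAffected) < 1)
    msg <- c(msg, "grid must be non-empty")
  if (length(object@methods) < 1) msg <- c(msg, "at least one method required")
  if (!all(object@modes %in% c("post_normalization", "design_matrix")))
    msg <- c(msg, "unknown mode")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (is.null(msg)) TRUE else msg
})
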