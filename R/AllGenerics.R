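#' @importFrom BiocGenerics counts
NULL

#' Accessors for svbench classes
#'
#' `geneMeans()` and `geneDispersions()` extract the per-gene NB parameters;
#' `baselineCounts()` the batch-free assay of a simulated experiment;
#' `truthLabels()` the per-gene truth labels; `effectSpec()` the planted
#' covariates and loadings; `sizeFactors()`/`effectiveLibSizes()` the scale
#' factors; `nLatent()`, `latentFactors()` and `varianceExplained()` the
#' pieces of a [LatentEstimate-class]; `residValues()` and `residDesign()`
#' the pieces of a [ResidualMatrix-class].
#'
#' @param object an svbench S4 object.
#' @return The slot contents named by each accessor.
#' @examples
#' b <- defaultBaseline(10)
#' geneMeans(b)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneMeans", function(object) standardGeneric("geneMeans"))
#' @rdname accessors
#' @export
setGeneric("geneDispersions",
           function(object) standardGeneric("geneDispersions"))
#' @rdname accessors
#' @export
setGeneric("baselineCounts",
           function(object) standardGeneric("baselineCounts"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("effectSpec", function(object) standardGeneric("effectSpec"))
#' @rdname accessors
#' @export
setGeneric("effectiveLibSizes",
           function(object) standardGeneric("effectiveLibSizes"))
#' @rdname accessors
#' @export
setGeneric("nLatent", function(object) standardGeneric("nLatent"))
#' @rdname accessors
#' @export
setGeneric("latentFactors", function(object) standardGeneric("latentFactors"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setGeneric("residValues", function(object) standardGeneric("residValues"))
#' @rdname accessors
#' @export
setGeneric("residDesign", function(object) standardGeneric("residDesign"))

#' @rdname accessors
#' @export
setMethod("geneMeans", "NBParams", function(object) {
  setNames(object@mu, object@geneIds)
})

#' @rdname accessors
#' @export
setMethod("geneDispersions", "NBParams", function(object) {
  setNames(object@phi, object@geneIds)
})

#' Number of genes in an NBParams object
#' @param x an [NBParams-class].
#' @return integer gene count.
#' @export
setMethod("length", "NBParams", function(x) length(x@mu))

#' @describeIn accessors counts assay of a simulated experiment.
#' @export
setMethod("counts", "SimBatchExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname accessors
#' @export
setMethod("baselineCounts", "SimBatchExperiment", function(object) {
  if (!"baseline" %in% SummarizedExperiment::assayNames(object))
    stop("no baseline assay: the dataset was simulated with baseline = \"none\"")
  SummarizedExperiment::assay(object, "baseline")
})

#' @rdname accessors
#' @export
setMethod("truthLabels", "SimBatchExperiment", function(object) {
  setNames(as.character(SummarizedExperiment::rowData(object)$truth),
           rownames(object))
})

#' @rdname accessors
#' @export
setMethod("effectSpec", "SimBatchExperiment", function(object) {
  S4Vectors::metadata(object)$effects
})

#' @rdname accessors
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "ScaleFactors", function(object) {
  setNames(object@factors, names(object@libSizes))
})

#' @rdname accessors
#' @export
setMethod("effectiveLibSizes", "ScaleFactors", function(object) {
  setNames(object@effectiveSizes, names(object@libSizes))
})

#' @rdname accessors
#' @export
setMethod("nLatent", "LatentEstimate", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("latentFactors", "LatentEstimate", function(object) object@factors)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "LatentEstimate",
          function(object) object@varExplained)

#' @rdname accessors
#' @export
setMethod("residValues", "ResidualMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("residDesign", "ResidualMatrix", function(object) object@design)

setMethod("show", "NBParams", function(object) {
  cat("NBParams with", length(object@mu), "genes\n")
  cat("  mu  range:", format(range(object@mu), digits = 4), "\n")
  cat("  phi range:", format(range(object@phi), digits = 4), "\n")
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:", object@scenario, "\n")
  cat("  batch kinds:", paste(object@batchKinds, collapse = ", "), "\n")
  cat("  N =", object@nSamples, " G =", object@nGenes, "\n")
  cat("  % batch-affected =", object@pctBatchAffected,
      " % DE =", object@pctDE, "\n")
})

setMethod("show", "EffectSpec", function(object) {
  cat("EffectSpec with", ncol(object@gamma), "variable(s):",
      paste(object@kind, collapse = ", "), "\n")
  cat("  affected genes per column:",
      paste(colSums(object@affected), collapse = ", "), "\n")
})

setMethod("show", "ScaleFactors", function(object) {
  cat(object@method, "scale factors for", length(object@factors),
      "samples\n")
  cat("  factors:", format(object@factors, digits = 4), "\n")
})

setMethod("show", "LatentEstimate", function(object) {
  cat("LatentEstimate (", object@method, "): k =", object@k, "\n")
  if (length(object@varExplained))
    cat("  variance explained:",
        format(object@varExplained, digits = 3), "\n")
})

setMethod("show", "VariancePrior", function(object) {
  cat("VariancePrior: d0 =", object@d0, ", s0^2 =",
      format(object@s0sq, digits = 5), "\n")
})

setMethod("show", "ResidualMatrix", function(object) {
  cat("ResidualMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples; design rank",
      qr(object@design)$rank, "\n")
})
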