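# Plain-text I/O: gene-by-sample matrices (TSV and MatrixMarket), covariate
# tables, and benchmark configuration files (YAML / JSON).

#' Read / write gene-by-sample count matrices
#'
#' TSV layout: header row of sample identifiers, first column `gene_id`.
#' MatrixMarket files carry the numeric matrix; companion `*.rownames` /
#' `*.colnames` single-column text files carry identifiers when written by
#' [writeCountsMM()]. Integer matrices round-trip exactly.
#'
#' @param path file path.
#' @param counts matrix to write.
#' @return matrices for readers; invisibly `path` for writers.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
#' writeCountsTSV(m, f)
#' all(readCountsTSV(f) == m)
#' @export
readCountsTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.delim(path, check.names = FALSE),
                 error = function(e) stop("malformed TSV ", path, ": ",
                                          conditionMessage(e)))
  if (ncol(df) < 2L || colnames(df)[1L] != "gene_id")
    stop("line 1: expected a 'gene_id' first column in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1L, drop = FALSE], 1L,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("line ", bad[1L] + 1L, ": non-numeric count in ", path)
  }
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  m
}

#' @rdname readCountsTSV
#' @export
writeCountsTSV <- function(counts, path) {
  counts <- asCountMatrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readCountsTSV
#' @export
readCountsMM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(Matrix::readMM(path))
  rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
  rownames(m) <- if (file.exists(rn)) readLines(rn)
                 else sprintf("gene%04d", seq_len(nrow(m)))
  colnames(m) <- if (file.exists(cn)) readLines(cn)
                 else sprintf("sample%03d", seq_len(ncol(m)))
  m
}

#' @rdname readCountsTSV
#' @export
writeCountsMM <- function(counts, path) {
  counts <- asCountMatrix(counts)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".rownames"))
  writeLines(colnames(counts), paste0(path, ".colnames"))
  invisible(path)
}

#' Read a sample covariate table
#'
#' TSV with a `sample_id` column; remaining columns are covariates.
#'
#' @param path file path.
#' @return data.frame with sample identifiers as row names.
#' @examples
#' f <- tempfile()
#' write.table(data.frame(sample_id = c("a", "b"), group = 0:1), f,
#'             sep = "\t", quote = FALSE, row.names = FALSE)
#' readCovariates(f)
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("covariate table must have a 'sample_id' column: ", path)
  rownames(df) <- df$sample_id
  df[, setdiff(colnames(df), "sample_id"), drop = FALSE]
}

#' Construct a [BenchmarkConfig-class]
#'
#' @param scenario `"batch_only"` or `"batch_plus_biology"`.
#' @param batchKinds character vector from `c("binary","continuous","both")`.
#' @param nSamples integer vector of sample sizes.
#' @param nGenes gene count per dataset.
#' @param pctBatchAffected,pctDE numeric vectors of percentages.
#' @param methods latent methods (see [runWorkflow3()]); `"sva_be"` alone is
#'   enough for count-recovery benchmarks.
#' @param modes testing modes; empty to skip DE testing.
#' @param pcaThreshold PCA variance threshold.
#' @param nReplicates replicates per grid cell (default 200; the full-scale
#'   profile uses 1000).
#' @param masterSeed master seed for the replicate streams.
#' @param outDir optional output directory for tidy CSVs and a manifest.
#' @return A [BenchmarkConfig-class].
#' @examples
#' benchmarkConfig(nSamples = 20, pctBatchAffected = 10, nReplicates = 2)
#' @export
benchmarkConfig <- function(scenario = "batch_only",
                            batchKinds = "binary",
                            nSamples = c(20L, 50L, 100L, 200L),
                            nGenes = 1000L,
                            pctBatchAffected = c(5, 10, 15),
                            pctDE = 0,
                            methods = "sva_be",
                            modes = character(0),
                            pcaThreshold = 0.07,
                            nReplicates = 200L,
                            masterSeed = 1L,
                            outDir = NA_character_) {
  new("BenchmarkConfig", scenario = scenario, batchKinds = batchKinds,
      nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
      pctBatchAffected = as.numeric(pctBatchAffected),
      pctDE = as.numeric(pctDE), methods = methods, modes = modes,
      pcaThreshold = as.numeric(pcaThreshold),
      nReplicates = as.integer(nReplicates),
      masterSeed = as.integer(masterSeed), outDir = outDir)
}

#' Read a benchmark configuration from YAML or JSON
#'
#' Field names mirror the arguments of [benchmarkConfig()]; unknown fields
#' are rejected and missing required fields are named in the error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [BenchmarkConfig-class].
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"nSamples": [20], "pctBatchAffected": [10],
#'             "nReplicates": 2}', f)
#' readBenchConfig(f)
#' @export
readBenchConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path))
           jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("config must be .yaml, .yml or .json: ", path)
  allowed <- names(formals(benchmarkConfig))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  required <- c("nSamples", "pctBatchAffected", "nReplicates")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  do.call(benchmarkConfig, cfg)
}
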