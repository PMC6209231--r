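# Configuration-driven scenario runner: simulate -> estimate latent factors
# -> (optionally) adjust/test -> accumulate the evaluation metrics.

expandKinds <- function(kind) {
  if (kind == "both") c("binary", "continuous") else kind
}

cellKeyString <- function(scenario, kind, N, pctB, pctDE) {
  paste(scenario, kind, N, pctB, pctDE, sep = "|")
}

# One replicate of one grid cell. Returns a list of tidy metric rows.
# Uses the raw simulation path (no SummarizedExperiment container) since a
# grid run builds tens of thousands of datasets.
benchReplicate <- function(baseline, cfg, kindLabel, methods, modes,
                           metrics, pcaThreshold) {
  simMode <- if ("distance" %in% metrics) "coupled" else "none"
  effects <- drawEffects(cfg)
  raw <- simulateRaw(baseline, effects, simMode)
  effects <- raw$effects   # loadings may have been resampled on overflow
  y <- log2p1(raw$counts)
  isBatch <- effects@kind %in% c("binary_batch", "continuous_batch")
  bio <- which(!isBatch)
  hasGroup <- length(bio) == 1L
  Xprim <- if (hasGroup)
    cbind(intercept = 1, group = effects@gamma[, bio])
  else matrix(1, ncol(y), 1, dimnames = list(NULL, "intercept"))
  batchCov <- effects@gamma[, isBatch, drop = FALSE]
  resid <- residualMatrix(y, Xprim)
  trueJ <- sum(isBatch)

  rows <- list()
  add <- function(method, mode, metric, value, weight = 1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, mode = mode, metric = metric, value = value,
      weight = weight, true_j = trueJ, stringsAsFactors = FALSE)
  }

  latentCache <- new.env(parent = emptyenv())
  kCache <- new.env(parent = emptyenv())
  getLatent <- function(method) {
    if (!is.null(latentCache[[method]])) return(latentCache[[method]])
    est <- estimateLatent(y, Xprim, method, batchCov, pcaThreshold, 20L,
                          0.10, cache = kCache)
    latentCache[[method]] <- est
    est
  }

  if ("correct_k" %in% metrics) {
    for (m in intersect(methods, c("sva_be", "sva_leek", "pca"))) {
      k <- switch(m,
        sva_be = numSVBE(resid),
        sva_leek = suppressWarnings(numSVLeek(resid)),
        pca = estimatePCA(resid, pcaThreshold)@k)
      add(m, NA_character_, "k_hat", as.numeric(k))
    }
  }

  if ("distance" %in% metrics) {
    logBase <- log2p1(raw$baseline)
    for (m in setdiff(methods, "none")) {
      est <- getLatent(m)
      adj <- removeBatch(y, Xprim, est@factors)
      add(m, NA_character_, "distance", distanceToBaseline(adj, logBase))
      add(m, NA_character_, "k_used", as.numeric(est@k))
    }
  }

  if ("type1" %in% metrics && length(modes) > 0 && hasGroup) {
    nullGenes <- raw$truth == "null"
    for (m in methods) {
      est <- getLatent(m)
      for (mode in modes) {
        if (mode == "post_normalization") {
          adj <- removeBatch(y, Xprim, est@factors)
          fit <- moderatedTTest(adj, Xprim, "group")
        } else {
          X <- if (est@k > 0) cbind(Xprim, est@factors) else Xprim
          fit <- moderatedTTest(y, X, "group")
        }
        rej <- mean(fit$p_value[nullGenes] < 0.05, na.rm = TRUE)
        add(m, mode, "type1_fraction", rej, weight = sum(nullGenes))
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the simulation benchmark over a scenario grid
#'
#' For every grid cell (batch kind x sample size x percent batch-affected x
#' percent DE) and every replicate: simulate a dataset, estimate latent
#' factors with each method, optionally adjust/test in each mode, and
#' accumulate metrics. Fully deterministic given `masterSeed`: each
#' replicate's seed derives from a hash of the cell's parameter string and
#' the replicate counter, so extending the grid never perturbs existing
#' streams. Replicates that fail are logged and excluded, with counts
#' reported in the manifest.
#'
#' Metrics: `"correct_k"` (latent-count recovery; methods `sva_be`,
#' `sva_leek`, `pca`), `"distance"` (Frobenius distance of adjusted data to
#' the log batch-free baseline, per replicate), `"type1"` (per-replicate
#' fraction of null genes with p < 0.05, with the null-gene count as
#' weight; requires a biological factor and at least one mode).
#'
#' @param config a [BenchmarkConfig-class].
#' @param metrics character subset of `c("correct_k", "distance", "type1")`.
#' @param baseline an [NBParams-class]; default `defaultBaseline(nGenes)`.
#' @param verbose print per-cell progress to stderr.
#' @return list with `results` (tidy data.frame: one row per cell x
#'   replicate x method x metric), `summary` (per-cell aggregates from
#'   [summarizeBenchmark()]), and `manifest` (seeds, failures, versions).
#'   When `config@outDir` is set the three are also written as
#'   `results.csv`, `summary.csv` and `manifest.yaml`.
#' @examples
#' cfg <- benchmarkConfig(nSamples = 20L, nGenes = 200L,
#'                        pctBatchAffected = 10, nReplicates = 2L)
#' out <- runBenchmark(cfg, metrics = "correct_k", verbose = FALSE)
#' out$summary
#' @export
runBenchmark <- function(config, metrics = "correct_k", baseline = NULL,
                         verbose = TRUE) {
  stopifnot(is(config, "BenchmarkConfig"),
            all(metrics %in% c("correct_k", "distance", "type1")))
  if (is.null(baseline)) baseline <- defaultBaseline(config@nGenes)
  stopifnot(length(baseline) == config@nGenes)

  grid <- expand.grid(kind = config@batchKinds, N = config@nSamples,
                      pctB = config@pctBatchAffected, pctDE = config@pctDE,
                      stringsAsFactors = FALSE)
  allRows <- vector("list", nrow(grid))
  failures <- list()
  for (ci in seq_len(nrow(grid))) {
    g <- grid[ci, ]
    key <- cellKeyString(config@scenario, g$kind, g$N, g$pctB, g$pctDE)
    if (verbose)
      message("cell ", ci, "/", nrow(grid), ": ", key)
    cfg <- scenarioConfig(config@scenario, expandKinds(g$kind),
                          nSamples = g$N, nGenes = config@nGenes,
                          pctBatchAffected = g$pctB, pctDE = g$pctDE)
    cellRows <- vector("list", config@nReplicates)
    for (r in seq_len(config@nReplicates)) {
      seed <- childSeed(config@masterSeed, key, r)
      set.seed(seed)
      rows <- tryCatch(
        suppressMessages(benchReplicate(baseline, cfg, g$kind,
                                        config@methods, config@modes,
                                        metrics, config@pcaThreshold)),
        error = function(e) {
          failures[[length(failures) + 1L]] <<-
            list(cell = key, replicate = r, error = conditionMessage(e))
          NULL
        })
      if (!is.null(rows)) {
        rows$replicate <- r; rows$seed <- seed
        cellRows[[r]] <- rows
      }
    }
    cell <- do.call(rbind, cellRows)
    if (!is.null(cell)) {
      cell$scenario <- config@scenario; cell$batch_kind <- g$kind
      cell$n_samples <- g$N; cell$pct_batch <- g$pctB; cell$pct_de <- g$pctDE
      allRows[[ci]] <- cell
    }
  }
  results <- do.call(rbind, allRows)
  summary <- summarizeBenchmark(results)
  manifest <- list(
    package = as.character(utils::packageVersion("svbench")),
    masterSeed = config@masterSeed,
    nReplicates = config@nReplicates,
    metrics = metrics,
    methods = config@methods,
    modes = config@modes,
    grid = grid,
    nFailures = length(failures),
    failures = failures)
  if (length(failures))
    warning(length(failures), " replicate(s) failed and were excluded")
  if (!is.na(config@outDir)) {
    if (!dir.exists(config@outDir))
      dir.create(config@outDir, recursive = TRUE)
    utils::write.csv(results, file.path(config@outDir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config@outDir, "summary.csv"),
                     row.names = FALSE)
    manifest$grid <- NULL
    yaml::write_yaml(manifest, file.path(config@outDir, "manifest.yaml"))
  }
  list(results = results, summary = summary, manifest = manifest)
}

#' Aggregate tidy benchmark rows per grid cell
#'
#' Computes, per cell x method (x mode where applicable):
#' `correct_k_rate` (percent of replicates with `k_hat` equal to the true
#' number of batch variables), `median_distance`, and `avg_type1` (the
#' weighted mean of per-replicate null-gene rejection fractions, weights
#' the null-gene counts — equal to averaging per-gene type-I error rates
#' over null genes).
#'
#' @param results the tidy `results` data.frame from [runBenchmark()].
#' @return data.frame of per-cell summaries (column `value`, named by
#'   `metric`).
#' @examples
#' cfg <- benchmarkConfig(nSamples = 20L, nGenes = 200L,
#'                        pctBatchAffected = 10, nReplicates = 2L)
#' out <- runBenchmark(cfg, metrics = "correct_k", verbose = FALSE)
#' summarizeBenchmark(out$results)
#' @export
summarizeBenchmark <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    return(data.frame())
  cellCols <- c("scenario", "batch_kind", "n_samples", "pct_batch",
                "pct_de", "method", "mode")
  out <- list()
  kh <- results[results$metric == "k_hat", ]
  if (nrow(kh)) {
    agg <- stats::aggregate(cbind(hit = kh$value == kh$true_j) ~
                              scenario + batch_kind + n_samples +
                              pct_batch + pct_de + method,
                            data = kh, FUN = mean)
    agg$metric <- "correct_k_rate"; agg$value <- 100 * agg$hit
    agg$hit <- NULL; agg$mode <- NA_character_
    out[[length(out) + 1L]] <- agg
  }
  dd <- results[results$metric == "distance", ]
  if (nrow(dd)) {
    agg <- stats::aggregate(value ~ scenario + batch_kind + n_samples +
                              pct_batch + pct_de + method,
                            data = dd, FUN = median)
    agg$metric <- "median_distance"; agg$mode <- NA_character_
    out[[length(out) + 1L]] <- agg
  }
  t1 <- results[results$metric == "type1_fraction", ]
  if (nrow(t1)) {
    t1$wv <- t1$value * t1$weight
    agg <- stats::aggregate(cbind(wv, weight) ~ scenario + batch_kind +
                              n_samples + pct_batch + pct_de + method + mode,
                            data = t1, FUN = sum)
    agg$value <- agg$wv / agg$weight
    agg$metric <- "avg_type1"
    agg$wv <- NULL; agg$weight <- NULL
    out[[length(out) + 1L]] <- agg
  }
  cols <- c(cellCols, "metric", "value")
  do.call(rbind, lapply(out, function(d) d[, cols]))
}
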