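# Synthetic count generation: NB2 baselines with multiplicative batch /
# biology mean shifts mu_g * exp(sum_j omega_gj * gamma_nj).

#' Draw sample covariates and gene loadings for a scenario
#'
#' Creates one column per simulated variable, in the order binary batch,
#' continuous batch, biology (restricted to the kinds the scenario
#' requests). Binary covariates are Bernoulli(`bernoulliP`), continuous ones
#' standard uniform; gene loadings are Normal(0, sigma) on an affected-gene
#' subset drawn without replacement at the configured percentage (rounded
#' half away from zero), independently per variable so masks may overlap.
#'
#' @param config a [ScenarioConfig-class].
#' @return An [EffectSpec-class].
#' @examples
#' set.seed(1)
#' drawEffects(scenarioConfig("batch_only", "binary", nSamples = 20,
#'                            nGenes = 100, pctBatchAffected = 10))
#' @export
drawEffects <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  N <- config@nSamples; G <- config@nGenes
  kinds <- character(0); sigmas <- numeric(0); pcts <- numeric(0)
  if ("binary" %in% config@batchKinds) {
    kinds <- c(kinds, "binary_batch")
    sigmas <- c(sigmas, config@sigmaBinaryBatch)
    pcts <- c(pcts, config@pctBatchAffected)
  }
  if ("continuous" %in% config@batchKinds) {
    kinds <- c(kinds, "continuous_batch")
    sigmas <- c(sigmas, config@sigmaContinuousBatch)
    pcts <- c(pcts, config@pctBatchAffected)
  }
  if (config@scenario == "batch_plus_biology") {
    kinds <- c(kinds, "biology")
    sigmas <- c(sigmas, config@sigmaBiology)
    pcts <- c(pcts, config@pctDE)
  }
  J <- length(kinds)
  gamma <- matrix(0, N, J)
  omega <- matrix(0, G, J)
  affected <- matrix(FALSE, G, J)
  for (j in seq_len(J)) {
    gamma[, j] <- if (kinds[j] == "continuous_batch") runif(N)
                  else rbinom(N, 1L, config@bernoulliP)
    nAff <- as.integer(roundHalfAway(pcts[j] / 100 * G))
    if (pcts[j] > 0 && nAff == 0L)
      stop("pct ", pcts[j], "% of G = ", G,
           " genes rounds to zero affected genes; increase nGenes")
    if (nAff > 0L) {
      idx <- sample.int(G, nAff)
      affected[idx, j] <- TRUE
      omega[idx, j] <- rnorm(nAff, 0, sigmas[j])
    }
  }
  colnames(gamma) <- colnames(omega) <- colnames(affected) <- kinds
  new("EffectSpec", gamma = gamma, omega = omega, kind = kinds,
      sigma = sigmas, affected = affected)
}

# NB quantile/draw helpers handling the phi = 0 (Poisson) boundary.
nbDraw <- function(mu, phi) {
  out <- numeric(length(mu))
  pois <- phi == 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois))
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
  out
}

nbQuantile <- function(u, mu, phi) {
  out <- numeric(length(mu))
  pois <- phi == 0
  if (any(pois)) out[pois] <- qpois(u[pois], mu[pois])
  if (any(!pois))
    out[!pois] <- qnbinom(u[!pois], mu = mu[!pois], size = 1 / phi[!pois])
  out
}

#' Simulate a batch-affected count dataset
#'
#' Draws each count from NB2 with mean
#' \eqn{\mu_g \exp(\sum_j \omega_{gj}\gamma_{nj})} and dispersion
#' \eqn{\phi_g} (variance \eqn{\mu + \phi\mu^2}). The batch-free baseline
#' assay zeroes every batch loading while keeping biological effects.
#'
#' `baseline` controls how the baseline assay is produced:
#' \describe{
#'   \item{`"coupled"`}{counts and baseline are inverse-CDF transforms of
#'     one shared uniform draw per cell, so their difference reflects batch
#'     signal rather than Monte-Carlo noise; genes untouched by batch have
#'     bit-identical rows in the two assays.}
#'   \item{`"independent"`}{baseline drawn from an independent stream.}
#'   \item{`"none"`}{no baseline assay; counts come from a fast direct
#'     sampler. Use for large benchmark runs that never compute the
#'     distance-to-baseline metric.}
#' }
#'
#' @param params an [NBParams-class] baseline.
#' @param effects an [EffectSpec-class] with matching gene count.
#' @param baseline `"coupled"` (default), `"independent"` or `"none"`.
#' @param sampleIds optional sample identifiers.
#' @return A [SimBatchExperiment-class]. Truth labels in `rowData()$truth`
#'   are `"null"`, `"batch_affected"`, `"de"` or `"both"`; sample covariates
#'   sit in `colData()` (column `group` for the biological factor).
#' @examples
#' set.seed(1)
#' cfg <- scenarioConfig("batch_only", "binary", nSamples = 10, nGenes = 50,
#'                       pctBatchAffected = 10)
#' sim <- simulateCounts(defaultBaseline(50), drawEffects(cfg))
#' table(truthLabels(sim))
#' @export
simulateCounts <- function(params, effects,
                           baseline = c("coupled", "independent", "none"),
                           sampleIds = NULL) {
  stopifnot(is(params, "NBParams"), is(effects, "EffectSpec"))
  baseline <- match.arg(baseline)
  N <- nrow(effects@gamma)
  if (is.null(sampleIds)) sampleIds <- sprintf("sample%03d", seq_len(N))
  raw <- simulateRaw(params, effects, baseline)
  cnt <- raw$counts
  dimnames(cnt) <- list(params@geneIds, sampleIds)
  assays <- list(counts = cnt)
  if (!is.null(raw$baseline)) {
    base <- raw$baseline
    dimnames(base) <- dimnames(cnt)
    assays$baseline <- base
  }
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  for (j in seq_along(raw$effects@kind)) {
    nm <- switch(raw$effects@kind[j], binary_batch = "batch_binary",
                 continuous_batch = "batch_continuous", biology = "group")
    cd[[nm]] <- raw$effects@gamma[, j]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(truth = raw$truth,
                                   row.names = params@geneIds),
    colData = cd,
    metadata = list(effects = raw$effects, baselineMode = baseline))
  new("SimBatchExperiment", se)
}

# Unadorned simulation path shared by simulateCounts and the benchmark
# runner: returns plain matrices and the truth labels, skipping the
# SummarizedExperiment container. Consumes the RNG identically to
# simulateCounts.
simulateRaw <- function(params, effects, baseline) {
  G <- length(params)
  if (nrow(effects@omega) != G)
    stop("effects were drawn for ", nrow(effects@omega),
         " genes but baseline has ", G)
  N <- nrow(effects@gamma)

  # mean shift; resample any single loading whose shift overflows
  shift <- effects@omega %*% t(effects@gamma)   # G x N
  muFull <- params@mu * exp(shift)
  guard <- 0L
  while (any(!is.finite(muFull))) {
    bad <- unique(which(!is.finite(muFull), arr.ind = TRUE)[, 1L])
    message("resampling extreme loadings for ", length(bad), " gene(s)")
    for (g in bad) {
      j <- which(effects@affected[g, ] & abs(effects@omega[g, ]) ==
                   max(abs(effects@omega[g, effects@affected[g, ]])))[1L]
      effects@omega[g, j] <- rnorm(1L, 0, effects@sigma[j])
    }
    shift <- effects@omega %*% t(effects@gamma)
    muFull <- params@mu * exp(shift)
    guard <- guard + 1L
    if (guard > 100L) stop("mean shift overflow persists after resampling")
  }

  isBatch <- effects@kind %in% c("binary_batch", "continuous_batch")
  batchAffected <- if (any(isBatch))
    rowSums(effects@affected[, isBatch, drop = FALSE]) > 0 else rep(FALSE, G)
  bioAffected <- if (any(!isBatch))
    rowSums(effects@affected[, !isBatch, drop = FALSE]) > 0 else rep(FALSE, G)
  truth <- ifelse(batchAffected & bioAffected, "both",
           ifelse(batchAffected, "batch_affected",
           ifelse(bioAffected, "de", "null")))

  phi <- rep(params@phi, N)  # column-major expansion over samples
  if (baseline == "none") {
    cnt <- matrix(nbDraw(as.vector(muFull), phi), G, N)
    base <- NULL
  } else {
    omegaBase <- effects@omega
    omegaBase[, isBatch] <- 0
    muBase <- params@mu * exp(omegaBase %*% t(effects@gamma))
    if (baseline == "coupled") {
      u <- runif(G * N)
      cnt <- matrix(nbQuantile(u, as.vector(muFull), phi), G, N)
      base <- cnt
      aff <- batchAffected
      if (any(aff)) {
        sel <- rep(aff, N)
        base[aff, ] <- matrix(nbQuantile(u[sel], as.vector(muBase)[sel],
                                         phi[sel]), sum(aff), N)
      }
    } else {
      cnt <- matrix(nbDraw(as.vector(muFull), phi), G, N)
      base <- matrix(nbDraw(as.vector(muBase), phi), G, N)
    }
  }

  list(counts = cnt, baseline = base, truth = truth, effects = effects)
}

#' Export a simulated dataset as tab-separated text
#'
#' Writes the counts (and baseline, when present) as gene-by-sample TSV
#' matrices, plus companion tables of truth labels and sample covariates.
#'
#' @param sim a [SimBatchExperiment-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths.
#' @examples
#' set.seed(1)
#' cfg <- scenarioConfig("batch_only", "binary", nSamples = 6, nGenes = 20,
#'                       pctBatchAffected = 10)
#' sim <- simulateCounts(defaultBaseline(20), drawEffects(cfg))
#' exportSimulation(sim, tempdir())
#' @export
exportSimulation <- function(sim, dir, prefix = "sim") {
  stopifnot(is(sim, "SimBatchExperiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "-counts.tsv")))
  writeCountsTSV(counts(sim), paths[["counts"]])
  if ("baseline" %in% SummarizedExperiment::assayNames(sim)) {
    paths[["baseline"]] <- file.path(dir, paste0(prefix, "-baseline.tsv"))
    writeCountsTSV(baselineCounts(sim), paths[["baseline"]])
  }
  paths[["truth"]] <- file.path(dir, paste0(prefix, "-truth.tsv"))
  write.table(data.frame(gene_id = rownames(sim), truth = truthLabels(sim)),
              paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths[["covariates"]] <- file.path(dir, paste0(prefix, "-covariates.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sim))
  write.table(cbind(sample_id = rownames(cd), cd), paths[["covariates"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
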