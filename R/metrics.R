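# Evaluation metrics: correct latent-count rate, distance to the batch-free
# baseline, averaged empirical type-I error, and DE-overlap summaries.

#' Percentage of replicates with the correct latent-factor count
#'
#' @param estimatedKs integer vector, one estimate per replicate dataset.
#' @param trueJ the true number of simulated latent variables.
#' @return percentage in [0, 100].
#' @examples
#' correctSVRate(c(1, 1, 2, 0), 1)
#' @export
correctSVRate <- function(estimatedKs, trueJ) {
  stopifnot(length(estimatedKs) > 0, length(trueJ) == 1L)
  100 * mean(estimatedKs == trueJ)
}

#' Euclidean distance between normalized and baseline matrices
#'
#' The Frobenius norm of the difference of the two log-scale matrices (one
#' scalar per replicate dataset). With `perSample = TRUE`, returns instead
#' the mean over samples of per-sample (column) Euclidean distances.
#'
#' @param adjusted G x N normalized log-expression.
#' @param baselineLog G x N log-transformed batch-free baseline.
#' @param perSample aggregate per sample instead of over the whole matrix.
#' @return non-negative scalar.
#' @examples
#' distanceToBaseline(matrix(1, 10, 10), matrix(0, 10, 10))
#' @export
distanceToBaseline <- function(adjusted, baselineLog, perSample = FALSE) {
  adjusted <- as.matrix(adjusted); baselineLog <- as.matrix(baselineLog)
  if (!all(dim(adjusted) == dim(baselineLog)))
    stop("matrices must have identical dimensions")
  d <- adjusted - baselineLog
  if (perSample) mean(sqrt(colSums(d^2))) else sqrt(sum(d^2))
}

#' Empirical type-I error of null genes
#'
#' Per-gene rejection rate across replicate simulations and their average:
#' the fraction of replicates with p < `alpha`, averaged over null genes.
#'
#' @param pMatrix null-genes x replicates matrix of p-values.
#' @param alpha nominal level (default 0.05).
#' @return list with `perGene` (vector of per-gene rates) and `average`
#'   (their mean).
#' @examples
#' empiricalType1(matrix(runif(5000), 50), alpha = 0.05)$average
#' @export
empiricalType1 <- function(pMatrix, alpha = 0.05) {
  pMatrix <- as.matrix(pMatrix)
  if (ncol(pMatrix) == 0L) stop("zero replicates")
  stopifnot(all(pMatrix >= 0 & pMatrix <= 1, na.rm = TRUE))
  perGene <- rowMeans(pMatrix < alpha, na.rm = TRUE)
  list(perGene = perGene, average = mean(perGene))
}

#' Overlap of significant genes between DE result tables
#'
#' Venn-style exclusive subset cardinalities of the sets
#' `{genes with q_value < qThreshold}` of each method.
#'
#' @param resultTables named list of DE result tables sharing one gene
#'   universe (each with columns `gene_id` and `q_value`).
#' @param qThreshold significance cutoff on the adjusted p-value.
#' @return named integer vector; names are `&`-joined method subsets, plus
#'   `"none"` for genes significant nowhere.
#' @examples
#' t1 <- S4Vectors::DataFrame(gene_id = c("a", "b"), q_value = c(0.01, 0.2))
#' t2 <- S4Vectors::DataFrame(gene_id = c("a", "b"), q_value = c(0.01, 0.01))
#' deOverlap(list(m1 = t1, m2 = t2), 0.05)
#' @export
deOverlap <- function(resultTables, qThreshold = 0.05) {
  stopifnot(is.list(resultTables), length(resultTables) >= 1,
            !is.null(names(resultTables)))
  ids <- lapply(resultTables, function(t) as.character(t$gene_id))
  universe <- ids[[1L]]
  for (i in seq_along(ids))
    if (!setequal(ids[[i]], universe))
      stop("result tables do not share a gene universe")
  member <- vapply(resultTables, function(t) {
    q <- t$q_value[match(universe, as.character(t$gene_id))]
    !is.na(q) & q < qThreshold
  }, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(resultTables)))
  key <- apply(member, 1L, function(row) {
    s <- names(resultTables)[row]
    if (length(s) == 0) "none" else paste(s, collapse = "&")
  })
  table(key)
}
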