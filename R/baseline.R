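# Baseline parameter fixtures and their 3-column TSV serialization.

#' Built-in synthetic baseline parameter fixture
#'
#' A frozen synthetic set of per-gene NB parameters spanning realistic bulk
#' RNA-seq ranges: means log-uniform on [1, 1e4] and dispersions uniform on
#' [0.05, 1]. The fixture is generated from a pinned internal seed, so the
#' same `nGenes` always yields the same parameters; it stands in for
#' baselines a user would estimate from a pilot dataset with
#' [fitBaseline()].
#'
#' @param nGenes number of genes (default 1000).
#' @return An [NBParams-class] with `nGenes` genes.
#' @examples
#' defaultBaseline(5)
#' @export
defaultBaseline <- function(nGenes = 1000L) {
  nGenes <- as.integer(nGenes)
  stopifnot(nGenes >= 2L)
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(rs)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", rs, envir = globalenv())
  })
  set.seed(20181031L)  # fixture pin; not a tuning knob
  mu <- 10^runif(nGenes, 0, 4)
  phi <- runif(nGenes, 0.05, 1.0)
  nbParams(sprintf("gene%04d", seq_len(nGenes)), mu, phi)
}

#' Load baseline NB parameters from a fixture
#'
#' Accepts either a path to a 3-column tab-separated file (header
#' `gene_id`, `mu_star`, `phi_star`) or a builtin name of the form
#' `"default-<G>"`, e.g. `"default-1000"`.
#'
#' @param x file path or builtin fixture name.
#' @return An [NBParams-class].
#' @examples
#' p <- loadBaseline("default-1000")
#' length(p)
#' @export
loadBaseline <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^default-[0-9]+$", x))
    return(defaultBaseline(as.integer(sub("^default-", "", x))))
  if (!file.exists(x))
    stop("baseline fixture not found: ", x)
  readBaseline(x)
}

#' Read / write baseline parameters as tab-separated text
#'
#' The on-disk format is UTF-8 TSV with a header row and columns
#' `gene_id`, `mu_star`, `phi_star`. Malformed rows are reported with their
#' line number.
#'
#' @param path file path.
#' @param params an [NBParams-class] (for writing).
#' @return `readBaseline()` returns an [NBParams-class]; `writeBaseline()`
#'   invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeBaseline(defaultBaseline(10), f)
#' length(readBaseline(f))
#' @export
readBaseline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("baseline fixture has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("gene_id", "mu_star", "phi_star")))
    stop("line 1: expected header 'gene_id\\tmu_star\\tphi_star' in ", path)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": expected 3 tab-separated fields in ", path)
  ids <- vapply(fields, `[[`, character(1), 1L)
  mu <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  phi <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(mu) | !is.finite(phi))
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": non-numeric mu_star/phi_star in ", path)
  bad <- which(mu <= 0)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": mu_star must be > 0 in ", path)
  bad <- which(phi < 0)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": phi_star must be >= 0 in ", path)
  nbParams(ids, mu, phi)
}

#' @rdname readBaseline
#' @export
writeBaseline <- function(params, path) {
  stopifnot(is(params, "NBParams"))
  df <- data.frame(gene_id = params@geneIds,
                   mu_star = format(params@mu, digits = 15),
                   phi_star = format(params@phi, digits = 15))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("gene_id\tmu_star\tphi_star", con)
  writeLines(paste(df$gene_id, df$mu_star, df$phi_star, sep = "\t"), con)
  invisible(path)
}

#' Estimate baseline NB parameters from a pilot count matrix
#'
#' Fits the intercept-only NB2 model gene by gene with [fitNB()]; genes with
#' degenerate fits (all-zero rows) are dropped with a message, since a
#' baseline mean of zero cannot seed the simulator.
#'
#' @param counts gene-by-sample matrix of non-negative integers.
#' @return An [NBParams-class] for the retained genes.
#' @examples
#' m <- matrix(rpois(40, 20), 10, dimnames = list(paste0("g", 1:10), NULL))
#' fitBaseline(m)
#' @export
fitBaseline <- function(counts) {
  counts <- asCountMatrix(counts)
  fits <- apply(counts, 1L, fitNB)
  ok <- vapply(fits, function(f) f@converged, logical(1))
  if (any(!ok))
    message("dropping ", sum(!ok), " gene(s) with degenerate baseline fits")
  nbParams(rownames(counts)[ok],
           vapply(fits[ok], function(f) f@mu, numeric(1)),
           vapply(fits[ok], function(f) f@phi, numeric(1)))
}
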