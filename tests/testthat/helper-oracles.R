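# Independent straight-line oracles, deliberately written as naive
# transcriptions of the formulas so they share no code with the package.

# TMM factor of one test sample against a reference sample.
oracleTMMPair <- function(x, r, Nx, Nr, logratioTrim = 0.3, sumTrim = 0.05) {
  keep <- x > 0 & r > 0
  x <- x[keep]; r <- r[keep]
  M <- log2((x / Nx) / (r / Nr))
  A <- 0.5 * log2((x / Nx) * (r / Nr))
  w <- (Nx - x) / (Nx * x) + (Nr - r) / (Nr * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# Full TMM factor vector with an explicit reference column, rescaled to
# geometric mean 1.
oracleTMM <- function(counts, refCol) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    oracleTMMPair(counts[, j], counts[, refCol], lib[j], lib[refCol])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Hand step-up BH adjustment.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    v <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

# Naive per-gene moderated t with an explicitly supplied prior.
oracleModT <- function(y, design, contrast, d0, s0sq) {
  N <- ncol(y); p <- ncol(design)
  XtXinv <- solve(t(design) %*% design)
  v <- XtXinv[contrast, contrast]
  out <- data.frame(t = numeric(nrow(y)), df = numeric(nrow(y)),
                    p = numeric(nrow(y)))
  for (g in seq_len(nrow(y))) {
    fit <- lm.fit(design, y[g, ])
    s2 <- sum(fit$residuals^2) / (N - p)
    st2 <- if (is.infinite(d0)) s0sq
           else if (d0 == 0) s2
           else (d0 * s0sq + (N - p) * s2) / (d0 + N - p)
    tg <- fit$coefficients[contrast] / sqrt(st2 * v)
    out$t[g] <- tg
    out$df[g] <- d0 + N - p
    out$p[g] <- 2 * pt(-abs(tg), d0 + N - p)
  }
  out
}

# Naive per-gene residuals of y (G x N) on a design.
oracleResiduals <- function(y, design) {
  t(apply(y, 1L, function(row) lm.fit(design, row)$residuals))
}

# Simulate one small scenario and return pieces used by several tests.
simPlanted <- function(N = 100, G = 1000, pct = 15, kind = "binary",
                       base = defaultBaseline(G)) {
  cfg <- scenarioConfig("batch_only", kind, nSamples = N, nGenes = G,
                        pctBatchAffected = pct)
  eff <- drawEffects(cfg)
  sim <- simulateCounts(base, eff, "none")
  list(sim = sim, eff = eff,
       y = logCounts(counts(sim)),
       resid = residualMatrix(logCounts(counts(sim)), matrix(1, N)))
}
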