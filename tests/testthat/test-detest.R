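# Batch removal, variance prior, moderated t, BH, and the workflow runner.

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_identical(bhAdjust(0.37), 0.37)
  set.seed(41)
  p <- runif(200)
  expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  expect_true(all(bhAdjust(p) >= p))
  perm <- sample(200)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]), tolerance = 1e-12)
  pNA <- c(0.01, NA, 0.5)
  adj <- bhAdjust(pNA)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracleBH(c(0.01, 0.5)), tolerance = 1e-12)
})

test_that("removeBatch removes batch signal but preserves the group contrast", {
  set.seed(42)
  N <- 40
  group <- rep(0:1, each = N / 2)
  batch <- rep(c(0, 1), N / 2)           # balanced against group
  y <- matrix(rnorm(100 * N), 100, N) +
    outer(rnorm(100, 0, 2), batch) + outer(rnorm(100, 1), group)
  Xp <- cbind(1, group)
  adj <- removeBatch(y, Xp, cbind(batch))

  # re-fitting batch on the adjusted data finds nothing
  refit <- qr.coef(qr(cbind(Xp, batch)), t(adj))[3, ]
  expect_lt(max(abs(refit)), 1e-8)

  # balanced design: the group-mean difference is untouched
  d0 <- rowMeans(y[, group == 1]) - rowMeans(y[, group == 0])
  d1 <- rowMeans(adj[, group == 1]) - rowMeans(adj[, group == 0])
  expect_lt(max(abs(d0 - d1)), 1e-8)

  # zero-column batch design is a no-op
  expect_identical(removeBatch(y, Xp, matrix(0, N, 0)), y)
  expect_error(removeBatch(y, Xp, cbind(g2 = group)), "collinear")
})

test_that("variance-prior recovery and its degenerate limits", {
  expect_identical(estimateVariancePrior(rep(2, 50), 10)@d0, Inf)
  expect_identical(estimateVariancePrior(3, 10)@d0, Inf)

  set.seed(43)
  d0 <- 4; s0 <- 2; G <- 5000
  sigma2 <- d0 * s0 / rchisq(G, d0)   # gene variances from the prior
  s2 <- sigma2 * rchisq(G, 12) / 12   # observed sample variances, 12 df
  pr <- estimateVariancePrior(s2, df = 12)
  expect_lt(abs(pr@d0 - d0) / d0, 0.15)
  expect_lt(abs(pr@s0sq - s0) / s0, 0.15)

  perm <- sample(G)
  pr2 <- estimateVariancePrior(s2[perm], 12)
  expect_equal(pr@d0, pr2@d0, tolerance = 1e-12)
  expect_equal(pr@s0sq, pr2@s0sq, tolerance = 1e-12)
})

test_that("moderated t matches the straight-line shrinkage implementation", {
  set.seed(44)
  N <- 12
  y <- matrix(rnorm(20 * N), 20, N,
              dimnames = list(paste0("g", 1:20), NULL))
  X <- cbind(intercept = 1, group = rep(0:1, each = 6))
  pr <- variancePrior(4, 0.5)
  got <- moderatedTTest(y, X, "group", prior = pr)
  want <- oracleModT(y, X, 2, 4, 0.5)
  expect_lt(max(abs(got$t_stat - want$t)), 1e-8)
  expect_lt(max(abs(got$p_value - want$p)), 1e-8)
  expect_equal(got$df, want$df, tolerance = 1e-12)

  # d0 = 0 reduces to the ordinary per-gene t
  ord <- moderatedTTest(y, X, "group", prior = variancePrior(0, 1))
  want0 <- oracleModT(y, X, 2, 0, 1)
  expect_lt(max(abs(ord$t_stat - want0$t)), 1e-10)

  # d0 = Inf pools every gene at s0^2
  inf <- moderatedTTest(y, X, "group", prior = variancePrior(Inf, 0.7))
  wantI <- oracleModT(y, X, 2, Inf, 0.7)
  expect_lt(max(abs(inf$t_stat - wantI$t)), 1e-10)
})

test_that("estimated prior and statistics agree with the limma reference", {
  set.seed(45)
  N <- 16
  y <- matrix(rnorm(300 * N, sd = rep(sqrt(2 * 4 / rchisq(300, 4)), N)),
              300, N, dimnames = list(paste0("g", 1:300), NULL))
  X <- cbind(1, rep(0:1, each = 8))
  got <- moderatedTTest(y, X, 2)
  if (requireNamespace("limma", quietly = TRUE)) {
    fit <- limma::eBayes(limma::lmFit(y, X))
    pr <- S4Vectors::metadata(got)$prior
    expect_equal(pr@d0, fit$df.prior, tolerance = 1e-6)
    expect_equal(pr@s0sq, fit$s2.prior, tolerance = 1e-6)
    expect_equal(unname(got$t_stat), unname(fit$t[, 2]), tolerance = 1e-8)
    expect_equal(unname(got$p_value), unname(fit$p.value[, 2]),
                 tolerance = 1e-8)
  }
})

test_that("workflow modes differ exactly by the latent degrees of freedom", {
  set.seed(46)
  base <- defaultBaseline(500)
  cfg <- scenarioConfig("batch_plus_biology", "binary", nSamples = 30,
                        nGenes = 500, pctBatchAffected = 15, pctDE = 5)
  sim <- simulateCounts(base, drawEffects(cfg), "none")
  run <- function(mode) {
    set.seed(99)
    suppressMessages(runWorkflow3(sim, "ruv_r", mode))
  }
  post <- run("post_normalization")
  design <- run("design_matrix")
  k <- nLatent(post$latent)
  expect_gte(k, 1L)
  expect_identical(nLatent(design$latent), k)
  # the df bookkeeping IS the point: post mode ignores the k factors
  expect_equal(post$df, 30 - 2)
  expect_equal(design$df, 30 - 2 - k)

  # determinism: identical seeds and config give identical tables
  post2 <- run("post_normalization")
  expect_identical(as.data.frame(post$result), as.data.frame(post2$result))
})
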