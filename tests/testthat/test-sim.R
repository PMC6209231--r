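# Synthetic-data generator: effect draws, NB moments, coupling, labels.

test_that("drawEffects hits the configured affected-gene counts exactly", {
  set.seed(1)
  cfg <- scenarioConfig("batch_only", "binary", nSamples = 20,
                        nGenes = 1000, pctBatchAffected = 15)
  eff <- drawEffects(cfg)
  expect_identical(sum(eff@omega[, 1] != 0), 150L)
  expect_identical(sum(eff@affected[, 1]), 150L)

  cfg0 <- scenarioConfig("batch_only", "binary", nSamples = 20,
                         nGenes = 1000, pctBatchAffected = 0)
  eff0 <- drawEffects(cfg0)
  expect_true(all(eff0@omega == 0))

  # a percentage rounding to zero genes is rejected
  tiny <- scenarioConfig("batch_only", "binary", nSamples = 20,
                         nGenes = 5, pctBatchAffected = 1)
  expect_error(drawEffects(tiny), "zero affected genes")
})

test_that("three-variable configs give ordered kinds and near-independent masks", {
  set.seed(2)
  cfg <- scenarioConfig("batch_plus_biology", c("binary", "continuous"),
                        nSamples = 10, nGenes = 200,
                        pctBatchAffected = 20, pctDE = 25)
  overlaps <- replicate(1000, {
    eff <- drawEffects(cfg)
    sum(eff@affected[, 1] & eff@affected[, 3])
  })
  eff <- drawEffects(cfg)
  expect_identical(eff@kind, c("binary_batch", "continuous_batch", "biology"))
  expect_true(all(eff@gamma[, 1] %in% c(0, 1)))
  expect_true(all(eff@gamma[, 2] >= 0 & eff@gamma[, 2] <= 1))
  # expected overlap = G * 0.20 * 0.25 = 10; MC se of the mean ~ 0.1
  expect_lt(abs(mean(overlaps) - 200 * 0.20 * 0.25), 0.5)
})

test_that("simulated counts match the NB mean-shift and variance moments", {
  set.seed(3)
  n <- 1e5
  params <- nbParams("g1", mu = 100, phi = 0.1)
  eff <- new("EffectSpec",
             gamma = matrix(1, n, 1), omega = matrix(log(2), 1, 1),
             kind = "binary_batch", sigma = 2,
             affected = matrix(TRUE, 1, 1))
  sim <- simulateCounts(params, eff, "none")
  x <- as.numeric(counts(sim))
  # E[x] = 100 * exp(log 2) = 200; se = sd/sqrt(n)
  expect_lt(abs(mean(x) - 200) / 200, 0.01)
  expect_lt(abs(mean(x) - 200), 3 * sd(x) / sqrt(n))

  params2 <- nbParams("g1", mu = 50, phi = 0.2)
  eff0 <- new("EffectSpec",
              gamma = matrix(0, n, 1), omega = matrix(0, 1, 1),
              kind = "binary_batch", sigma = 2,
              affected = matrix(FALSE, 1, 1))
  sim2 <- simulateCounts(params2, eff0, "none")
  v <- var(as.numeric(counts(sim2)))
  expect_lt(abs(v - 550) / 550, 0.03)
})

test_that("coupled baseline shares rows with counts for batch-free genes", {
  set.seed(4)
  base <- defaultBaseline(300)
  cfg <- scenarioConfig("batch_plus_biology", "binary", nSamples = 12,
                        nGenes = 300, pctBatchAffected = 10, pctDE = 10)
  sim <- simulateCounts(base, drawEffects(cfg), "coupled")
  truth <- truthLabels(sim)
  free <- truth %in% c("null", "de")
  expect_identical(counts(sim)[free, ], baselineCounts(sim)[free, ])
  expect_false(identical(counts(sim)[!free, ], baselineCounts(sim)[!free, ]))

  # with no effects at all the two assays are identical matrices
  cfg0 <- scenarioConfig("batch_only", "binary", nSamples = 12,
                         nGenes = 300, pctBatchAffected = 0)
  sim0 <- simulateCounts(base, drawEffects(cfg0), "coupled")
  expect_identical(counts(sim0), baselineCounts(sim0))
})

test_that("simulation is deterministic under a fixed seed and labels add up", {
  base <- defaultBaseline(400)
  cfg <- scenarioConfig("batch_plus_biology", c("binary", "continuous"),
                        nSamples = 16, nGenes = 400,
                        pctBatchAffected = 10, pctDE = 5)
  run <- function() {
    set.seed(77)
    simulateCounts(base, drawEffects(cfg), "coupled")
  }
  s1 <- run(); s2 <- run()
  expect_identical(counts(s1), counts(s2))
  expect_identical(baselineCounts(s1), baselineCounts(s2))
  expect_identical(truthLabels(s1), truthLabels(s2))

  truth <- truthLabels(s1)
  nDE <- sum(truth %in% c("de", "both"))
  nBatch <- sum(truth %in% c("batch_affected", "both"))
  expect_identical(nDE, 20L)            # 5% of 400
  # two batch variables, 40 genes each, drawn independently (overlap allowed)
  expect_true(nBatch <= 80L && nBatch >= 40L)
  eff <- effectSpec(s1)
  expect_identical(colSums(eff@affected)[["binary_batch"]], 40)
})

test_that("baseline fixtures load, validate, and round-trip", {
  p <- loadBaseline("default-1000")
  expect_s4_class(p, "NBParams")
  expect_identical(length(p), 1000L)
  expect_identical(geneMeans(loadBaseline("default-1000")), geneMeans(p))

  f <- tempfile(fileext = ".tsv")
  writeBaseline(p, f)
  expect_equal(geneMeans(readBaseline(f)), geneMeans(p), tolerance = 1e-12)
  expect_equal(geneDispersions(readBaseline(f)), geneDispersions(p),
               tolerance = 1e-12)

  writeLines(c("gene_id\tmu_star\tphi_star", "g1\t0\t0.2"), f)
  expect_error(readBaseline(f), "line 2.*mu_star")
  writeLines(c("gene_id\tmu_star\tphi_star", "g1\t5"), f)
  expect_error(readBaseline(f), "line 2")

  # fit from a simulated pilot matrix, write, reload: round trip
  set.seed(5)
  m <- matrix(rnbinom(200 * 20, mu = 30, size = 4), 200,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  fit <- fitBaseline(m)
  writeBaseline(fit, f)
  expect_equal(geneDispersions(readBaseline(f)), geneDispersions(fit),
               tolerance = 1e-12)
})
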