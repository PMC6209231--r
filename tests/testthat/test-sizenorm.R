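# Scale factors, CPM filtering and gene-length normalizations.

test_that("UQ factors match the worked example and its symmetry cases", {
  a <- c(10, 20, 30, 40, 100)
  m <- cbind(A = a, B = 2 * a)
  sf <- uqFactors(m)
  expect_equal(unname(sizeFactors(sf)), c(40 / 60, 80 / 60),
               tolerance = 1e-12)
  expect_equal(normalizeCounts(m, sf)[, "A"], a * 1.5,
               tolerance = 1e-12, ignore_attr = TRUE)

  same <- cbind(a, a, a)
  expect_equal(unname(sizeFactors(uqFactors(same))), rep(1, 3),
               tolerance = 1e-12)

  withZero <- rbind(m, c(0, 0))
  expect_equal(sizeFactors(uqFactors(withZero)), sizeFactors(uqFactors(m)),
               tolerance = 1e-12)
})

test_that("TMM factors are 1 for identical or depth-scaled samples", {
  set.seed(21)
  a <- rnbinom(200, mu = 100, size = 2) + 1
  expect_equal(unname(sizeFactors(tmmFactors(cbind(a, a)))), c(1, 1),
               tolerance = 1e-9)
  f <- sizeFactors(tmmFactors(cbind(a, 2 * a)))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-9)
})

test_that("TMM matches an independent trimmed weighted-mean implementation", {
  set.seed(22)
  a <- rnbinom(40, mu = 200, size = 5) + 1
  b <- a
  b[1:5] <- b[1:5] * 16
  m <- cbind(A = a, B = b)
  got <- sizeFactors(tmmFactors(m, referenceSample = 1))
  expect_equal(unname(got), oracleTMM(m, 1), tolerance = 1e-6)

  # larger random instance, still against the straight-line oracle
  m2 <- matrix(rnbinom(400, mu = 80, size = 2) + 1, 100)
  got2 <- sizeFactors(tmmFactors(m2, referenceSample = 2))
  expect_equal(unname(got2), oracleTMM(m2, 2), tolerance = 1e-6)
})

test_that("TMM and RLE factors are invariant to global rescaling", {
  set.seed(23)
  m <- matrix(rnbinom(300, mu = 60, size = 3) + 1, 75)
  expect_equal(sizeFactors(tmmFactors(m)), sizeFactors(tmmFactors(m * 4)),
               tolerance = 1e-9)
  expect_equal(sizeFactors(rleFactors(m)), sizeFactors(rleFactors(m * 4)),
               tolerance = 1e-12)
})

test_that("RLE matches the closed form and the median-ratio reference", {
  a <- c(10, 20, 30, 40)
  f <- sizeFactors(rleFactors(cbind(A = a, B = 2 * a)))
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(a, a)
  expect_equal(unname(sizeFactors(rleFactors(same))), c(1, 1),
               tolerance = 1e-12)

  # odd all-positive gene count: the median of ratios then equals the
  # reference implementation's exp(median(log ratio))
  set.seed(24)
  m <- matrix(rnbinom(396, mu = 50, size = 2) + 1, 99,
              dimnames = list(NULL, paste0("s", 1:4)))
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(sizeFactors(rleFactors(m))[perm]),
               unname(sizeFactors(rleFactors(m[, perm]))),
               tolerance = 1e-12)
  if (requireNamespace("DESeq2", quietly = TRUE)) {
    ds <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(sizeFactors(rleFactors(m))), unname(ds),
                 tolerance = 1e-10)
  }
  zeroRow <- m
  zeroRow[cbind(seq_len(nrow(m)), sample(1:4, nrow(m), TRUE))] <- 0
  expect_error(rleFactors(zeroRow), "positive in all samples")
})

test_that("CPM definition, filtering and idempotence", {
  m <- matrix(c(1, 999999), 2, 1,
              dimnames = list(c("a", "b"), "s1"))
  expect_equal(cpm(m)["a", "s1"], 1.0, tolerance = 1e-12)

  m2 <- rbind(keep = c(100, 100, 100, 100),
              lose = c(0, 0, 0, 0),
              edge = c(100, 0, 0, 0))
  colnames(m2) <- paste0("s", 1:4)
  kept <- cpmFilter(m2, threshold = 1, minSamples = 3)
  expect_identical(rownames(kept), "keep")
  expect_identical(cpmFilter(kept, 1, 3), kept)

  # hand-computed survivor set on a 6-gene toy
  toy <- matrix(c(10, 0, 3, 0, 1, 500,
                  12, 1, 0, 0, 2, 600,
                  11, 0, 4, 1, 0, 550), 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  libs <- colSums(toy)
  surv <- rownames(toy)[rowSums(sweep(toy, 2, libs, "/") * 1e6 > 1) >= 3]
  expect_identical(rownames(cpmFilter(toy, 1, 3)), surv)
})

test_that("gene-length normalizations follow their unit definitions", {
  m <- matrix(c(100, 200), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lib <- matrix(c(100, 999900), 2, 1,
                dimnames = list(c("a", "b"), "s1"))
  expect_equal(rpkm(lib, c(1000, 1e6))["a", "s1"], 100, tolerance = 1e-12)

  tp <- tpm(m, c(1000, 2000))
  expect_equal(unname(tp[, 1]), c(5e5, 5e5), tolerance = 1e-9)
  set.seed(25)
  big <- matrix(rnbinom(500, mu = 40, size = 2) + 1, 100)
  expect_equal(unname(colSums(tpm(big, runif(100, 200, 5000)))),
               rep(1e6, 5), tolerance = 1e-6)

  expect_equal(erpkm(m, c(1000, 2000), readLength = 1),
               rpkm(m, c(1000, 2000)), tolerance = 1e-12)
  expect_error(erpkm(m, c(1000, 50), readLength = 100), "smaller")
  expect_error(rpkm(m, c(1000, -5)), "lengths")
})
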