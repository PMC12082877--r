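test_that("pearson handles exact linear relations and degenerate input", {
  a <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(pearsonColoc(a, a), 1)
  expect_equal(pearsonColoc(a, -a + 100), -1)
  expect_equal(pearsonColoc(a, 2 * a), 1)
  expect_error(pearsonColoc(a, matrix(5, 2, 2)), "constant")
  expect_error(pearsonColoc(matrix(1), matrix(2)), "at least 2")
})

test_that("Mander's coefficients match hand computation and the oracle", {
  a <- c(10, 20, 0, 0); b <- c(0, 20, 30, 0)
  mm <- mandersCoefficients(a, b, 0, 0)
  expect_equal(unname(mm["M1"]), 20 / 30, tolerance = 1e-12)
  expect_equal(unname(mm["M2"]), 20 / 50, tolerance = 1e-12)
  expect_equal(mm, oracleManders(a, b, 0, 0), tolerance = 1e-12)
  # identical channels, zero thresholds
  x <- c(5, 1, 9, 3)
  expect_equal(unname(mandersCoefficients(x, x, 0, 0)), c(1, 1))
  # spatially disjoint channels
  expect_equal(unname(mandersCoefficients(c(1, 2, 0, 0), c(0, 0, 3, 4))),
               c(0, 0))
  expect_error(mandersCoefficients(c(0, 0), c(1, 2)), "undefined coefficient")
})

test_that("M1/M2 are invariant under positive channel scaling", {
  set.seed(5)
  a <- rpois(400, 20); b <- rpois(400, 15)
  base <- mandersCoefficients(a, b, 8, 6)
  scaled <- mandersCoefficients(3.5 * a, b, 3.5 * 8, 6)
  expect_equal(base, scaled, tolerance = 1e-12)
  scaledB <- mandersCoefficients(a, 0.2 * b, 8, 0.2 * 6)
  expect_equal(base, scaledB, tolerance = 1e-12)
})

test_that("measured M1/M2 on noiseless images match the ground truth", {
  for (seed in c(3, 11)) {
    sim <- simulateMitoImage(imageSimConfig(
      fieldSizePx = c(128, 128), nObjects = 8, integrityProb = 0.7,
      seed = seed, noisePoisson = FALSE, noiseGaussianSd = 0,
      backgroundLevel = 0))
    mm <- mandersCoefficients(sim$truth$immClean, sim$truth$ommClean, 0, 0)
    expect_equal(unname(mm["M1"]), sim$truth$m1, tolerance = 1e-9)
    expect_equal(unname(mm["M2"]), sim$truth$m2, tolerance = 1e-9)
  }
})

test_that("Costes threshold equals the exhaustive per-level oracle", {
  # background cluster + linearly related signal cluster
  set.seed(2)
  a <- matrix(c(rnorm(900, 20, 3), rnorm(100, 200, 10)), 25)
  b <- matrix(c(rnorm(900, 20, 3), a[901:1000] + rnorm(100, 0, 5)), 25)
  ct <- costesAutoThreshold(a, b)
  ref <- oracleCostes(a, b)
  expect_identical(ct@floor, ref$floor)
  expect_equal(ct@tA, ref$tA, tolerance = 1e-12)
  expect_equal(ct@tB, ref$tB, tolerance = 1e-12)
  expect_lte(ct@rBelow, 0)
  expect_gt(ct@tA, min(a)); expect_lt(ct@tA, 200)
  # synthetic count images
  for (seed in 1:6) {
    im <- syntheticCountImage(seed)
    ct <- costesAutoThreshold(im$a, im$b)
    ref <- oracleCostes(im$a, im$b)
    expect_identical(ct@floor, ref$floor)
    expect_equal(ct@tA, ref$tA, tolerance = 1e-12)
  }
})

test_that("identical channels on a ramp hit the floor flag", {
  r <- matrix(seq(1, 100, length.out = 400), 20)
  ct <- costesAutoThreshold(r, r + 0.5 * r)
  expect_true(ct@floor)
  expect_equal(ct@tA, min(r), tolerance = 1e-12)
  expect_error(costesAutoThreshold(r, matrix(5, 20, 20)), "degenerate")
})

test_that("channel-swapping symmetric data swaps the thresholds", {
  set.seed(9)
  base <- c(rnorm(800, 30, 4), rnorm(200, 150, 12))
  noise <- rnorm(1000, 0, 4)
  a <- base + noise; b <- base - noise   # symmetric roles, slope 1
  ctAB <- costesAutoThreshold(a, b)
  ctBA <- costesAutoThreshold(b, a)
  ref <- oracleCostes(b, a)
  expect_equal(ctBA@tA, ref$tA, tolerance = 1e-12)
  expect_equal(ctAB@slope, 1 / ctBA@slope, tolerance = 1e-8)
  # swapped-role threshold agrees with the original up to the flatness of
  # the sub-threshold correlation near its zero crossing
  expect_lt(abs(ctBA@tA - ctAB@tB), 10)
})

test_that("randomization p-value detects self-alignment and respects its support", {
  sim <- simulateMitoImage(imageSimConfig(fieldSizePx = c(80, 80),
                                          nObjects = 6, seed = 9))
  a <- immChannel(sim$image); b <- ommChannel(sim$image)
  rr <- costesRandomization(a, b, blockSizePx = 5, nRounds = 999, seed = 2)
  expect_lte(rr$p, 0.01)
  expect_gte(rr$p, 1 / 1000)  # add-one estimator never reaches 0
  expect_gt(rr$rObs, rr$nullMean + 5 * rr$nullSd)
  r1 <- costesRandomization(a, b, blockSizePx = 5, nRounds = 1, seed = 3)
  expect_true(r1$p %in% c(1 / 2, 1))
  expect_error(costesRandomization(a, b, blockSizePx = 200), "block-size")
})

test_that("cytofluorogram exports exact pixel pairs", {
  a <- matrix(c(1, 2, 3), 1); b <- 2 * a
  cf <- cytofluorogram(a, b)
  expect_identical(nrow(cf), 3L)
  expect_true(all(cf$B == 2 * cf$A))
  sim <- simulateMitoImage(imageSimConfig(fieldSizePx = c(64, 64),
                                          nObjects = 4, seed = 13))
  cf2 <- cytofluorogram(immChannel(sim$image), ommChannel(sim$image))
  expect_equal(stats::cor(cf2$A, cf2$B),
               pearsonColoc(immChannel(sim$image), ommChannel(sim$image)),
               tolerance = 1e-12)
})

test_that("mean M1/M2 fall monotonically with integrity loss", {
  levels <- seq(1, 0.2, by = -0.2)
  m1m2 <- sapply(levels, function(p) {
    vals <- sapply(1:3, function(seed) {
      s <- simulateMitoImage(imageSimConfig(
        fieldSizePx = c(128, 128), nObjects = 10, integrityProb = p,
        seed = seed, noisePoisson = FALSE, noiseGaussianSd = 0,
        backgroundLevel = 0))
      mandersCoefficients(s$truth$immClean, s$truth$ommClean, 0, 0)
    })
    rowMeans(vals)
  })
  # series runs from intact to mostly broken: scores must fall with it
  expect_lte(stats::cor(seq_along(levels), m1m2[1, ], method = "spearman"),
             -0.9)
  expect_lte(stats::cor(seq_along(levels), m1m2[2, ], method = "spearman"),
             -0.9)
})
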