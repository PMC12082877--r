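noiseless <- function(...) imageSimConfig(..., noisePoisson = FALSE,
                                          noiseGaussianSd = 0,
                                          backgroundLevel = 0)

test_that("same config and seed give bit-identical images and truth", {
  cfg <- imageSimConfig(fieldSizePx = c(96, 96), nObjects = 5, seed = 21)
  s1 <- simulateMitoImage(cfg)
  s2 <- simulateMitoImage(cfg)
  expect_identical(ommChannel(s1$image), ommChannel(s2$image))
  expect_identical(immChannel(s1$image), immChannel(s2$image))
  expect_identical(s1$truth$objects, s2$truth$objects)
  cc <- cohortSimConfig(seed = 21)
  expect_identical(simulateCohort(cc), simulateCohort(cc))
})

test_that("intact objects give high analytic overlap, disjoint shells give zero", {
  for (seed in 1:3) {
    s <- simulateMitoImage(noiseless(fieldSizePx = c(128, 128),
                                     nObjects = 6, integrityProb = 1,
                                     seed = seed))
    expect_gte(s$truth$m1, 0.8)
    expect_gte(s$truth$m2, 0.8)
  }
  # shell offset far beyond the profile truncation reach: disjoint supports
  s <- simulateMitoImage(noiseless(fieldSizePx = c(160, 160), nObjects = 4,
                                   integrityProb = 0, singleChannelBias = 1,
                                   shellOffsetPx = 12, seed = 5))
  expect_identical(s$truth$m1, 0)
  expect_identical(s$truth$m2, 0)
})

test_that("stored analytic M1/M2 are recomputable by a pixel-sum oracle", {
  for (seed in c(2, 9)) {
    s <- simulateMitoImage(noiseless(fieldSizePx = c(128, 128),
                                     nObjects = 8, integrityProb = 0.6,
                                     seed = seed))
    om <- oracleManders(s$truth$immClean, s$truth$ommClean, 0, 0)
    expect_equal(unname(om["M1"]), s$truth$m1, tolerance = 1e-12)
    expect_equal(unname(om["M2"]), s$truth$m2, tolerance = 1e-12)
  }
})

test_that("lowering integrity_prob never raises analytic M1 + M2", {
  for (seed in 1:4) {
    tot <- vapply(seq(1, 0, by = -0.2), function(p) {
      s <- simulateMitoImage(noiseless(fieldSizePx = c(128, 128),
                                       nObjects = 10, integrityProb = p,
                                       seed = seed))
      s$truth$m1 + s$truth$m2
    }, numeric(1))
    expect_true(all(diff(tot) <= 1e-12))
  }
})

test_that("ground truth bookkeeping and placement errors behave", {
  cfg <- noiseless(fieldSizePx = c(128, 128), nObjects = 7, seed = 3)
  s <- simulateMitoImage(cfg)
  expect_identical(nrow(s$truth$objects), 7L)
  expect_true(all(s$truth$objects$channels %in%
                  c("both", "OMM_only", "IMM_only")))
  # objects longer than the field cannot be placed
  expect_error(simulateMitoImage(noiseless(fieldSizePx = c(16, 16),
                                           nObjects = 1,
                                           lengthRangeUm = c(2, 2.2),
                                           seed = 1)),
               "placement")
  expect_error(imageSimConfig(integrityProb = 1.4), "probabilities")
  expect_error(imageSimConfig(lengthRangeUm = c(3, 1)), "ordered")
})

test_that("cohort tables reproduce the study design row counts", {
  tab <- simulateCohort(cohortSimConfig(seed = 2))
  counts <- table(tab$genotype, tab$sex)
  expect_identical(unname(counts["WT", "male"]), 90L)
  expect_identical(unname(counts["WT", "female"]), 60L)
  expect_identical(unname(counts["KO", "male"]), 120L)
  expect_identical(unname(counts["KO", "female"]), 90L)
  expect_identical(length(unique(tab$animal_id)), 14L)
  # each animal maps to exactly one cell
  cellsPerAnimal <- tapply(interaction(tab$genotype, tab$sex),
                           tab$animal_id, function(x) length(unique(x)))
  expect_true(all(cellsPerAnimal == 1))
})

test_that("zero-noise cohorts hit the cell means exactly", {
  cfg <- cohortSimConfig(sdAnimal = c(aspect_ratio = 0, m2 = 0,
                                      mito_count = 0),
                         sdResid = c(aspect_ratio = 0, m2 = 0,
                                     mito_count = 0),
                         seed = 8)
  tab <- simulateCohort(cfg)
  cellIdx <- as.integer(interaction(tab$genotype, tab$sex,
                                    lex.order = FALSE))
  # interaction order: WT.male KO.male WT.female KO.female
  lookup <- c(1, 3, 2, 4)  # map to config cell order WTm WTf KOm KOf
  for (rsp in c("aspect_ratio", "m2", "mito_count"))
    expect_equal(tab[[rsp]],
                 cfg$cellMeans[[rsp]][lookup[cellIdx]], tolerance = 0)
  expect_error(cohortSimConfig(nAnimalsPerGroup = 0), "config error")
  expect_error(cohortSimConfig(neuronsPerAnimal = 0), "config error")
})

test_that("between-animal variance of animal means matches theory", {
  # var(animal mean) = sd_animal^2 + sd_resid^2 / neurons_per_animal
  sdA <- 0.1; sdR <- 0.4; m <- 20L
  cfg0 <- cohortSimConfig(neuronsPerAnimal = m,
                          cellMeans = list(aspect_ratio = rep(3, 4),
                                           m2 = rep(0.5, 4),
                                           mito_count = rep(60, 4)),
                          sdAnimal = c(aspect_ratio = sdA, m2 = 0.02,
                                       mito_count = 5),
                          sdResid = c(aspect_ratio = sdR, m2 = 0.06,
                                      mito_count = 12))
  vs <- vapply(1:200, function(rep) {
    cfg <- cfg0; cfg$seed <- rep
    tab <- simulateCohort(cfg)
    am <- tapply(tab$aspect_ratio, tab$animal_id, mean)
    cell <- tapply(as.character(interaction(tab$genotype, tab$sex)),
                   tab$animal_id, unique)
    mean(vapply(unique(cell), function(cl) {
      v <- am[cell == cl]
      sum((v - mean(v))^2) / (length(v) - 1)
    }, numeric(1)))
  }, numeric(1))
  expected <- sdA^2 + sdR^2 / m
  expect_lt(abs(mean(vs) - expected) / expected, 0.1)
})

test_that("image, truth and config files round-trip through disk", {
  td <- withr::local_tempdir()
  cfg <- imageSimConfig(fieldSizePx = c(64, 64), nObjects = 3, seed = 12)
  s <- simulateMitoImage(cfg)
  p <- file.path(td, "img.tif")
  writeMitoTiff(s$image, p)
  img2 <- readMitoTiff(p)
  expect_equal(ommChannel(img2), round(ommChannel(s$image)))
  expect_equal(immChannel(img2), round(immChannel(s$image)))
  writeGroundTruthCsv(s$truth, file.path(td, "truth.csv"))
  gt <- read.csv(file.path(td, "truth.csv"))
  expect_identical(nrow(gt), 3L)
  expect_equal(gt$analytic_m1[1], s$truth$m1, tolerance = 1e-12)
  writeSimConfig(cfg, file.path(td, "cfg.yaml"))
  expect_identical(readSimConfig(file.path(td, "cfg.yaml")), cfg)
  ccfg <- cohortSimConfig(seed = 4)
  writeSimConfig(ccfg, file.path(td, "ccfg.yaml"))
  cfg2 <- readSimConfig(file.path(td, "ccfg.yaml"))
  expect_identical(simulateCohort(cfg2), simulateCohort(ccfg))
})
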