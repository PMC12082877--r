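quietCohort <- function(seed = 1, ...) simulateCohort(cohortSimConfig(seed = seed, ...))

test_that("near-zero-noise cohorts recover the programmed cell means", {
  cfg <- cohortSimConfig(sdAnimal = c(aspect_ratio = 1e-10, m2 = 1e-10,
                                      mito_count = 1e-10),
                         sdResid = c(aspect_ratio = 1e-10, m2 = 1e-10,
                                     mito_count = 1e-10),
                         cellMeans = list(aspect_ratio = c(2, 2.2, 2.4, 2.6),
                                          m2 = c(0.9, 0.8, 0.7, 0.6),
                                          mito_count = c(50, 55, 60, 65)),
                         seed = 1)
  tab <- simulateCohort(cfg)
  fit <- fitMitoLMM(tab, "m2")
  em <- estimatedMarginalMeans(fit)
  key <- paste(em$genotype, em$sex, sep = "_")
  want <- c(WT_male = 0.9, WT_female = 0.8, KO_male = 0.7, KO_female = 0.6)
  expect_equal(unname(want[key]), em$emmean, tolerance = 1e-6)
  expect_lt(fit@sigmaU, 1e-6)
})

test_that("balanced-design REML equals the closed-form moment estimators", {
  cfg <- cohortSimConfig(nAnimalsPerGroup = 3L, neuronsPerAnimal = 12L,
                         sdAnimal = c(aspect_ratio = 0.5, m2 = 0.05,
                                      mito_count = 8),
                         sdResid = c(aspect_ratio = 1.0, m2 = 0.08,
                                     mito_count = 15),
                         cellMeans = list(aspect_ratio = c(3, 4, 5, 6),
                                          m2 = c(0.5, 0.5, 0.5, 0.5),
                                          mito_count = c(60, 60, 60, 60)),
                         seed = 6)
  tab <- simulateCohort(cfg)
  fit <- fitMitoLMM(tab, "aspect_ratio")
  mom <- oracleBalancedMoM(tab, "aspect_ratio")
  expect_equal(fit@sigmaE^2, mom$sigmaE2, tolerance = 1e-6)
  expect_equal(fit@sigmaU^2, mom$sigmaU2, tolerance = 1e-6)
})

test_that("the fit agrees with lme4 and emmeans on the study design", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("emmeans")
  tab <- quietCohort(seed = 7)
  fit <- fitMitoLMM(tab, "m2")
  lf <- lme4::lmer(m2 ~ genotype * sex + (1 | animal_id), data = tab,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit@sigmaU, vc$sdcor[1], tolerance = 1e-5)
  expect_equal(fit@sigmaE, vc$sdcor[2], tolerance = 1e-5)
  expect_equal(unname(fit@beta), unname(lme4::fixef(lf)), tolerance = 1e-6)
  em <- as.data.frame(emmeans::emmeans(lf, ~ genotype * sex))
  ours <- estimatedMarginalMeans(fit)
  merged <- merge(ours, em, by = c("genotype", "sex"))
  expect_equal(merged$emmean.x, merged$emmean.y, tolerance = 1e-6)
  expect_equal(merged$se, merged$SE, tolerance = 1e-5)
})

test_that("unbalanced-cell marginal means match a dense GLS oracle", {
  cfg <- cohortSimConfig(neuronsPerAnimal = c(30L, 7L, 24L, 13L), seed = 12)
  tab <- simulateCohort(cfg)
  fit <- fitMitoLMM(tab, "aspect_ratio")
  # dense GLS at the estimated variance components
  X <- stats::model.matrix(~ genotype * sex, tab)
  Z <- stats::model.matrix(~ factor(animal_id) - 1, tab)
  V <- fit@sigmaU^2 * tcrossprod(Z) + fit@sigmaE^2 * diag(nrow(tab))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% tab$aspect_ratio)
  grid <- expand.grid(genotype = levels(tab$genotype),
                      sex = levels(tab$sex))
  L <- stats::model.matrix(~ genotype * sex, grid)
  expect_equal(unname(estimatedMarginalMeans(fit)$emmean),
               unname(drop(L %*% beta)), tolerance = 1e-8)
  expect_gt(fit@sigmaU, 0)
  # the GLS mean differs from the raw pooled mean under imbalance
  raw <- tapply(tab$aspect_ratio,
                interaction(tab$genotype, tab$sex), mean)
  expect_false(isTRUE(all.equal(unname(raw)[1:4],
                                estimatedMarginalMeans(fit)$emmean,
                                tolerance = 1e-8)))
})

test_that("lambda forced to zero reproduces ordinary two-way ANOVA", {
  tab <- quietCohort(seed = 4)
  fit0 <- fitMitoLMM(tab, "m2", lambdaFixed = 0)
  lmfit <- stats::lm(m2 ~ genotype * sex, data = tab)
  expect_equal(unname(fit0@beta), unname(stats::coef(lmfit)),
               tolerance = 1e-8)
  s2 <- sum(stats::residuals(lmfit)^2) / stats::df.residual(lmfit)
  expect_equal(fit0@sigmaE^2, s2, tolerance = 1e-8)
})

test_that("the profiled REML optimum beats a 64-point lambda grid", {
  tab <- quietCohort(seed = 19)
  fit <- fitMitoLMM(tab, "aspect_ratio")
  X <- stats::model.matrix(~ genotype * sex, tab)
  devHat <- oracleRemlDeviance(fit@lambda, X, tab$aspect_ratio,
                               tab$animal_id)
  grid <- exp(seq(log(1e-6), log(1e6), length.out = 64))
  devGrid <- vapply(grid, oracleRemlDeviance, numeric(1), design = X,
                    y = tab$aspect_ratio, animal = tab$animal_id)
  expect_lte(devHat, min(devGrid) + 1e-6)
})

test_that("fits are invariant to animal relabeling and row order", {
  tab <- quietCohort(seed = 23)
  fit <- fitMitoLMM(tab, "m2")
  tab2 <- tab[sample(nrow(tab)), ]
  tab2$animal_id <- paste0("zz_", tab2$animal_id)
  fit2 <- fitMitoLMM(tab2, "m2")
  # summation order over animals differs, so agreement is to solver
  # tolerance, not bit level
  expect_equal(fit@beta, fit2@beta, tolerance = 1e-6)
  expect_equal(fit@sigmaU, fit2@sigmaU, tolerance = 1e-5)
  expect_equal(fit@sigmaE, fit2@sigmaE, tolerance = 1e-6)
})

test_that("contrast tables carry 6 Tukey-adjusted pairwise comparisons", {
  tab <- quietCohort(seed = 3)
  fit <- fitMitoLMM(tab, "m2")
  ct <- tukeyContrasts(fit)
  expect_identical(nrow(ct), 6L)
  expect_true(all(ct$p_adjusted >= ct$p_value))
  expect_true(all(ct$p_adjusted > 0 & ct$p_adjusted <= 1))
  expect_true(all(ct$df == fit@nAnimals - 4))
})

test_that("degenerate designs raise the documented errors", {
  tab <- quietCohort(seed = 2)
  oneCell <- tab[tab$genotype == "WT" & tab$sex == "male", ]
  expect_error(fitMitoLMM(oneCell, "m2"), "design error")
  oneAnimal <- tab[tab$animal_id == tab$animal_id[1], ]
  expect_error(fitMitoLMM(oneAnimal, "m2"), "error")
})

test_that("the null family-wise error rate is close to nominal", {
  cfg0 <- cohortSimConfig(cellMeans = list(aspect_ratio = rep(3, 4),
                                           m2 = rep(0.5, 4),
                                           mito_count = rep(60, 4)))
  rej <- vapply(1:400, function(rep) {
    cfg <- cfg0; cfg$seed <- 10000 + rep
    tab <- simulateCohort(cfg)
    any(tukeyContrasts(fitMitoLMM(tab, "aspect_ratio"))$p_adjusted <= 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
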