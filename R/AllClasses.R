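#' Two-channel mitochondrial image
#'
#' Container for one confocal optical section carrying an outer-membrane
#' (OMM, e.g. TOMM20) channel and an inner-membrane/matrix (IMM, e.g. PMPCB)
#' channel on the same pixel grid, plus the lateral pixel calibration.
#'
#' @slot omm numeric matrix, OMM channel intensities (finite, >= 0).
#' @slot imm numeric matrix, IMM/matrix channel intensities, same dim as omm.
#' @slot pixelSize single positive numeric, lateral pixel size in micrometres.
#'
#' @seealso [MitoImage()] for the constructor, [ommChannel()], [immChannel()],
#'   [pixelSize()] for accessors.
#' @export
setClass("MitoImage",
  representation(omm = "matrix", imm = "matrix", pixelSize = "numeric"))

setValidity("MitoImage", function(object) {
  msg <- character()
  if (!is.numeric(object@omm) || !is.numeric(object@imm))
    msg <- c(msg, "both channels must be numeric matrices")
  if (!identical(dim(object@omm), dim(object@imm)))
    msg <- c(msg, "channels must share the same dimensions")
  if (any(!is.finite(object@omm)) || any(!is.finite(object@imm)))
    msg <- c(msg, "intensities must be finite")
  else if (any(object@omm < 0) || any(object@imm < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MitoImage
#'
#' @param omm,imm numeric matrices of identical dimension holding the OMM and
#'   IMM/matrix channel intensities.
#' @param pixelSize lateral pixel size in micrometres. The default 0.0467
#'   um/px corresponds to the calibration in which a 15 px object spans
#'   0.7 um.
#' @return A [MitoImage-class] object.
#' @examples
#' img <- MitoImage(matrix(runif(64), 8), matrix(runif(64), 8))
#' dim(ommChannel(img))
#' @export
MitoImage <- function(omm, imm, pixelSize = 0.0467) {
  new("MitoImage", omm = as.matrix(omm), imm = as.matrix(imm),
      pixelSize = as.numeric(pixelSize))
}

setMethod("show", "MitoImage", function(object) {
  d <- dim(object@omm)
  cat("MitoImage:", d[1], "x", d[2], "px,",
      format(object@pixelSize, digits = 4), "um/px\n")
  cat("  OMM range:", format(range(object@omm), digits = 4), "\n")
  cat("  IMM range:", format(range(object@imm), digits = 4), "\n")
})

#' Costes automatic threshold result
#'
#' Paired channel thresholds obtained by descending along the orthogonal
#' (total-least-squares) regression line of channel B on channel A until the
#' Pearson correlation of the sub-threshold pixels is no longer positive.
#'
#' @slot slope,intercept orthogonal regression of B on A.
#' @slot tA,tB paired thresholds with tB = slope * tA + intercept.
#' @slot rBelow Pearson correlation of sub-threshold pixels at the stopping
#'   point (NA when the floor was reached without a sign change).
#' @slot floor logical; TRUE when the scan reached the minimum intensity of A
#'   without finding a non-positive sub-threshold correlation.
#' @export
setClass("CostesThreshold",
  representation(slope = "numeric", intercept = "numeric",
                 tA = "numeric", tB = "numeric",
                 rBelow = "numeric", floor = "logical"))

setMethod("show", "CostesThreshold", function(object) {
  cat("CostesThreshold: T_A =", format(object@tA, digits = 5),
      ", T_B =", format(object@tB, digits = 5), "\n")
  cat("  regression B =", format(object@slope, digits = 5), "* A +",
      format(object@intercept, digits = 5), "\n")
  cat("  r(sub-threshold) =", format(object@rBelow, digits = 4),
      if (object@floor) " [floor reached]" else "", "\n", sep = "")
})

#' Per-image colocalization result
#'
#' Membrane-integrity readout for one two-channel image: Pearson correlation,
#' thresholded Mander's coefficients, the thresholds used, and the Costes
#' block-randomization p-value. Channel A is the IMM/matrix marker and
#' channel B the OMM marker, so M1 measures IMM-to-OMM overlap and M2 the
#' converse.
#'
#' @slot pearson image-wide Pearson correlation of the two channels.
#' @slot m1,m2 thresholded Mander's coefficients in [0, 1].
#' @slot thresholds a [CostesThreshold-class] (or fixed pair wrapped in one).
#' @slot randomizationP p-value of the Costes block-randomization test
#'   (NA when the test was not run).
#' @slot nRounds,blockSize randomization settings used.
#' @export
setClass("ColocResult",
  representation(pearson = "numeric", m1 = "numeric", m2 = "numeric",
                 thresholds = "CostesThreshold",
                 randomizationP = "numeric",
                 nRounds = "integer", blockSize = "integer"))

setValidity("ColocResult", function(object) {
  msg <- character()
  ok01 <- function(x) all(!is.finite(x) | (x >= 0 & x <= 1))
  if (!ok01(object@m1) || !ok01(object@m2))
    msg <- c(msg, "M1 and M2 must lie in [0, 1]")
  if (is.finite(object@pearson) &&
      (object@pearson < -1 - 1e-12 || object@pearson > 1 + 1e-12))
    msg <- c(msg, "pearson must lie in [-1, 1]")
  if (is.finite(object@randomizationP) &&
      (object@randomizationP <= 0 || object@randomizationP > 1))
    msg <- c(msg, "randomization p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult\n")
  cat("  Pearson r:", format(object@pearson, digits = 4), "\n")
  cat("  M1 (IMM->OMM):", format(object@m1, digits = 4),
      " M2 (OMM->IMM):", format(object@m2, digits = 4), "\n")
  cat("  thresholds: T_A =", format(object@thresholds@tA, digits = 4),
      ", T_B =", format(object@thresholds@tB, digits = 4), "\n")
  if (is.finite(object@randomizationP))
    cat("  randomization p:", format(object@randomizationP, digits = 4),
        sprintf("(%d rounds, %d px blocks)\n",
                object@nRounds, object@blockSize))
})

#' Random-intercept linear mixed model fit
#'
#' REML fit of y = X beta + u_animal + e for one per-neuron response, with
#' sex, genotype and their interaction as fixed effects and animal as a
#' random intercept. The between-animal/residual variance ratio is profiled
#' out and optimized in one dimension.
#'
#' @slot response name of the modelled response column.
#' @slot beta named fixed-effect estimates.
#' @slot vcovBeta covariance matrix of the fixed effects.
#' @slot sigmaU,sigmaE between-animal and residual standard deviations.
#' @slot lambda profiled variance ratio sigmaU^2 / sigmaE^2.
#' @slot remlLogLik REML log-likelihood at the optimum.
#' @slot df error degrees of freedom used for contrasts (animals - cells).
#' @slot cellMeans data.frame of estimated marginal means per sex x genotype
#'   cell with standard errors.
#' @slot nObs,nAnimals problem sizes.
#' @export
setClass("MitoLMMFit",
  representation(response = "character", beta = "numeric",
                 vcovBeta = "matrix", sigmaU = "numeric", sigmaE = "numeric",
                 lambda = "numeric", remlLogLik = "numeric", df = "numeric",
                 cellMeans = "data.frame", nObs = "integer",
                 nAnimals = "integer"))

setValidity("MitoLMMFit", function(object) {
  msg <- character()
  if (object@sigmaU < 0 || object@sigmaE < 0)
    msg <- c(msg, "variance components must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MitoLMMFit", function(object) {
  cat("MitoLMMFit:", object@response, "~ genotype * sex + (1 | animal)\n")
  cat(sprintf("  n = %d neurons, %d animals; REML logLik = %.3f\n",
              object@nObs, object@nAnimals, object@remlLogLik))
  cat(sprintf("  sigma_animal = %.4g, sigma_resid = %.4g\n",
              object@sigmaU, object@sigmaE))
  cat("  cell means:\n")
  print(object@cellMeans, row.names = FALSE)
})

#' Factor analysis of mixed data result
#'
#' Joint dimension reduction of quantitative per-neuron metrics (PCA-like,
#' standardized) and qualitative labels (MCA-like, indicator scaling), with
#' eigenvalues, per-variable contributions, the correlation-circle
#' coordinates of the quantitative variables, and per-row factor scores.
#'
#' @slot eigenvalues nonincreasing eigenvalues, one per nontrivial dimension.
#' @slot percentVar,cumPercent percent and cumulative percent of total
#'   inertia per dimension.
#' @slot contributions matrix (variables x dimensions) of percent
#'   contributions; categories of a qualitative variable are aggregated.
#' @slot quantCor matrix (quantitative variables x dimensions) of
#'   correlations between each variable and the row scores.
#' @slot rowScores matrix (rows x dimensions) of factor scores.
#' @slot quantVars,qualVars names of the input variables.
#' @slot totalInertia sum of eigenvalues, equal to K + sum(c_q - 1).
#' @export
setClass("FAMDResult",
  representation(eigenvalues = "numeric", percentVar = "numeric",
                 cumPercent = "numeric", contributions = "matrix",
                 quantCor = "matrix", rowScores = "matrix",
                 quantVars = "character", qualVars = "character",
                 totalInertia = "numeric"))

setValidity("FAMDResult", function(object) {
  msg <- character()
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be >= 0")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE) &&
      any(diff(object@eigenvalues) > 1e-8))
    msg <- c(msg, "eigenvalues must be nonincreasing")
  if (abs(sum(object@percentVar) - 100) > 1e-6)
    msg <- c(msg, "percent variance must sum to 100")
  if (any(abs(colSums(object@contributions) - 100) > 1e-6))
    msg <- c(msg, "contributions must sum to 100 per dimension")
  if (any(abs(object@quantCor) > 1 + 1e-8))
    msg <- c(msg, "correlation-circle coordinates must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FAMDResult", function(object) {
  k <- length(object@eigenvalues)
  cat("FAMDResult:", nrow(object@rowScores), "rows,",
      length(object@quantVars), "quantitative +",
      length(object@qualVars), "qualitative variables\n")
  cat("  ", k, "nontrivial dimensions, total inertia",
      format(object@totalInertia, digits = 6), "\n")
  tab <- data.frame(dim = seq_len(k),
                    eigenvalue = round(object@eigenvalues, 4),
                    percent = round(object@percentVar, 2),
                    cumulative = round(object@cumPercent, 2))
  print(utils::head(tab, 5), row.names = FALSE)
  if (k > 5) cat("  ...\n")
})
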