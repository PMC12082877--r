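#' Configuration for the synthetic two-channel mitochondria image generator
#'
#' Defines a field of capsule-shaped (rod/ellipse-like) mitochondrial objects
#' rendered in two partially overlapping channels: the IMM/matrix channel as
#' a filled capsule with a soft (Gaussian) edge, and the OMM channel as a
#' Gaussian membrane ridge at the capsule boundary offset outward by
#' `shellOffsetPx`. An integrity parameter controls whether an object is
#' rendered in both channels (intact) or in a single channel only (membrane
#' integrity lost: OMM-only or IMM-only objects).
#'
#' @param fieldSizePx integer pair, image size (rows, cols) in pixels.
#' @param pixelSizeUm lateral pixel size in micrometres. Default 0.0467,
#'   the calibration at which a 15 px object spans 0.7 um.
#' @param nObjects number of mitochondrial objects to place.
#' @param lengthRangeUm ordered positive pair within (0, 5]; object lengths
#'   are drawn uniformly from this interval. Default 0.7--2.2 um, the size
#'   range of individual mitochondria under the 15/45 px rules.
#' @param widthUm capsule width (diameter) in micrometres.
#' @param integrityProb probability in [0, 1] that an object is intact,
#'   i.e. rendered in BOTH channels.
#' @param singleChannelBias given a non-intact object, probability that it is
#'   OMM-only (vs IMM-only).
#' @param shellOffsetPx nonnegative offset (px) of the OMM membrane ridge
#'   outward from the IMM capsule boundary.
#' @param edgeSigmaPx Gaussian cross-section width (px) of the membrane ridge
#'   and of the IMM edge roll-off; emulates the lateral blur of confocal
#'   imaging. Profiles are truncated at 3 * edgeSigmaPx.
#' @param peakIntensity peak per-object signal in counts.
#' @param noiseGaussianSd additive Gaussian read-noise SD (0 disables).
#' @param noisePoisson logical; Poisson-resample the noiseless signal
#'   (shot noise).
#' @param backgroundLevel constant background offset in counts.
#' @param seed integer RNG seed; the same config and seed give bit-identical
#'   output.
#' @return A validated list of class `ImageSimConfig`.
#' @seealso [simulateMitoImage()]
#' @export
imageSimConfig <- function(fieldSizePx = c(256L, 256L),
                           pixelSizeUm = 0.0467,
                           nObjects = 25L,
                           lengthRangeUm = c(0.7, 2.2),
                           widthUm = 0.28,
                           integrityProb = 1,
                           singleChannelBias = 0.5,
                           shellOffsetPx = 1L,
                           edgeSigmaPx = 1.5,
                           peakIntensity = 120,
                           noiseGaussianSd = 2,
                           noisePoisson = TRUE,
                           backgroundLevel = 5,
                           seed = 1L) {
  stopifnot(length(fieldSizePx) == 2L, all(fieldSizePx >= 8),
            length(pixelSizeUm) == 1L, pixelSizeUm > 0,
            length(nObjects) == 1L, nObjects >= 1,
            length(lengthRangeUm) == 2L)
  if (!(lengthRangeUm[1] > 0 && lengthRangeUm[2] <= 5 &&
        lengthRangeUm[1] <= lengthRangeUm[2]))
    stop("lengthRangeUm must be an ordered positive interval within (0, 5]")
  if (widthUm <= 0) stop("widthUm must be positive")
  for (p in c(integrityProb, singleChannelBias))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]")
  if (shellOffsetPx < 0) stop("shellOffsetPx must be >= 0")
  if (edgeSigmaPx <= 0) stop("edgeSigmaPx must be positive")
  if (noiseGaussianSd < 0 || backgroundLevel < 0)
    stop("noise parameters must be >= 0")
  structure(list(
    fieldSizePx = as.integer(fieldSizePx), pixelSizeUm = pixelSizeUm,
    nObjects = as.integer(nObjects), lengthRangeUm = lengthRangeUm,
    widthUm = widthUm, integrityProb = integrityProb,
    singleChannelBias = singleChannelBias,
    shellOffsetPx = as.numeric(shellOffsetPx), edgeSigmaPx = edgeSigmaPx,
    peakIntensity = peakIntensity, noiseGaussianSd = noiseGaussianSd,
    noisePoisson = isTRUE(noisePoisson), backgroundLevel = backgroundLevel,
    seed = as.integer(seed)), class = "ImageSimConfig")
}

# cross-section profiles: distance d from the capsule medial segment,
# capsule radius r, membrane ridge radius rm, Gaussian width s, reach = 3 s
.immProfile <- function(d, r, s, reach) {
  out <- numeric(length(d))
  inside <- d <= r
  edge <- !inside & d <= r + reach
  out[inside] <- 1
  out[edge] <- exp(-(d[edge] - r)^2 / (2 * s^2))
  out
}

.ommProfile <- function(d, rm, s, reach) {
  out <- numeric(length(d))
  on <- abs(d - rm) <= reach
  out[on] <- exp(-(d[on] - rm)^2 / (2 * s^2))
  out
}

#' Generate a ground-truthed synthetic two-channel mitochondria image
#'
#' Places `nObjects` capsules at uniform random positions and orientations,
#' renders each in the channel(s) dictated by its integrity draw, applies
#' optional Poisson shot noise and Gaussian read noise over a constant
#' background, and returns both the noisy [MitoImage-class] and the ground
#' truth: per-object records, the noiseless channel grids, and the analytic
#' Mander's M1/M2 overlap fractions computed on the noiseless grids
#' (support thresholds at zero).
#'
#' Integrity draws are nested: with the placement seed fixed, lowering
#' `integrityProb` only ever removes objects from the intact set, so the
#' analytic M1 + M2 never increases.
#'
#' @param config an [imageSimConfig()].
#' @return A list with elements `image` (a [MitoImage-class]) and `truth`
#'   (class `MitoGroundTruth`): `objects` data.frame (center, orientation,
#'   length, channel membership), `ommClean`/`immClean` noiseless grids,
#'   and analytic `m1`, `m2`.
#' @examples
#' sim <- simulateMitoImage(imageSimConfig(fieldSizePx = c(96, 96),
#'                                         nObjects = 4, seed = 7))
#' sim$truth$m1
#' @export
simulateMitoImage <- function(config) {
  stopifnot(inherits(config, "ImageSimConfig"))
  set.seed(config$seed)
  nr <- config$fieldSizePx[1]; nc <- config$fieldSizePx[2]
  px <- config$pixelSizeUm
  r <- config$widthUm / 2 / px
  s <- config$edgeSigmaPx
  reach <- 3 * s
  rm. <- r + config$shellOffsetPx
  n <- config$nObjects

  lenUm <- stats::runif(n, config$lengthRangeUm[1], config$lengthRangeUm[2])
  lenPx <- lenUm / px
  halfSeg <- pmax((lenPx - 2 * r) / 2, 0)
  margin <- halfSeg + max(r, rm.) + reach + 1
  if (any(2 * margin + 2 > min(nr, nc)))
    stop("placement error: objects of length up to ",
         format(max(lenUm), digits = 3), " um do not fit a ",
         nr, "x", nc, " px field at ", format(px, digits = 4), " um/px")
  cy <- stats::runif(n, 1 + margin, nr - margin)
  cx <- stats::runif(n, 1 + margin, nc - margin)
  theta <- stats::runif(n, 0, pi)
  uIntegrity <- stats::runif(n)
  vBias <- stats::runif(n)
  intact <- uIntegrity <= config$integrityProb
  ommOnly <- !intact & (vBias <= config$singleChannelBias)
  immOnly <- !intact & !ommOnly

  ommClean <- matrix(0, nr, nc)
  immClean <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    rows <- max(1L, floor(cy[i] - margin[i])):min(nr, ceiling(cy[i] + margin[i]))
    cols <- max(1L, floor(cx[i] - margin[i])):min(nc, ceiling(cx[i] + margin[i]))
    dy <- outer(rows - cy[i], rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - cx[i])
    ux <- cos(theta[i]); uy <- sin(theta[i])
    t <- pmin(pmax(dx * ux + dy * uy, -halfSeg[i]), halfSeg[i])
    d <- sqrt((dx - t * ux)^2 + (dy - t * uy)^2)
    amp <- config$peakIntensity
    if (intact[i] || immOnly[i])
      immClean[rows, cols] <- immClean[rows, cols] +
        amp * .immProfile(d, r, s, reach)
    if (intact[i] || ommOnly[i])
      ommClean[rows, cols] <- ommClean[rows, cols] +
        amp * .ommProfile(d, rm., s, reach)
  }

  # analytic overlap fractions on the noiseless grids (support thresholds
  # at zero); an empty reference channel colocalizes nothing, hence 0
  m1 <- if (sum(immClean) > 0) sum(immClean[ommClean > 0]) / sum(immClean) else 0
  m2 <- if (sum(ommClean) > 0) sum(ommClean[immClean > 0]) / sum(ommClean) else 0

  addNoise <- function(clean) {
    sig <- clean + config$backgroundLevel
    x <- if (config$noisePoisson) {
      stats::rpois(length(sig), lambda = sig)
    } else sig
    if (config$noiseGaussianSd > 0)
      x <- x + stats::rnorm(length(sig), 0, config$noiseGaussianSd)
    matrix(pmax(x, 0), nrow(clean), ncol(clean))
  }
  ommNoisy <- addNoise(ommClean)
  immNoisy <- addNoise(immClean)

  objects <- data.frame(
    id = seq_len(n),
    center_row = cy, center_col = cx, orientation = theta,
    length_um = lenUm, length_px = lenPx,
    channels = factor(ifelse(intact, "both",
                             ifelse(ommOnly, "OMM_only", "IMM_only")),
                      levels = c("both", "OMM_only", "IMM_only")))
  truth <- structure(list(objects = objects, ommClean = ommClean,
                          immClean = immClean, m1 = m1, m2 = m2),
                     class = "MitoGroundTruth")
  list(image = MitoImage(ommNoisy, immNoisy, pixelSize = px), truth = truth)
}

#' @export
print.MitoGroundTruth <- function(x, ...) {
  cat("MitoGroundTruth:", nrow(x$objects), "objects (",
      sum(x$objects$channels == "both"), "intact,",
      sum(x$objects$channels == "OMM_only"), "OMM-only,",
      sum(x$objects$channels == "IMM_only"), "IMM-only )\n")
  cat("  analytic M1 =", format(x$m1, digits = 5),
      ", M2 =", format(x$m2, digits = 5), "\n")
  invisible(x)
}

#' Configuration for the hierarchical cohort simulator
#'
#' Describes a two-sex, two-genotype study with animals nested in
#' sex x genotype cells and neurons nested in animals, matching the
#' random-intercept structure assumed by [fitMitoLMM()]. The default design
#' (3/3/5/3 animals contributing 30/20/24/30 neurons each, i.e.
#' 90/60/120/90 neurons for WT male / WT female / KO male / KO female)
#' mirrors the MNTB study design this package targets.
#'
#' Cell order throughout is `WT_male, WT_female, KO_male, KO_female`.
#'
#' @param nAnimalsPerGroup positive integer per cell (length 4, cell order
#'   above; a scalar is recycled).
#' @param neuronsPerAnimal positive integer per cell (recycled likewise);
#'   every animal in a cell contributes this many neurons.
#' @param cellMeans named list with numeric length-4 vectors `aspect_ratio`,
#'   `m2` and `mito_count`: the true cell means of each response.
#' @param sdAnimal named numeric: between-animal random-intercept SD per
#'   response.
#' @param sdResid named numeric: residual (neuron-level) SD per response.
#' @param seed integer RNG seed.
#' @return A validated list of class `CohortSimConfig`.
#' @seealso [simulateCohort()]
#' @export
cohortSimConfig <- function(nAnimalsPerGroup = c(3L, 3L, 5L, 3L),
                            neuronsPerAnimal = c(30L, 20L, 24L, 30L),
                            cellMeans = list(
                              aspect_ratio = c(2.0, 2.0, 2.1, 2.1),
                              m2 = c(0.85, 0.85, 0.85, 0.75),
                              mito_count = c(60, 60, 60, 60)),
                            sdAnimal = c(aspect_ratio = 0.10, m2 = 0.02,
                                         mito_count = 5),
                            sdResid = c(aspect_ratio = 0.40, m2 = 0.06,
                                        mito_count = 12),
                            seed = 1L) {
  cells <- c("WT_male", "WT_female", "KO_male", "KO_female")
  nAnimalsPerGroup <- rep(as.integer(nAnimalsPerGroup), length.out = 4L)
  neuronsPerAnimal <- rep(as.integer(neuronsPerAnimal), length.out = 4L)
  if (any(nAnimalsPerGroup < 1L))
    stop("config error: every sex x genotype cell needs >= 1 animal")
  if (any(neuronsPerAnimal < 1L))
    stop("config error: every animal needs >= 1 neuron")
  responses <- c("aspect_ratio", "m2", "mito_count")
  stopifnot(all(responses %in% names(cellMeans)))
  for (rsp in responses) {
    stopifnot(length(cellMeans[[rsp]]) == 4L, all(is.finite(cellMeans[[rsp]])))
    if (!(rsp %in% names(sdAnimal)) || !(rsp %in% names(sdResid)))
      stop("sdAnimal and sdResid must name every response")
  }
  if (any(unlist(sdAnimal) < 0) || any(unlist(sdResid) < 0))
    stop("variance components must be >= 0")
  structure(list(cells = cells, nAnimalsPerGroup = nAnimalsPerGroup,
                 neuronsPerAnimal = neuronsPerAnimal, cellMeans = cellMeans,
                 sdAnimal = sdAnimal, sdResid = sdResid,
                 seed = as.integer(seed)),
            class = "CohortSimConfig")
}

#' Simulate a hierarchical per-neuron cohort table
#'
#' Draws one random intercept per animal and per response
#' (Normal(0, sdAnimal)), then per-neuron residuals (Normal(0, sdResid))
#' around the true cell mean. M2 draws are truncated to [0, 1], aspect
#' ratios to [1, Inf), and mitochondrial counts are rounded to nonnegative
#' integers.
#'
#' @param config a [cohortSimConfig()].
#' @return A data.frame with one row per neuron and columns `animal_id`,
#'   `sex`, `genotype`, `aspect_ratio`, `m2`, `mito_count`. The true
#'   parameters are attached as `attr(x, "truth")`.
#' @examples
#' tab <- simulateCohort(cohortSimConfig(seed = 3))
#' table(tab$genotype, tab$sex)
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortSimConfig"))
  set.seed(config$seed)
  cellSex <- c("male", "female", "male", "female")
  cellGeno <- c("WT", "WT", "KO", "KO")
  responses <- c("aspect_ratio", "m2", "mito_count")
  rows <- vector("list", 0L)
  for (g in 1:4) {
    for (a in seq_len(config$nAnimalsPerGroup[g])) {
      animalEff <- vapply(responses, function(rsp)
        stats::rnorm(1, 0, config$sdAnimal[[rsp]]), numeric(1))
      m <- config$neuronsPerAnimal[g]
      draws <- lapply(responses, function(rsp)
        config$cellMeans[[rsp]][g] + animalEff[[rsp]] +
          stats::rnorm(m, 0, config$sdResid[[rsp]]))
      names(draws) <- responses
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%s_a%d", config$cells[g], a),
        sex = cellSex[g], genotype = cellGeno[g],
        aspect_ratio = pmax(draws$aspect_ratio, 1),
        m2 = pmin(pmax(draws$m2, 0), 1),
        mito_count = pmax(round(draws$mito_count), 0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$sex <- factor(out$sex, levels = c("male", "female"))
  out$genotype <- factor(out$genotype, levels = c("WT", "KO"))
  attr(out, "truth") <- list(cellMeans = config$cellMeans,
                             sdAnimal = config$sdAnimal,
                             sdResid = config$sdResid,
                             cells = config$cells)
  out
}
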