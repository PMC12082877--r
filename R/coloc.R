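#' Pearson correlation of two channels
#'
#' @param chA,chB numeric matrices or vectors of equal length.
#' @param mask optional logical selection of analyzed pixels.
#' @return Sample Pearson correlation over the analyzed pixels.
#' @export
pearsonColoc <- function(chA, chB, mask = NULL) {
  a <- as.numeric(chA); b <- as.numeric(chB)
  stopifnot(length(a) == length(b))
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    a <- a[mask]; b <- b[mask]
  }
  if (length(a) < 2L)
    stop("need at least 2 analyzed pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a channel is constant on the analyzed pixels")
  stats::cor(a, b)
}

#' Costes automatic threshold
#'
#' Fits the orthogonal (total-least-squares) regression line B = a A + c,
#' then scans the candidate threshold T_A downward over the observed
#' intensity levels of channel A. At each step the Pearson correlation of
#' the sub-threshold pixels (A < T_A and B < a T_A + c) is computed; the
#' scan stops at the first T_A where that correlation is <= 0 (steps where
#' it is undefined -- fewer than 2 sub-threshold pixels, or a constant
#' sub-threshold channel -- are passed over). If the scan reaches the
#' minimum of A without a sign change, the floor thresholds are returned
#' with the floor flag set.
#'
#' @param chA,chB numeric matrices or vectors of equal length, both
#'   non-constant.
#' @return A [CostesThreshold-class].
#' @export
costesAutoThreshold <- function(chA, chB) {
  a <- as.numeric(chA); b <- as.numeric(chB)
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate regression: constant channel")
  sxx <- stats::var(a); syy <- stats::var(b); sxy <- stats::cov(a, b)
  if (sxy == 0)
    stop("degenerate regression: zero inter-channel covariance")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  if (slope <= 0)
    stop("threshold search refused: orthogonal regression slope is not ",
         "positive (slope = ", format(slope, digits = 4),
         "); channels appear anti-correlated")
  intercept <- mean(b) - slope * mean(a)
  levels <- sort(unique(a), decreasing = TRUE)
  for (tA in levels) {
    below <- a < tA & b < slope * tA + intercept
    if (sum(below) < 2L) next
    ab <- a[below]; bb <- b[below]
    if (stats::sd(ab) == 0 || stats::sd(bb) == 0) next
    r <- stats::cor(ab, bb)
    if (r <= 0)
      return(new("CostesThreshold", slope = slope, intercept = intercept,
                 tA = tA, tB = slope * tA + intercept, rBelow = r,
                 floor = FALSE))
  }
  tA <- min(a)
  new("CostesThreshold", slope = slope, intercept = intercept,
      tA = tA, tB = slope * tA + intercept, rBelow = NA_real_, floor = TRUE)
}

#' Mander's colocalization coefficients
#'
#' With channel A the IMM/matrix marker and channel B the OMM marker:
#' M1 is the fraction of A intensity found in pixels where B is above its
#' threshold, and M2 the converse. The default thresholded variant restricts
#' the denominator to own-channel above-threshold pixels (the JaCoP
#' convention); `thresholded = FALSE` uses the classic definition with the
#' full own-channel intensity in the denominator. With zero thresholds and
#' nonnegative intensities the two variants coincide.
#'
#' @param chA,chB numeric matrices or vectors of equal length.
#' @param tA,tB thresholds for A and B (e.g. from [costesAutoThreshold()]).
#' @param thresholded logical, see above.
#' @return Named numeric vector `c(M1 = ..., M2 = ...)`, both in [0, 1].
#' @export
mandersCoefficients <- function(chA, chB, tA = 0, tB = 0,
                                thresholded = TRUE) {
  a <- as.numeric(chA); b <- as.numeric(chB)
  stopifnot(length(a) == length(b))
  aAbove <- a > tA; bAbove <- b > tB
  den1 <- if (thresholded) sum(a[aAbove]) else sum(a)
  den2 <- if (thresholded) sum(b[bAbove]) else sum(b)
  if (den1 <= 0 || den2 <= 0)
    stop("undefined coefficient: no above-threshold intensity in a ",
         "reference channel")
  c(M1 = sum(a[aAbove & bAbove]) / den1,
    M2 = sum(b[aAbove & bAbove]) / den2)
}

#' Costes block-randomization test
#'
#' Partitions channel B into square tiles of `blockSizePx` pixels (edges
#' cropped to full tiles), shuffles the tile positions uniformly at random
#' `nRounds` times and recomputes the Pearson correlation against channel A
#' each round, building a null distribution for the observed correlation.
#' The p-value uses the add-one estimator
#' p = (1 + #\{null r >= observed r\}) / (nRounds + 1), so p is never 0.
#'
#' @param chA,chB numeric matrices of identical dimension.
#' @param blockSizePx tile edge in pixels (default 5, about one PSF width
#'   at 0.0467 um/px).
#' @param nRounds number of shuffles (>= 1).
#' @param seed integer RNG seed.
#' @return List with `p`, `rObs`, `nullMean`, `nullSd`, `nRounds`,
#'   `blockSizePx`.
#' @export
costesRandomization <- function(chA, chB, blockSizePx = 5L, nRounds = 199L,
                                seed = 1L) {
  stopifnot(is.matrix(chA), is.matrix(chB),
            identical(dim(chA), dim(chB)), nRounds >= 1L)
  bs <- as.integer(blockSizePx)
  nbr <- nrow(chA) %/% bs; nbc <- ncol(chA) %/% bs
  if (nbr * nbc < 2L)
    stop("block-size error: need at least 2 full ", bs, "x", bs,
         " px blocks in the image")
  rows <- seq_len(nbr * bs); cols <- seq_len(nbc * bs)
  a <- chA[rows, cols]; b <- chB[rows, cols]
  # linear pixel indices of each tile, in tile raster order
  blockOf <- matrix(0L, length(rows), length(cols))
  blockOf[] <- (((row(blockOf) - 1L) %/% bs) +
                nbr * ((col(blockOf) - 1L) %/% bs)) + 1L
  ord <- order(blockOf)                 # pixels grouped by tile id
  tilePix <- matrix(ord, nrow = bs * bs)  # bs^2 x ntiles pixel indices
  av <- as.numeric(a); bv <- as.numeric(b)
  rObs <- stats::cor(av, bv)
  set.seed(seed)
  ntiles <- nbr * nbc
  nullR <- numeric(nRounds)
  aC <- av - mean(av); aS <- sqrt(sum(aC^2))
  for (k in seq_len(nRounds)) {
    perm <- sample.int(ntiles)
    bShuf <- bv[as.vector(tilePix[, perm])]
    # place shuffled tiles back into tile raster order
    bNew <- numeric(length(bv))
    bNew[as.vector(tilePix)] <- bShuf
    bC <- bNew - mean(bNew)
    nullR[k] <- sum(aC * bC) / (aS * sqrt(sum(bC^2)))
  }
  p <- (1 + sum(nullR >= rObs)) / (nRounds + 1)
  list(p = p, rObs = rObs, nullMean = mean(nullR), nullSd = stats::sd(nullR),
       nRounds = as.integer(nRounds), blockSizePx = bs)
}

#' Cytofluorogram
#'
#' Paired (A, B) intensity samples over the analyzed pixels, with no
#' binning loss.
#'
#' @param chA,chB numeric matrices or vectors of equal length.
#' @param mask optional logical selection of analyzed pixels.
#' @return data.frame with one `(A, B)` pair per analyzed pixel.
#' @export
cytofluorogram <- function(chA, chB, mask = NULL) {
  a <- as.numeric(chA); b <- as.numeric(chB)
  stopifnot(length(a) == length(b), length(a) >= 1L)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    a <- a[mask]; b <- b[mask]
  }
  data.frame(A = a, B = b)
}

#' Full colocalization analysis of one two-channel image
#'
#' Runs the Pearson correlation, automatic thresholding (Costes by default),
#' thresholded Mander's M1/M2 (channel A = IMM/matrix, channel B = OMM, so
#' M1 reads IMM-to-OMM overlap) and, optionally, the Costes
#' block-randomization control.
#'
#' @param image a [MitoImage-class].
#' @param thresholdMode "costes" (default), "otsu" (per-channel 256-bin Otsu
#'   thresholds) or "fixed".
#' @param fixedThresholds numeric length-2 `(tA, tB)` for
#'   `thresholdMode = "fixed"`.
#' @param randomize logical; run the randomization test.
#' @param blockSizePx,nRounds,seed randomization settings, see
#'   [costesRandomization()].
#' @return A [ColocResult-class].
#' @examples
#' sim <- simulateMitoImage(imageSimConfig(fieldSizePx = c(96, 96),
#'                                         nObjects = 4, seed = 2))
#' colocalize(sim$image, randomize = FALSE)
#' @export
colocalize <- function(image, thresholdMode = c("costes", "otsu", "fixed"),
                       fixedThresholds = NULL, randomize = TRUE,
                       blockSizePx = 5L, nRounds = 199L, seed = 1L) {
  stopifnot(is(image, "MitoImage"))
  thresholdMode <- match.arg(thresholdMode)
  a <- immChannel(image); b <- ommChannel(image)
  thr <- switch(thresholdMode,
    costes = costesAutoThreshold(a, b),
    otsu = {
      tA <- otsuThreshold(a); tB <- otsuThreshold(b)
      new("CostesThreshold", slope = NA_real_, intercept = NA_real_,
          tA = tA, tB = tB, rBelow = NA_real_, floor = FALSE)
    },
    fixed = {
      stopifnot(length(fixedThresholds) == 2L)
      new("CostesThreshold", slope = NA_real_, intercept = NA_real_,
          tA = fixedThresholds[1], tB = fixedThresholds[2],
          rBelow = NA_real_, floor = FALSE)
    })
  mm <- mandersCoefficients(a, b, thr@tA, thr@tB)
  rand <- if (randomize) {
    costesRandomization(a, b, blockSizePx, nRounds, seed)
  } else list(p = NA_real_, nRounds = NA_integer_,
              blockSizePx = NA_integer_)
  new("ColocResult", pearson = pearsonColoc(a, b),
      m1 = unname(mm["M1"]), m2 = unname(mm["M2"]), thresholds = thr,
      randomizationP = rand$p,
      nRounds = as.integer(rand$nRounds),
      blockSize = as.integer(rand$blockSizePx))
}
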