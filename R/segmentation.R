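#' Segmentation configuration
#'
#' Settings for object detection on the IMM/matrix channel and for the size
#' calibration rules: objects whose size (a length in px, by default the
#' caliper extent along the principal axis) is below `minSizePx` are
#' discarded as background; objects above `maxSizePx` are counted as
#' multiple organelles via `ceiling(size / maxSizePx)` (aggregated-like
#' structures counted as individual organelles).
#'
#' @param thresholdMethod "otsu" (256-bin histogram Otsu) or "fixed".
#' @param fixedThreshold threshold value, required when
#'   `thresholdMethod = "fixed"`.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#'   Default 8, matching Fiji particle analysis.
#' @param minSizePx minimum object size in px (default 15, i.e. 0.7 um at
#'   0.0467 um/px); objects with size < minSizePx are discarded, size >=
#'   minSizePx retained.
#' @param maxSizePx maximum size of an individual mitochondrion in px
#'   (default 45, i.e. 2.2 um).
#' @param sizeMeasure "major_axis" (caliper length along the principal axis)
#'   or "skeleton_length".
#' @return A validated list of class `SegmentationConfig`.
#' @export
segmentationConfig <- function(thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = NULL,
                               connectivity = 8L,
                               minSizePx = 15L,
                               maxSizePx = 45L,
                               sizeMeasure = c("major_axis",
                                               "skeleton_length")) {
  thresholdMethod <- match.arg(thresholdMethod)
  sizeMeasure <- match.arg(sizeMeasure)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (thresholdMethod == "fixed" &&
      (is.null(fixedThreshold) || !is.finite(fixedThreshold)))
    stop("fixedThreshold must be given for thresholdMethod = 'fixed'")
  minSizePx <- as.integer(minSizePx); maxSizePx <- as.integer(maxSizePx)
  if (minSizePx < 1L || maxSizePx <= minSizePx)
    stop("need 0 < minSizePx < maxSizePx")
  structure(list(thresholdMethod = thresholdMethod,
                 fixedThreshold = fixedThreshold,
                 connectivity = connectivity,
                 minSizePx = minSizePx, maxSizePx = maxSizePx,
                 sizeMeasure = sizeMeasure),
            class = "SegmentationConfig")
}

#' Otsu threshold on a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over the candidate cut
#' points of a 256-bin histogram spanning the observed intensity range. Ties
#' (e.g. an empty gap between two well-separated classes) are resolved by
#' averaging the tying cut points.
#'
#' @param x numeric matrix or vector of intensities.
#' @param nbins number of histogram bins (default 256).
#' @return The threshold value; pixels with intensity strictly above it are
#'   foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  if (!length(x) || any(!is.finite(x))) stop("image must be finite, nonempty")
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("degenerate histogram: constant image has no Otsu threshold")
  w <- (hi - lo) / nbins
  bin <- pmin(pmax(floor((x - lo) / w) + 1L, 1L), nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / length(x)
  mids <- lo + (seq_len(nbins) - 0.5) * w
  w0 <- cumsum(p)[-nbins]
  mu0 <- cumsum(p * mids)[-nbins]
  muT <- sum(p * mids)
  valid <- w0 > 0 & w0 < 1
  sigmaB <- rep(-Inf, nbins - 1L)
  sigmaB[valid] <- (muT * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  best <- which(sigmaB >= max(sigmaB) - 1e-12)
  lo + mean(best) * w
}

#' Threshold one channel to a binary mask
#'
#' @param image numeric matrix of intensities.
#' @param config a [segmentationConfig()].
#' @return Logical matrix, TRUE where intensity is strictly above the
#'   threshold.
#' @export
thresholdChannel <- function(image, config = segmentationConfig()) {
  stopifnot(is.matrix(image), inherits(config, "SegmentationConfig"))
  thr <- switch(config$thresholdMethod,
                otsu = otsuThreshold(image),
                fixed = config$fixedThreshold)
  image > thr
}

#' Label connected foreground components
#'
#' Components of the binary mask under 4- or 8-connectivity, computed on the
#' pixel-adjacency graph. Labels are positive integers in raster order of
#' each component's first pixel; background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels.
#' @export
labelMask <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  addEdges <- function(dr, dc) {
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    ok <- rr + dr >= 1L & rr + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    ok2 <- mask[nb]
    rbind(pos[idx[ok][ok2]], pos[nb[ok2]])
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  em <- do.call(cbind, lapply(shifts, function(s) addEdges(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(em)) g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)$membership
  # relabel in raster order of first occurrence
  first <- !duplicated(comp)
  relab <- integer(max(comp)); relab[comp[first]] <- seq_len(sum(first))
  lab[idx] <- relab[comp]
  lab
}
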