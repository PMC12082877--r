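# Marching-squares (midpoint-polygon) boundary length of a binary mask:
# each 2x2 pixel-corner cell contributes the length of the 0.5-isocontour
# through it (sqrt(2)/2 for one corner set, 1 for an adjacent pair, sqrt(2)
# for a diagonal pair). Less staircase bias than a chain-code trace.
.msPerimeter <- function(mask) {
  if (!any(mask)) return(0)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  a <- m[-nrow(m), -ncol(m)]   # (i,   j)
  b <- m[-nrow(m), -1]         # (i,   j+1)
  cc <- m[-1, -1]              # (i+1, j+1)
  d <- m[-1, -ncol(m)]         # (i+1, j)
  case <- a + 2L * b + 4L * cc + 8L * d
  h <- sqrt(2) / 2
  lenTable <- c(0, h, h, 1, h, sqrt(2), 1, h, h, 1, sqrt(2), h, 1, h, h, 0)
  sum(lenTable[case + 1L])
}

#' Shape metrics of one connected component
#'
#' Computes the moment-equivalent-ellipse axes from the second central
#' moments of the pixel coordinates, the caliper length along the principal
#' axis, the marching-squares boundary length, and the derived shape
#' descriptors: aspect
#' ratio (major/minor axis of the equivalent ellipse), circularity
#' (4 pi area / perimeter^2, clamped to <= 1) and form factor
#' (1 / circularity).
#'
#' Components whose minor axis vanishes (single pixels, perfectly collinear
#' pixels) are flagged `degenerate`; their aspect ratio is reported as `NA`
#' and they are excluded from aspect-ratio/form-factor summaries, but they
#' still count towards mitochondrial mass.
#'
#' @param coords two-column matrix of (row, col) pixel coordinates.
#' @param mask optional logical matrix holding just this component (used for
#'   perimeter tracing; reconstructed from `coords` when absent).
#' @return A one-row data.frame with columns `area_px`, `major_axis_px`,
#'   `minor_axis_px`, `length_px`, `perimeter_px`, `aspect_ratio`,
#'   `circularity`, `form_factor`, `degenerate`.
#' @export
shapeMetrics <- function(coords, mask = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 1L)
  n <- nrow(coords)
  ctr <- colMeans(coords)
  xc <- coords[, 1] - ctr[1]; yc <- coords[, 2] - ctr[2]
  # second central moments with divisor n (moment-equivalent ellipse)
  cxx <- sum(xc * xc) / n; cyy <- sum(yc * yc) / n; cxy <- sum(xc * yc) / n
  tr <- cxx + cyy; det <- cxx * cyy - cxy * cxy
  disc <- sqrt(max((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  degenerate <- n == 1L || l2 < 1e-10
  ar <- if (degenerate) NA_real_ else sqrt(l1 / l2)
  # caliper extent along the principal axis (+1 px for pixel width)
  if (l1 < 1e-12) {
    lengthPx <- 1
  } else {
    ang <- 0.5 * atan2(2 * cxy, cxx - cyy)
    proj <- xc * cos(ang) + yc * sin(ang)
    lengthPx <- diff(range(proj)) + 1
  }
  if (is.null(mask)) {
    rmin <- min(coords[, 1]); cmin <- min(coords[, 2])
    mask <- matrix(FALSE, max(coords[, 1]) - rmin + 3L,
                   max(coords[, 2]) - cmin + 3L)
    mask[cbind(coords[, 1] - rmin + 2L, coords[, 2] - cmin + 2L)] <- TRUE
  }
  perim <- .msPerimeter(mask)
  circ <- min(4 * pi * n / perim^2, 1)
  data.frame(area_px = n, major_axis_px = major, minor_axis_px = minor,
             length_px = lengthPx, perimeter_px = perim,
             aspect_ratio = ar, circularity = circ, form_factor = 1 / circ,
             degenerate = degenerate)
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative thinning to a one-pixel-wide medial skeleton.
#'
#' @param mask logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- (mask & !is.na(mask)) * 1L
  nr <- nrow(img); nc <- ncol(img)
  if (!any(img == 1L)) return(img == 1L)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    rs <- (1 + max(dr, 0)):(nrow(m) + min(dr, 0))
    cs <- (1 + max(dc, 0)):(ncol(m) + min(dc, 0))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (phase == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- pad == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        pad[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)] == 1L
}

#' Skeleton length per labeled component
#'
#' Skeletonizes the mask and measures, per component of `labels`, the
#' skeleton path length: adjacent skeleton-pixel pairs contribute 1 for
#' axial neighbours and sqrt(2) for diagonal neighbours; a diagonal step is
#' not counted when the two pixels already share an axial skeleton
#' neighbour (so an L-shaped corner is not double-counted). An isolated
#' skeleton pixel has length 0.
#'
#' @param mask logical matrix.
#' @param labels integer label matrix from [labelMask()] (computed from
#'   `mask` with 8-connectivity when absent).
#' @return A list with `skeleton` (logical matrix) and `lengths` (named
#'   numeric vector, one entry per positive label).
#' @export
skeletonLengths <- function(mask, labels = NULL) {
  if (is.null(labels)) labels <- labelMask(mask, 8L)
  skel <- skeletonize(mask)
  nlab <- max(labels)
  lens <- setNames(numeric(nlab), as.character(seq_len(nlab)))
  if (!any(skel) || nlab == 0L)
    return(list(skeleton = skel, lengths = lens))
  nr <- nrow(skel); nc <- ncol(skel)
  s <- matrix(FALSE, nr + 2L, nc + 2L)
  s[2:(nr + 1L), 2:(nc + 1L)] <- skel
  lb <- matrix(0L, nr + 2L, nc + 2L)
  lb[2:(nr + 1L), 2:(nc + 1L)] <- labels
  idx <- which(s)
  rr <- ((idx - 1L) %% (nr + 2L)) + 1L
  cc <- ((idx - 1L) %/% (nr + 2L)) + 1L
  here <- lb[idx]
  nbr <- function(dr, dc) s[cbind(rr + dr, cc + dc)]
  # axial edges counted once (right and down neighbours)
  axial <- (nbr(0L, 1L) + nbr(1L, 0L))
  # diagonal edges (down-right and up-right), skipped when an axial
  # two-step path exists through a shared skeleton pixel
  dr1 <- nbr(1L, 1L) & !(nbr(0L, 1L) | nbr(1L, 0L))
  dr2 <- nbr(-1L, 1L) & !(nbr(0L, 1L) | nbr(-1L, 0L))
  contrib <- axial * 1 + (dr1 + dr2) * sqrt(2)
  for (l in seq_len(nlab))
    lens[l] <- sum(contrib[here == l])
  list(skeleton = skel, lengths = lens)
}
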