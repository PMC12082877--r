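#' Label a mask and measure/filter mitochondrial objects
#'
#' Connected components of the mask are labeled with the configured
#' connectivity and measured with [shapeMetrics()] and [skeletonLengths()].
#' Each component's size -- a length in pixels, either the principal-axis
#' caliper length (`major_axis`, default) or the skeleton length -- is then
#' put through the calibration rules: components with size < `minSizePx`
#' are discarded as background, retained components contribute
#' `ceiling(size / maxSizePx)` organelles to the mitochondrial mass, so an
#' aggregated-like structure twice the maximal single-organelle size counts
#' as two organelles.
#'
#' @param mask logical matrix from [thresholdChannel()].
#' @param config a [segmentationConfig()].
#' @return A data.frame of retained objects (class `MitoObjectTable`), one
#'   row per component, with measurement columns from [shapeMetrics()] plus
#'   `label`, `skeleton_length_px`, `size_px`, `count_contribution`.
#'   An empty mask yields a zero-row table.
#' @seealso [summarizeMorphology()], [filterObjects()]
#' @export
labelAndFilter <- function(mask, config = segmentationConfig()) {
  stopifnot(is.matrix(mask), inherits(config, "SegmentationConfig"))
  labels <- labelMask(mask, config$connectivity)
  nlab <- max(labels)
  if (nlab == 0L) return(filterObjects(.emptyObjectTable(), config))
  skel <- skeletonLengths(mask & labels > 0L, labels)
  rows <- vector("list", nlab)
  idx <- which(labels > 0L)
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  lab <- labels[idx]
  for (l in seq_len(nlab)) {
    sel <- lab == l
    m <- shapeMetrics(cbind(rr[sel], cc[sel]))
    m$label <- l
    m$skeleton_length_px <- unname(skel$lengths[as.character(l)])
    rows[[l]] <- m
  }
  objects <- do.call(rbind, rows)
  filterObjects(objects, config)
}

.emptyObjectTable <- function() {
  data.frame(area_px = integer(0), major_axis_px = numeric(0),
             minor_axis_px = numeric(0), length_px = numeric(0),
             perimeter_px = numeric(0), aspect_ratio = numeric(0),
             circularity = numeric(0), form_factor = numeric(0),
             degenerate = logical(0), label = integer(0),
             skeleton_length_px = numeric(0))
}

#' Apply the size-calibration filter to a measured object table
#'
#' Idempotent: filtering an already-filtered table changes nothing.
#'
#' @param objects a data.frame of measured objects (from [labelAndFilter()]
#'   or assembled by hand with at least the size column in use).
#' @param config a [segmentationConfig()].
#' @return The retained rows with `size_px` and `count_contribution` set.
#' @export
filterObjects <- function(objects, config = segmentationConfig()) {
  stopifnot(is.data.frame(objects))
  size <- switch(config$sizeMeasure,
                 major_axis = objects$length_px,
                 skeleton_length = objects$skeleton_length_px)
  objects$size_px <- size
  keep <- size >= config$minSizePx
  objects <- objects[keep, , drop = FALSE]
  objects$count_contribution <-
    as.integer(ceiling(objects$size_px / config$maxSizePx))
  rownames(objects) <- NULL
  class(objects) <- c("MitoObjectTable", "data.frame")
  objects
}

#' Summarize per-image morphology and mitochondrial mass
#'
#' @param objects a `MitoObjectTable` from [labelAndFilter()].
#' @return A one-row data.frame: `mito_count` (mitochondrial mass, the sum
#'   of `count_contribution` over retained objects), mean and median aspect
#'   ratio and form factor over non-degenerate objects (`NA` when no
#'   non-degenerate object remains), and `n_objects` (retained components).
#' @export
summarizeMorphology <- function(objects) {
  stopifnot(is.data.frame(objects))
  ok <- !objects$degenerate
  summ <- function(f, x) if (any(ok)) f(x[ok]) else NA_real_
  data.frame(
    n_objects = nrow(objects),
    mito_count = if (nrow(objects)) sum(objects$count_contribution) else 0L,
    aspect_ratio_mean = summ(mean, objects$aspect_ratio),
    aspect_ratio_median = summ(stats::median, objects$aspect_ratio),
    form_factor_mean = summ(mean, objects$form_factor),
    form_factor_median = summ(stats::median, objects$form_factor))
}
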