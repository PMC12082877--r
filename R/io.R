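#' Write a MitoImage to a two-page 16-bit TIFF
#'
#' Channel order is OMM page first, then IMM. Intensities are stored as
#' 16-bit unsigned integers; values are written as-is when already within
#' [0, 65535].
#'
#' @param image a [MitoImage-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeMitoTiff <- function(image, path) {
  stopifnot(is(image, "MitoImage"))
  clip <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(clip(ommChannel(image)), clip(immChannel(image))),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel TIFF into a MitoImage
#'
#' Accepts a multi-page/multi-channel TIFF (two grayscale pages, or one RGB
#' page whose first two color planes hold the channels) or two single-page
#' files. Pixel values are rescaled back to integer counts (readTIFF maps
#' k-bit samples to [0, 1]).
#'
#' @param path path to the TIFF (or the first channel's file).
#' @param path2 optional second file when channels are stored separately.
#' @param channelOrder character length-2 permutation of `c("omm", "imm")`
#'   giving the page/file order (default OMM first).
#' @param pixelSizeUm lateral pixel size in micrometres.
#' @return A [MitoImage-class].
#' @export
readMitoTiff <- function(path, path2 = NULL,
                         channelOrder = c("omm", "imm"),
                         pixelSizeUm = 0.0467) {
  stopifnot(length(channelOrder) == 2L,
            setequal(channelOrder, c("omm", "imm")))
  toCounts <- function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    round(m * 65535)
  }
  if (!is.null(path2)) {
    pages <- list(tiff::readTIFF(path), tiff::readTIFF(path2))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
      arr <- pages[[1]]
      if (dim(arr)[3] < 2L)
        stop("malformed TIFF: expected two channels in ", path)
      pages <- list(arr[, , 1L], arr[, , 2L])
    }
    if (length(pages) < 2L)
      stop("malformed TIFF: expected two pages/channels in ", path)
  }
  chans <- lapply(pages[1:2], toCounts)
  names(chans) <- channelOrder
  MitoImage(omm = chans[["omm"]], imm = chans[["imm"]],
            pixelSize = pixelSizeUm)
}

#' Write / read an image-simulation ground truth as CSV
#'
#' Only the per-object records are serialized (the noiseless grids live in
#' the TIFF written from them, if needed); analytic M1/M2 are stored as
#' extra columns repeated per row.
#'
#' @param truth a `MitoGroundTruth` from [simulateMitoImage()].
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeGroundTruthCsv <- function(truth, path) {
  stopifnot(inherits(truth, "MitoGroundTruth"))
  df <- truth$objects
  df$analytic_m1 <- truth$m1
  df$analytic_m2 <- truth$m2
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation config as a YAML key-value file
#'
#' @param config an [imageSimConfig()] or [cohortSimConfig()].
#' @param path file path.
#' @return `writeSimConfig` returns the path invisibly; `readSimConfig`
#'   returns the reconstructed config object.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(inherits(config, c("ImageSimConfig", "CohortSimConfig")))
  obj <- unclass(config)
  # named atomic vectors lose their names as YAML sequences; store as maps
  for (f in c("sdAnimal", "sdResid"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.list(obj[[f]])
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  switch(cls,
         ImageSimConfig = do.call(imageSimConfig, obj[names(obj) %in%
           names(formals(imageSimConfig))]),
         CohortSimConfig = {
           keep <- obj[names(obj) %in% names(formals(cohortSimConfig))]
           keep$cellMeans <- lapply(obj$cellMeans, as.numeric)
           keep$sdAnimal <- unlist(obj$sdAnimal)
           keep$sdResid <- unlist(obj$sdResid)
           do.call(cohortSimConfig, keep)
         },
         stop("unrecognized config class in ", path))
}
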