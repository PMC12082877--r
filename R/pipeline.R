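#' Image-stage: per-neuron records from two-channel images
#'
#' For each input image (one image = one neuron record), segments the
#' IMM/matrix channel, applies the 15/45 px size calibration, summarizes
#' morphology and mitochondrial mass, and runs the colocalization analysis
#' (Pearson, automatic thresholds, Mander's M1/M2, optional randomization
#' control). Raw intensities are used throughout; no deconvolution is ever
#' applied in quantification. A malformed or unreadable image is logged and
#' skipped; the run continues, and rows out plus logged failures always
#' equal images in.
#'
#' @param inputs either a data.frame with columns `path` (TIFF paths) plus
#'   `animal_id`, `sex`, `genotype`, or a list of entries
#'   `list(image = <MitoImage>, animal_id =, sex =, genotype =)`.
#' @param segConfig a [segmentationConfig()].
#' @param thresholdMode,blockSizePx,nRounds,randomize colocalization
#'   settings, see [colocalize()].
#' @param seed integer; the randomization seed for image i is `seed + i`.
#' @param channelOrder,pixelSizeUm forwarded to [readMitoTiff()] for path
#'   inputs.
#' @return data.frame with one `NeuronRecord` row per successfully analyzed
#'   image: metadata, `aspect_ratio`, `form_factor`, `mito_count`,
#'   `pearson_r`, `m1`, `m2`, `t_a`, `t_b`, `randomization_p`. Failures are
#'   attached as `attr(x, "failures")` (data.frame of input index and
#'   message).
#' @export
runImageStage <- function(inputs, segConfig = segmentationConfig(),
                          thresholdMode = "costes", blockSizePx = 5L,
                          nRounds = 199L, randomize = TRUE, seed = 1L,
                          channelOrder = c("omm", "imm"),
                          pixelSizeUm = 0.0467) {
  entries <- if (is.data.frame(inputs)) {
    stopifnot(all(c("path", "animal_id", "sex", "genotype") %in%
                  names(inputs)))
    lapply(seq_len(nrow(inputs)), function(i) as.list(inputs[i, ]))
  } else inputs
  rows <- list(); fails <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    rec <- tryCatch({
      img <- if (!is.null(e$image)) e$image else
        readMitoTiff(e$path, channelOrder = channelOrder,
                     pixelSizeUm = pixelSizeUm)
      mask <- thresholdChannel(immChannel(img), segConfig)
      objs <- labelAndFilter(mask, segConfig)
      morph <- summarizeMorphology(objs)
      cl <- colocalize(img, thresholdMode = thresholdMode,
                       randomize = randomize, blockSizePx = blockSizePx,
                       nRounds = nRounds, seed = seed + i)
      data.frame(animal_id = e$animal_id, sex = e$sex,
                 genotype = e$genotype,
                 aspect_ratio = morph$aspect_ratio_mean,
                 form_factor = morph$form_factor_mean,
                 mito_count = morph$mito_count,
                 pearson_r = cl@pearson, m1 = cl@m1, m2 = cl@m2,
                 t_a = cl@thresholds@tA, t_b = cl@thresholds@tB,
                 randomization_p = cl@randomizationP)
    }, error = function(err) {
      message("image ", i, " failed: ", conditionMessage(err))
      fails[[length(fails) + 1L]] <<- data.frame(
        index = i, message = conditionMessage(err))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out))
    out <- data.frame(animal_id = character(0), sex = character(0),
                      genotype = character(0))
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(index = integer(0), message = character(0))
  out
}

#' Statistics stage: mixed models, contrasts and FAMD on a neuron table
#'
#' Fits the random-intercept mixed model and Tukey-adjusted pairwise
#' contrasts for each requested response, runs the FAMD over the
#' quantitative metrics plus sex/genotype labels, and (optionally) writes
#' all outputs as CSV files plus a JSON run manifest.
#'
#' @param records `NeuronRecord` data.frame (from [runImageStage()] or
#'   [simulateCohort()]).
#' @param responses responses to model (default aspect ratio, M2, count).
#' @param famdQuantVars quantitative variables for the FAMD.
#' @param outDir optional output directory for CSVs and the manifest.
#' @param seeds named list or vector of seeds used upstream, recorded in
#'   the manifest.
#' @return List with `fits` (per-response [MitoLMMFit-class]), `contrasts`
#'   (per-response `ContrastTable`), `famd` (a [FAMDResult-class], or NULL
#'   when a label has fewer than 2 observed levels), and `manifest`.
#' @export
runStatsStage <- function(records,
                          responses = c("aspect_ratio", "m2", "mito_count"),
                          famdQuantVars = c("aspect_ratio", "m2",
                                            "mito_count"),
                          outDir = NULL, seeds = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  fits <- list(); contrasts <- list(); skipped <- character(0)
  for (rsp in responses) {
    res <- tryCatch({
      fit <- fitMitoLMM(records, rsp)
      list(fit = fit, ct = tukeyContrasts(fit))
    }, error = function(err) {
      message("stats stage: response '", rsp, "' skipped: ",
              conditionMessage(err))
      NULL
    })
    if (is.null(res)) {
      skipped <- c(skipped, rsp)
    } else {
      fits[[rsp]] <- res$fit
      contrasts[[rsp]] <- res$ct
    }
  }
  famdQuantVars <- intersect(famdQuantVars, names(records))
  fam <- tryCatch(
    famd(records, famdQuantVars, intersect(c("sex", "genotype"),
                                           names(records))),
    error = function(err) {
      message("stats stage: FAMD skipped: ", conditionMessage(err))
      NULL
    })
  manifest <- list(
    package = "mitomorph",
    version = as.character(utils::packageVersion("mitomorph")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_rows = nrow(records),
    n_animals = length(unique(records$animal_id)),
    responses_fitted = if (length(fits)) names(fits) else character(0),
    responses_skipped = skipped,
    famd_quant_vars = famdQuantVars,
    seeds = seeds)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(outDir, "neuron_records.csv"),
                     row.names = FALSE)
    for (rsp in names(fits)) {
      utils::write.csv(estimatedMarginalMeans(fits[[rsp]]),
                       file.path(outDir, paste0("emmeans_", rsp, ".csv")),
                       row.names = FALSE)
      utils::write.csv(contrasts[[rsp]],
                       file.path(outDir, paste0("contrasts_", rsp, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(fam)) {
      utils::write.csv(famdEigenvalues(fam),
                       file.path(outDir, "famd_eigenvalues.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(famdContributions(fam)),
                       file.path(outDir, "famd_contributions.csv"))
      utils::write.csv(as.data.frame(famdQuantCor(fam)),
                       file.path(outDir, "famd_correlation_circle.csv"))
      utils::write.csv(famdScoresByGroup(fam,
                         records[intersect(c("sex", "genotype"),
                                           names(records))]),
                       file.path(outDir, "famd_scores.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(fits = fits, contrasts = contrasts, famd = fam, manifest = manifest)
}

#' Run the full pipeline: images to statistics
#'
#' Thin composition of [runImageStage()] and [runStatsStage()].
#'
#' @param inputs image inputs, see [runImageStage()].
#' @param outDir optional output directory.
#' @param ... forwarded to [runImageStage()].
#' @return The [runStatsStage()] result, with the neuron table attached as
#'   `$records`.
#' @export
runPipeline <- function(inputs, outDir = NULL, ...) {
  records <- runImageStage(inputs, ...)
  res <- runStatsStage(records, outDir = outDir)
  res$records <- records
  res
}
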