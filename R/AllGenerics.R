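#' Accessors for MitoImage
#'
#' @param object a [MitoImage-class].
#' @return `ommChannel` and `immChannel` return the intensity matrices;
#'   `pixelSize` returns the lateral pixel size in micrometres.
#' @examples
#' img <- MitoImage(matrix(1, 4, 4), matrix(2, 4, 4), pixelSize = 0.05)
#' pixelSize(img)
#' @export
setGeneric("ommChannel", function(object) standardGeneric("ommChannel"))

#' @rdname ommChannel
#' @export
setGeneric("immChannel", function(object) standardGeneric("immChannel"))

#' @rdname ommChannel
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname ommChannel
setMethod("ommChannel", "MitoImage", function(object) object@omm)

#' @rdname ommChannel
setMethod("immChannel", "MitoImage", function(object) object@imm)

#' @rdname ommChannel
setMethod("pixelSize", "MitoImage", function(object) object@pixelSize)

#' Accessors for FAMDResult
#'
#' @param object a [FAMDResult-class].
#' @return `famdEigenvalues` returns a data.frame with eigenvalue, percent
#'   and cumulative percent of inertia per dimension; `famdContributions`
#'   the percent-contribution matrix (variables x dimensions);
#'   `famdQuantCor` the correlation-circle coordinates; `famdRowScores`
#'   the row factor-score matrix.
#' @export
setGeneric("famdEigenvalues",
           function(object) standardGeneric("famdEigenvalues"))

#' @rdname famdEigenvalues
#' @export
setGeneric("famdContributions",
           function(object) standardGeneric("famdContributions"))

#' @rdname famdEigenvalues
#' @export
setGeneric("famdQuantCor", function(object) standardGeneric("famdQuantCor"))

#' @rdname famdEigenvalues
#' @export
setGeneric("famdRowScores", function(object) standardGeneric("famdRowScores"))

#' @rdname famdEigenvalues
setMethod("famdEigenvalues", "FAMDResult", function(object)
  data.frame(dim = seq_along(object@eigenvalues),
             eigenvalue = object@eigenvalues,
             percent = object@percentVar,
             cumulative = object@cumPercent))

#' @rdname famdEigenvalues
setMethod("famdContributions", "FAMDResult",
          function(object) object@contributions)

#' @rdname famdEigenvalues
setMethod("famdQuantCor", "FAMDResult", function(object) object@quantCor)

#' @rdname famdEigenvalues
setMethod("famdRowScores", "FAMDResult", function(object) object@rowScores)
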