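#' Name of a texture set or trained observer's set
#' @param object a [TextureSetSpec-class] or [Observer-class]
#' @export
setGeneric("specName", function(object) standardGeneric("specName"))

#' @export
setMethod("specName", "TextureSetSpec", function(object) object@name)

#' @export
setMethod("specName", "Observer", function(object) object@specName)

#' Number of amplitude states of a texture set
#' @param object a [TextureSetSpec-class]
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @export
setMethod("nStates", "TextureSetSpec", function(object) object@nStates)

#' Interaction offsets of a texture set
#' @param object a [TextureSetSpec-class]
#' @return integer matrix with columns (dy, dx), one row per interacting pair
#' @export
setGeneric("offsets", function(object) standardGeneric("offsets"))

#' @export
setMethod("offsets", "TextureSetSpec", function(object) object@offsets)

#' Pairwise potential matrices of a texture set
#' @param object a [TextureSetSpec-class]
#' @export
setGeneric("potentials", function(object) standardGeneric("potentials"))

#' @export
setMethod("potentials", "TextureSetSpec", function(object) object@potentials)

#' Lattice shape (H, W) of a texture set
#' @param object a [TextureSetSpec-class]
#' @export
setGeneric("latticeShape", function(object) standardGeneric("latticeShape"))

#' @export
setMethod("latticeShape", "TextureSetSpec", function(object) object@latticeShape)

#' Inverse-temperature grid of a texture set or psychometric curve
#' @param object a [TextureSetSpec-class] or [PsychometricCurve-class]
#' @export
setGeneric("betaGrid", function(object) standardGeneric("betaGrid"))

#' @export
setMethod("betaGrid", "TextureSetSpec", function(object) object@betaGrid)

#' @export
setMethod("betaGrid", "PsychometricCurve", function(object) object@betaGrid)

#' Canonical ground-state tile of a texture set
#' @param object a [TextureSetSpec-class]
#' @export
setGeneric("groundStateTile", function(object) standardGeneric("groundStateTile"))

#' @export
setMethod("groundStateTile", "TextureSetSpec", function(object) object@groundStateTile)

#' Values of a statistic-like object
#' @param object a [QuadrantStatistic-class] or [OrderStatistic-class]
#' @export
setGeneric("statValues", function(object) standardGeneric("statValues"))

#' @export
setMethod("statValues", "QuadrantStatistic", function(object) object@values)

#' @export
setMethod("statValues", "OrderStatistic", function(object) object@value)

#' Order-parameter components
#' @param object an [OrderStatistic-class]
#' @export
setGeneric("orderValue", function(object) standardGeneric("orderValue"))

#' @export
setMethod("orderValue", "OrderStatistic", function(object) object@value)

#' @rdname orderValue
#' @export
setGeneric("orderBaselineValue", function(object) standardGeneric("orderBaselineValue"))

#' @export
setMethod("orderBaselineValue", "OrderStatistic", function(object) object@baseline)

#' @rdname orderValue
#' @export
setGeneric("orderFieldMatrix", function(object) standardGeneric("orderFieldMatrix"))

#' @export
setMethod("orderFieldMatrix", "OrderStatistic", function(object) object@field)

#' Proportions correct of a psychometric curve
#' @param object a [PsychometricCurve-class]
#' @export
setGeneric("pCorrect", function(object) standardGeneric("pCorrect"))

#' @export
setMethod("pCorrect", "PsychometricCurve", function(object) object@pCorrect)

#' Trials per grid point of a psychometric curve
#' @param object a [PsychometricCurve-class]
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @export
setMethod("nTrials", "PsychometricCurve", function(object) object@nTrials)

#' Binomial standard errors of a psychometric curve
#' @param object a [PsychometricCurve-class]
#' @export
setGeneric("curveSE", function(object) standardGeneric("curveSE"))

#' @export
setMethod("curveSE", "PsychometricCurve", function(object) object@se)

#' Convert a psychometric curve to a data.frame
#'
#' @param x a [PsychometricCurve-class]
#' @param row.names,optional,... passed on for S3 compatibility; unused.
#' @return data.frame with columns observer, mode, beta, n, k, p, se
#' @export
as.data.frame.PsychometricCurve <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(observer = x@observerId, mode = x@mode, beta = x@betaGrid,
             n = x@nTrials, k = as.integer(round(x@pCorrect * x@nTrials)),
             p = x@pCorrect, se = x@se, stringsAsFactors = FALSE)
}

setMethod("show", "TextureSetSpec", function(object) {
  cat("TextureSetSpec '", object@name, "'\n", sep = "")
  cat("  states:", object@nStates,
      " lattice:", paste(object@latticeShape, collapse = " x "), "\n")
  off <- apply(object@offsets, 1L, function(o) sprintf("(%d,%d)", o[1L], o[2L]))
  cat("  offsets:", paste(off, collapse = " "), "\n")
  if (length(object@betaGrid))
    cat("  beta grid:", paste(signif(object@betaGrid, 3L), collapse = ", "), "\n")
  if (!is.null(object@groundStateTile))
    cat("  ground-state tile:", paste(dim(object@groundStateTile), collapse = " x "),
        "\n")
  invisible(object)
})

setMethod("show", "OrderStatistic", function(object) {
  cat("OrderStatistic: value =", signif(object@value, 4L),
      " (uniform baseline", signif(object@baseline, 4L))
  if (object@baselineSE > 0) cat(" +/-", signif(object@baselineSE, 2L))
  cat(")\n")
  invisible(object)
})

setMethod("show", "QuadrantStatistic", function(object) {
  cat("QuadrantStatistic [", object@kind, "], ", length(object@values),
      " value(s)\n", sep = "")
  invisible(object)
})

setMethod("show", "DensityModel", function(object) {
  cat("DensityModel [", object@kind, "], ", object@dims, "-dimensional, fit to ",
      object@trainingN, " samples\n", sep = "")
  invisible(object)
})

setMethod("show", "GaborSpec", function(object) {
  cat(sprintf("GaborSpec: sigma = %g deg, freq = %g c/deg, theta = %g deg, %g px/deg\n",
              object@sigma, object@freq, object@theta, object@pixelScale))
  invisible(object)
})

setMethod("show", "RenderSpec", function(object) {
  cat(sprintf("RenderSpec (%s): blob sigma %.4g deg, spacing %.4g deg, %g px/deg\n",
              object@layout, object@blobSigma, object@blobSpacing,
              object@pixelScale))
  cat("  amplitudes:", paste(signif(object@amplitudeMap, 3L), collapse = ", "),
      " background:", signif(object@background, 3L), "\n")
  invisible(object)
})

setMethod("show", "PsychometricCurve", function(object) {
  cat("PsychometricCurve for observer '", object@observerId, "' (",
      object@mode, ")\n", sep = "")
  print(as.data.frame(object))
  invisible(object)
})

setMethod("show", "Observer", function(object) {
  cat("Observer [", object@kind, "] on set '", object@specName,
      "', beta = ", object@beta, ", mode = ", object@mode, "\n", sep = "")
  invisible(object)
})
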