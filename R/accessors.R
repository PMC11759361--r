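#' Construct an AxonStack
#'
#' @param voxels 4-D numeric array, dim (C, Z, Y, X), intensities in [0, 1].
#' @param channelRoles named vector mapping \code{axon}, \code{myelin},
#'   \code{nuclei} to channel indices.
#' @param pixelSizeUm in-plane pixel size (um/px).
#' @param zStepUm axial slice spacing (um).
#' @param fieldId,wellId,condition labels (default empty).
#' @return A validated [AxonStack-class] object.
#' @examples
#' v <- array(0, dim = c(3, 2, 8, 8))
#' s <- AxonStack(v, c(axon = 1, myelin = 2, nuclei = 3), 0.31, 2)
#' nSlices(s)
#' @export
AxonStack <- function(voxels, channelRoles, pixelSizeUm, zStepUm,
                      fieldId = "", wellId = "", condition = "") {
  roles <- channelRoles
  storage.mode(roles) <- "integer"
  new("AxonStack", voxels = voxels, channelRoles = roles,
      pixelSizeUm = as.numeric(pixelSizeUm), zStepUm = as.numeric(zStepUm),
      fieldId = as.character(fieldId), wellId = as.character(wellId),
      condition = as.character(condition))
}

#' @rdname AxonStack
#' @param x,object an AxonStack.
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname AxonStack
#' @export
setMethod("channelRoles", "AxonStack", function(x) x@channelRoles)

#' @rdname AxonStack
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname AxonStack
#' @export
setMethod("pixelSizeUm", "AxonStack", function(x) x@pixelSizeUm)

#' @rdname AxonStack
#' @export
setGeneric("zStepUm", function(x) standardGeneric("zStepUm"))

#' @rdname AxonStack
#' @export
setMethod("zStepUm", "AxonStack", function(x) x@zStepUm)

#' @rdname AxonStack
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname AxonStack
#' @export
setMethod("nSlices", "AxonStack", function(x) dim(x@voxels)[2L])

#' Extract one channel of an AxonStack as a (Z, Y, X) array
#'
#' @param x an [AxonStack-class].
#' @param role one of \code{"axon"}, \code{"myelin"}, \code{"nuclei"}.
#' @return numeric 3-D array (Z, Y, X).
#' @export
channelData <- function(x, role) {
  stopifnot(is(x, "AxonStack"))
  if (!role %in% names(x@channelRoles))
    stop("unknown channel role: ", role)
  d <- dim(x@voxels)
  arr <- x@voxels[x@channelRoles[[role]], , , , drop = FALSE]
  dim(arr) <- d[2:4]
  arr
}

#' Extract a single (Y, X) slice of one channel
#'
#' @inheritParams channelData
#' @param z slice index (1-based).
#' @return numeric matrix (Y, X).
#' @export
getSlice <- function(x, role, z) {
  stopifnot(is(x, "AxonStack"))
  d <- dim(x@voxels)
  if (z < 1L || z > d[2L]) stop("slice index out of range")
  m <- x@voxels[x@channelRoles[[role]], z, , , drop = FALSE]
  dim(m) <- d[3:4]
  m
}

setMethod("show", "AxonStack", function(object) {
  d <- dim(object@voxels)
  cat("AxonStack:", d[1L], "channels x", d[2L], "slices x",
      d[3L], "x", d[4L], "px\n")
  cat("  calibration:", object@pixelSizeUm, "um/px,",
      object@zStepUm, "um z-step\n")
  cat("  roles:", paste(names(object@channelRoles),
                        object@channelRoles, sep = "=", collapse = ", "), "\n")
  if (nzchar(object@fieldId) || nzchar(object@wellId))
    cat("  well:", object@wellId, " field:", object@fieldId,
        " condition:", object@condition, "\n")
})

setMethod("show", "PillarTrace", function(object) {
  cat("PillarTrace", object@pillarId, "-", length(object@z), "slices, area",
      round(mean(object@areas), 1), "px",
      if (object@borderTouching) "(border)" else "", "\n")
})

setMethod("show", "FieldMetrics", function(object) {
  cat("FieldMetrics:", object@nPillars, "pillars,",
      object@nFullyWrapped, "fully wrapped,",
      object@nNuclei, "nuclei\n")
  if (object@wiValid) cat("  WI =", signif(object@wi, 4), "\n")
  else cat("  WI undefined (no nuclei); field excluded from aggregation\n")
})

setMethod("show", "HertzFit", function(object) {
  cat(sprintf("HertzFit: E = %.4g Pa (nu = %.2f, %d points <= %.0f nm, rms %.3g N)\n",
              object@E, object@nu, object@nPointsUsed,
              object@depthCutoff * 1e9, object@rmsResidual))
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve '%s': %d points, depth up to %.0f nm, R = %.3g um\n",
              object@label, length(object@depth),
              max(object@depth) * 1e9, object@probeRadius * 1e6))
})

setMethod("show", "SyntheticFieldSpec", function(object) {
  cat("SyntheticFieldSpec:", object@gridRows, "x", object@gridCols,
      "grid,", object@pillarDiameterUm, "um pillars at",
      object@spacingUm, "um spacing\n")
  cat("  ", object@nSlices, "slices x", object@zStepUm, "um,",
      object@pixelSizeUm, "um/px;", nrow(object@wrapEvents),
      "wrap events,", object@nNuclei, "nuclei, seed", object@seed, "\n")
})

setMethod("show", "FieldGroundTruth", function(object) {
  cat("FieldGroundTruth:", nrow(object@perPillar), "pillars,",
      sum(object@perPillar$fully_wrapped), "fully wrapped,",
      object@nNuclei, "nuclei; expected WI =",
      signif(object@expectedWI, 4), "\n")
})

#' Accessors for field metrics and ground truth
#'
#' @param x a [FieldMetrics-class] or [FieldGroundTruth-class] object.
#' @return \code{wrappingIndexOf}: the wrapping index (NA when undefined);
#'   \code{perPillarTable}: the per-pillar data.frame;
#'   \code{sheathLengths}: pooled maximal sheath lengths (um).
#' @export
wrappingIndexOf <- function(x) {
  if (is(x, "FieldMetrics")) x@wi
  else if (is(x, "FieldGroundTruth")) x@expectedWI
  else stop("unsupported type")
}

#' @rdname wrappingIndexOf
#' @export
perPillarTable <- function(x) {
  if (is(x, "FieldMetrics") || is(x, "FieldGroundTruth")) x@perPillar
  else stop("unsupported type")
}

#' @rdname wrappingIndexOf
#' @export
sheathLengths <- function(x) {
  stopifnot(is(x, "FieldMetrics"))
  x@sheathLengthsUm
}
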