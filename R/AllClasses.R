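#' @import methods
#' @importFrom stats median mad rnorm rpois runif sd aov anova pnorm pchisq pt
#' @importFrom utils read.csv write.csv combn head
NULL

#' AxonStack: a calibrated multichannel confocal z-stack
#'
#' Container for a three-channel confocal volume of an artificial-axon (AA)
#' pillar field. Voxels are stored as a 4-D numeric array with dimensions
#' (channel, z, y, x); indices are 1-based and z = 1 is the first acquired
#' slice. Channel roles (\code{axon}, \code{myelin}, \code{nuclei}) map role
#' names to channel indices so downstream stages never guess channel order.
#'
#' @slot voxels numeric 4-D array, dim (C, Z, Y, X), intensities in [0, 1].
#' @slot channelRoles named integer vector mapping the roles
#'   \code{c("axon","myelin","nuclei")} to channel indices.
#' @slot pixelSizeUm in-plane pixel size (micrometres per pixel).
#' @slot zStepUm axial step between consecutive slices (micrometres).
#' @slot fieldId,wellId,condition free-text labels carried through to
#'   per-field outputs.
#'
#' @seealso [AxonStack()], [readStack()], [writeStack()], [generateField()]
#' @exportClass AxonStack
setClass("AxonStack",
  representation(
    voxels = "array",
    channelRoles = "integer",
    pixelSizeUm = "numeric",
    zStepUm = "numeric",
    fieldId = "character",
    wellId = "character",
    condition = "character"
  )
)

setValidity("AxonStack", function(object) {
  msgs <- character()
  d <- dim(object@voxels)
  if (length(d) != 4L)
    msgs <- c(msgs, "voxels must be a 4-D (C, Z, Y, X) array")
  roles <- c("axon", "myelin", "nuclei")
  if (!all(roles %in% names(object@channelRoles)))
    msgs <- c(msgs, "channelRoles must name all of 'axon', 'myelin', 'nuclei'")
  else {
    idx <- object@channelRoles[roles]
    if (anyDuplicated(idx))
      msgs <- c(msgs, "the three channel roles must map to distinct channels")
    if (length(d) == 4L && (any(idx < 1L) || any(idx > d[1L])))
      msgs <- c(msgs, "channelRoles indices out of range")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msgs <- c(msgs, "pixelSizeUm must be a single positive number")
  if (length(object@zStepUm) != 1L || !is.finite(object@zStepUm) ||
      object@zStepUm <= 0)
    msgs <- c(msgs, "zStepUm must be a single positive number")
  if (anyNA(object@voxels))
    msgs <- c(msgs, "voxels must not contain NA/NaN")
  if (length(msgs)) msgs else TRUE
})

#' PillarTrace: one pillar's cross-sections linked through z
#'
#' Result of per-slice connected-component detection on the axon mask with
#' greedy nearest-centroid linkage across adjacent slices. Pixel coordinates
#' are (y, x), 1-based.
#'
#' @slot pillarId integer identifier, deterministic (row-major by first-slice
#'   centroid).
#' @slot z integer vector of slice indices with an entry (strictly
#'   increasing, at most one entry per slice).
#' @slot centroids numeric matrix, one row per entry, columns (y, x).
#' @slot areas integer vector of cross-section areas (pixels).
#' @slot pixels list of 2-column integer matrices (y, x) giving each
#'   cross-section's pixel set.
#' @slot complete TRUE if the trace has an entry in every slice of the stack.
#' @slot borderTouching TRUE if any cross-section touches the image border.
#'
#' @seealso [detectPillars()], [measureDiameter()]
#' @exportClass PillarTrace
setClass("PillarTrace",
  representation(
    pillarId = "integer",
    z = "integer",
    centroids = "matrix",
    areas = "integer",
    pixels = "list",
    complete = "logical",
    borderTouching = "logical"
  )
)

setValidity("PillarTrace", function(object) {
  msgs <- character()
  n <- length(object@z)
  if (n == 0L) msgs <- c(msgs, "trace must have at least one slice entry")
  if (anyDuplicated(object@z)) msgs <- c(msgs, "at most one entry per slice")
  if (n > 1L && any(diff(object@z) <= 0L))
    msgs <- c(msgs, "slice indices must be strictly increasing")
  if (nrow(object@centroids) != n || length(object@areas) != n ||
      length(object@pixels) != n)
    msgs <- c(msgs, "per-slice slots must have one entry per slice")
  if (length(msgs)) msgs else TRUE
})

#' WrapProfile: per-slice circumference-coverage fractions for one pillar
#'
#' @slot pillarId integer pillar identifier.
#' @slot coverage numeric vector, one value per stack slice, each the
#'   fraction (in [0, 1]) of the pillar outline covered by myelin in that
#'   slice; slices where the pillar was not detected carry 0.
#' @slot zStepUm axial step (micrometres), used to convert slice runs to
#'   sheath lengths.
#'
#' @seealso [wrapFraction()], [sheathSegments()], [classifyFullyWrapped()]
#' @exportClass WrapProfile
setClass("WrapProfile",
  representation(
    pillarId = "integer",
    coverage = "numeric",
    zStepUm = "numeric"
  )
)

setValidity("WrapProfile", function(object) {
  msgs <- character()
  if (length(object@coverage) < 1L)
    msgs <- c(msgs, "coverage must have at least one slice")
  if (any(!is.finite(object@coverage)) ||
      any(object@coverage < 0) || any(object@coverage > 1))
    msgs <- c(msgs, "coverage values must lie in [0, 1]")
  if (length(object@zStepUm) != 1L || object@zStepUm <= 0)
    msgs <- c(msgs, "zStepUm must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' FieldMetrics: per-field wrapping quantification
#'
#' Output of [computeFieldMetrics()] for one field of view: object counts,
#' the myelin wrapping index WI (fully wrapped pillars / nuclei), pooled
#' sheath lengths, and a per-pillar table.
#'
#' @slot nPillars number of pillars analysed (after border/debris policy).
#' @slot nFullyWrapped number of pillars classified fully wrapped.
#' @slot nNuclei nuclei count for the field.
#' @slot wi wrapping index; \code{NA_real_} when \code{nNuclei == 0}
#'   (WI-undefined error state, see \code{wiValid}).
#' @slot wiValid FALSE when WI is undefined and the field must be excluded
#'   from aggregation.
#' @slot sheathLengthsUm maximal contiguous sheath length (micrometres) of
#'   each fully wrapped pillar.
#' @slot perPillar data.frame with one row per pillar: \code{pillar_id},
#'   \code{centroid_y}, \code{centroid_x}, \code{diameter_um},
#'   \code{max_segment_um}, \code{fully_wrapped}.
#' @slot params list of the parameter values used (thresholds, linking,
#'   classification) for provenance.
#'
#' @exportClass FieldMetrics
setClass("FieldMetrics",
  representation(
    nPillars = "integer",
    nFullyWrapped = "integer",
    nNuclei = "integer",
    wi = "numeric",
    wiValid = "logical",
    sheathLengthsUm = "numeric",
    perPillar = "data.frame",
    params = "list"
  )
)

setValidity("FieldMetrics", function(object) {
  msgs <- character()
  if (object@nFullyWrapped < 0L || object@nFullyWrapped > object@nPillars)
    msgs <- c(msgs, "0 <= nFullyWrapped <= nPillars violated")
  if (object@wiValid && object@nNuclei > 0L &&
      !isTRUE(all.equal(object@wi, object@nFullyWrapped / object@nNuclei)))
    msgs <- c(msgs, "wi must equal nFullyWrapped / nNuclei when defined")
  if (length(msgs)) msgs else TRUE
})

#' ForceCurve: an AFM force-indentation record
#'
#' @slot depth indentation depths in metres, non-decreasing.
#' @slot force forces in newtons.
#' @slot probeRadius spherical probe radius in metres.
#' @slot springConstant cantilever spring constant in N/m (carried for
#'   provenance; curves are already converted to force vs indentation).
#' @slot label free-text sample label.
#'
#' @seealso [generateForceCurve()], [fitHertz()], [deflectionToIndentation()]
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(
    depth = "numeric",
    force = "numeric",
    probeRadius = "numeric",
    springConstant = "numeric",
    label = "character"
  )
)

setValidity("ForceCurve", function(object) {
  msgs <- character()
  if (length(object@depth) != length(object@force))
    msgs <- c(msgs, "depth and force must have equal length")
  if (length(object@depth) < 10L)
    msgs <- c(msgs, "a force curve needs at least 10 points")
  if (is.unsorted(object@depth))
    msgs <- c(msgs, "depth must be non-decreasing")
  if (length(object@probeRadius) != 1L || object@probeRadius <= 0)
    msgs <- c(msgs, "probeRadius must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' HertzFit: spherical Hertzian contact fit of a force curve
#'
#' @slot E fitted Young's modulus (Pa).
#' @slot nu Poisson ratio assumed in the fit.
#' @slot contactOffset fitted (or assumed 0) contact-point offset (m).
#' @slot depthCutoff maximum indentation depth used (m).
#' @slot rmsResidual root-mean-square force residual (N) over the fitted
#'   points.
#' @slot nPointsUsed number of points inside the fitting window.
#'
#' @seealso [fitHertz()], [summarizeModulus()]
#' @exportClass HertzFit
setClass("HertzFit",
  representation(
    E = "numeric",
    nu = "numeric",
    contactOffset = "numeric",
    depthCutoff = "numeric",
    rmsResidual = "numeric",
    nPointsUsed = "integer"
  )
)

setValidity("HertzFit", function(object) {
  msgs <- character()
  if (object@E <= 0) msgs <- c(msgs, "E must be positive")
  if (object@nPointsUsed < 5L)
    msgs <- c(msgs, "a fit must use at least 5 points")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticFieldSpec: parameters of one synthetic pillar field
#'
#' Declarative description of a synthetic three-channel confocal field:
#' pillar grid geometry, imaging calibration, myelin wrap events, nuclei,
#' optics (in-plane Gaussian blur) and noise. See [syntheticFieldSpec()] for
#' defaults and units.
#'
#' @slot gridRows,gridCols pillar grid dimensions.
#' @slot spacingUm centre-to-centre pillar spacing (micrometres).
#' @slot pillarDiameterUm pillar diameter (micrometres).
#' @slot nSlices,zStepUm z-stack geometry.
#' @slot pixelSizeUm in-plane calibration (micrometres per pixel).
#' @slot wrapEvents data.frame with columns \code{pillar_index},
#'   \code{slice_start}, \code{slice_end} (1-based, inclusive),
#'   \code{angular_coverage} (fraction of the circumference) and
#'   \code{angular_offset} (radians).
#' @slot myelinThicknessUm radial thickness of the rendered myelin annulus.
#' @slot nNuclei,nucleusDiameterUm nuclei channel content.
#' @slot blurSigmaUm isotropic in-plane Gaussian blur (micrometres; 0 = none).
#' @slot gaussianSd additive read-noise standard deviation (intensity units,
#'   dynamic range [0, 1]).
#' @slot poisson logical; apply Poisson (shot-noise) resampling before read
#'   noise.
#' @slot seed integer random seed for nuclei placement and noise.
#'
#' @exportClass SyntheticFieldSpec
setClass("SyntheticFieldSpec",
  representation(
    gridRows = "integer",
    gridCols = "integer",
    spacingUm = "numeric",
    pillarDiameterUm = "numeric",
    nSlices = "integer",
    zStepUm = "numeric",
    pixelSizeUm = "numeric",
    wrapEvents = "data.frame",
    myelinThicknessUm = "numeric",
    nNuclei = "integer",
    nucleusDiameterUm = "numeric",
    blurSigmaUm = "numeric",
    gaussianSd = "numeric",
    poisson = "logical",
    seed = "integer"
  )
)

setValidity("SyntheticFieldSpec", function(object) {
  msgs <- character()
  if (object@gridRows < 1L || object@gridCols < 1L)
    msgs <- c(msgs, "grid must be at least 1 x 1")
  if (object@nSlices < 1L) msgs <- c(msgs, "nSlices must be >= 1")
  if (object@zStepUm <= 0) msgs <- c(msgs, "zStepUm must be > 0")
  if (object@pixelSizeUm <= 0) msgs <- c(msgs, "pixelSizeUm must be > 0")
  if (object@nNuclei < 0L) msgs <- c(msgs, "nNuclei must be >= 0")
  if (object@spacingUm <=
      object@pillarDiameterUm + 2 * object@myelinThicknessUm)
    msgs <- c(msgs,
      "spacingUm must exceed pillarDiameterUm + 2 * myelinThicknessUm")
  ev <- object@wrapEvents
  need <- c("pillar_index", "slice_start", "slice_end",
            "angular_coverage", "angular_offset")
  if (!all(need %in% names(ev))) {
    msgs <- c(msgs, paste("wrapEvents must have columns:",
                          paste(need, collapse = ", ")))
  } else if (nrow(ev)) {
    if (any(ev$slice_start < 1L) || any(ev$slice_end > object@nSlices) ||
        any(ev$slice_start > ev$slice_end))
      msgs <- c(msgs, "wrap event slice ranges must satisfy 1 <= start <= end <= nSlices")
    if (any(ev$angular_coverage < 0) || any(ev$angular_coverage > 1))
      msgs <- c(msgs, "angular_coverage must lie in [0, 1]")
    npil <- object@gridRows * object@gridCols
    if (any(ev$pillar_index < 1L) || any(ev$pillar_index > npil))
      msgs <- c(msgs, "wrap event pillar_index out of range")
    # overlapping events on one pillar would make the per-slice ground-truth
    # coverage ill-defined
    for (p in unique(ev$pillar_index)) {
      e <- ev[ev$pillar_index == p, , drop = FALSE]
      if (nrow(e) > 1L) {
        e <- e[order(e$slice_start), , drop = FALSE]
        if (any(e$slice_start[-1L] <= e$slice_end[-nrow(e)]))
          msgs <- c(msgs, "wrap events for one pillar must not overlap in z")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FieldGroundTruth: exact ground truth for a synthetic field
#'
#' Computed analytically from a [SyntheticFieldSpec-class] before blur and
#' noise are applied, so every downstream measurement has an exact reference.
#'
#' @slot perPillar data.frame, one row per pillar: \code{pillar_index},
#'   \code{centroid_y_px}, \code{centroid_x_px}, \code{true_diameter_um},
#'   \code{max_contig_um} (maximal contiguous sheath length at coverage
#'   > theta), \code{fully_wrapped}.
#' @slot coverage numeric matrix (pillars x slices) of true per-slice
#'   angular coverage fractions.
#' @slot nNuclei nuclei count placed in the field.
#' @slot expectedWI ground-truth wrapping index (\code{NA} when
#'   \code{nNuclei == 0}).
#' @slot thetaC,lMinUm thresholds under which \code{fully_wrapped} and
#'   \code{expectedWI} were computed.
#'
#' @exportClass FieldGroundTruth
setClass("FieldGroundTruth",
  representation(
    perPillar = "data.frame",
    coverage = "matrix",
    nNuclei = "integer",
    expectedWI = "numeric",
    thetaC = "numeric",
    lMinUm = "numeric"
  )
)
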