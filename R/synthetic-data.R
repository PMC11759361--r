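# Synthetic three-channel confocal fields of myelin-wrapped pillar arrays,
# with analytically known ground truth, plus synthetic AFM force curves and
# digital photomasks. Everything downstream is validated against these.

# rendering constants: dynamic range [0,1], quantized to 16-bit levels
.BG_INTENSITY <- 0.03
.FG_INTENSITY <- 0.85
.PHOTON_BUDGET <- 150   # photons at intensity 1.0 for Poisson shot noise

#' Describe a synthetic artificial-axon field
#'
#' Builds a validated [SyntheticFieldSpec-class]. Defaults reproduce the
#' platform's standard acquisition: a square pillar grid (3 um pillars at
#' 20 um spacing), an 8-slice z-stack at 2 um step imaged at 0.31 um/px with
#' a 20x air objective, myelin rendered as an annular arc of 0.6 um radial
#' thickness hugging the pillar boundary, 8 um nuclei placed in the
#' inter-pillar space, 0.4 um in-plane Gaussian blur, Poisson shot noise and
#' additive Gaussian read noise (sd 0.02 of the dynamic range).
#'
#' Wrap events are 1-based inclusive slice ranges; events for the same
#' pillar must not overlap in z. Pillars are indexed row-major
#' (1 = top-left).
#'
#' @param gridRows,gridCols pillar grid size.
#' @param spacingUm centre-to-centre spacing (um); must exceed
#'   \code{pillarDiameterUm + 2 * myelinThicknessUm}.
#' @param pillarDiameterUm pillar diameter (um).
#' @param nSlices,zStepUm z-stack geometry.
#' @param pixelSizeUm in-plane calibration (um/px).
#' @param wrapEvents data.frame with columns \code{pillar_index},
#'   \code{slice_start}, \code{slice_end}, \code{angular_coverage},
#'   \code{angular_offset}; see [wrapEvent()].
#' @param myelinThicknessUm radial thickness of the myelin annulus (um).
#' @param nNuclei,nucleusDiameterUm nuclei channel content.
#' @param blurSigmaUm in-plane Gaussian blur sigma (um); 0 disables.
#' @param gaussianSd read-noise sd (intensity units); 0 disables.
#' @param poisson apply Poisson shot-noise resampling.
#' @param seed integer seed controlling nuclei placement and noise.
#' @return a [SyntheticFieldSpec-class].
#' @examples
#' sp <- syntheticFieldSpec(wrapEvents = wrapEvent(5, 1, 4, 1.0))
#' sp
#' @export
syntheticFieldSpec <- function(gridRows = 3, gridCols = 3,
                               spacingUm = 20, pillarDiameterUm = 3,
                               nSlices = 8, zStepUm = 2,
                               pixelSizeUm = 0.31,
                               wrapEvents = emptyWrapEvents(),
                               myelinThicknessUm = 0.6,
                               nNuclei = 8, nucleusDiameterUm = 8,
                               blurSigmaUm = 0.4,
                               gaussianSd = 0.02, poisson = TRUE,
                               seed = 1L) {
  new("SyntheticFieldSpec",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      spacingUm = as.numeric(spacingUm),
      pillarDiameterUm = as.numeric(pillarDiameterUm),
      nSlices = as.integer(nSlices), zStepUm = as.numeric(zStepUm),
      pixelSizeUm = as.numeric(pixelSizeUm),
      wrapEvents = as.data.frame(wrapEvents),
      myelinThicknessUm = as.numeric(myelinThicknessUm),
      nNuclei = as.integer(nNuclei),
      nucleusDiameterUm = as.numeric(nucleusDiameterUm),
      blurSigmaUm = as.numeric(blurSigmaUm),
      gaussianSd = as.numeric(gaussianSd), poisson = as.logical(poisson),
      seed = as.integer(seed))
}

#' @rdname syntheticFieldSpec
#' @param pillarIndex row-major pillar index.
#' @param sliceStart,sliceEnd 1-based inclusive slice range of the event.
#' @param angularCoverage fraction of the circumference covered, in [0, 1].
#' @param angularOffset start angle of the arc (radians).
#' @export
wrapEvent <- function(pillarIndex, sliceStart, sliceEnd,
                      angularCoverage, angularOffset = 0) {
  data.frame(pillar_index = as.integer(pillarIndex),
             slice_start = as.integer(sliceStart),
             slice_end = as.integer(sliceEnd),
             angular_coverage = as.numeric(angularCoverage),
             angular_offset = as.numeric(angularOffset))
}

#' @rdname syntheticFieldSpec
#' @export
emptyWrapEvents <- function() {
  wrapEvent(integer(0), integer(0), integer(0), numeric(0), numeric(0))
}

#' Turn off blur and all noise in a field spec
#'
#' Convenience for the noise-free regime where the rendered raster equals the
#' analytic ground truth exactly.
#'
#' @param spec a [SyntheticFieldSpec-class].
#' @return the spec with \code{blurSigmaUm = 0}, \code{gaussianSd = 0},
#'   \code{poisson = FALSE}.
#' @export
noiseFree <- function(spec) {
  spec@blurSigmaUm <- 0
  spec@gaussianSd <- 0
  spec@poisson <- FALSE
  spec
}

# pillar centres in pixel coordinates (1-based, pixel centres at integers);
# row-major indexing. Margin of spacing/2 keeps every pillar interior.
.pillarCentres <- function(spec) {
  sp <- spec@spacingUm / spec@pixelSizeUm
  margin <- sp / 2
  cy <- margin + (seq_len(spec@gridRows) - 1L) * sp + 0.5
  cx <- margin + (seq_len(spec@gridCols) - 1L) * sp + 0.5
  grid <- expand.grid(x = cx, y = cy)   # x fastest -> row-major pillar index
  cbind(y = grid$y, x = grid$x)
}

.fieldDims <- function(spec) {
  sp <- spec@spacingUm / spec@pixelSizeUm
  side <- function(n) as.integer(ceiling((n - 1L) * sp + 2 * (sp / 2)) + 1L)
  c(H = side(spec@gridRows), W = side(spec@gridCols))
}

# bounding box of a disk of radius r about (cy, cx), clipped to the image
.bbox <- function(H, W, cy, cx, r) {
  list(ys = max(1L, floor(cy - r - 1)):min(H, ceiling(cy + r + 1)),
       xs = max(1L, floor(cx - r - 1)):min(W, ceiling(cx + r + 1)))
}

# logical H x W disk mask (computed on the disk's bounding box only)
.rasterDisk <- function(H, W, cy, cx, radiusPx) {
  out <- matrix(FALSE, H, W)
  bb <- .bbox(H, W, cy, cx, radiusPx)
  out[bb$ys, bb$xs] <- outer((bb$ys - cy)^2, (bb$xs - cx)^2, "+") <=
    radiusPx^2
  out
}

# logical H x W annular-arc mask: inner < d <= outer, angle within the arc
.rasterArc <- function(H, W, cy, cx, innerPx, outerPx, coverage, offset) {
  out <- matrix(FALSE, H, W)
  if (coverage <= 0) return(out)
  bb <- .bbox(H, W, cy, cx, outerPx)
  d2 <- outer((bb$ys - cy)^2, (bb$xs - cx)^2, "+")
  ring <- d2 > innerPx^2 & d2 <= outerPx^2
  if (coverage < 1) {
    ang <- atan2(outer(bb$ys - cy, rep(1, length(bb$xs))),
                 outer(rep(1, length(bb$ys)), bb$xs - cx))
    delta <- (ang - offset) %% (2 * pi)
    ring <- ring & delta < coverage * 2 * pi
  }
  out[bb$ys, bb$xs] <- ring
  out
}

#' Generate a digital photomask of pillar dot arrays
#'
#' Renders the printing mask used to photopolymerize pillar arrays: filled
#' white circles on a black background, \code{nArrays} blocks of
#' \code{rows x cols} dots each, tiled horizontally with a half-pitch margin
#' so all dots are disjoint.
#'
#' @param nArrays number of array blocks.
#' @param rows,cols dots per block.
#' @param dotRadiusPx dot radius in pixels (> 0).
#' @param pitchPx dot-to-dot pitch in pixels; must exceed
#'   \code{2 * dotRadiusPx} or the dots would merge (geometry error).
#' @return list with \code{mask} (integer 0/1 matrix) and \code{dotCount}.
#' @examples
#' pm <- generatePhotomask(2, 3, 4, dotRadiusPx = 2, pitchPx = 10)
#' pm$dotCount
#' @export
generatePhotomask <- function(nArrays, rows, cols, dotRadiusPx, pitchPx) {
  nArrays <- as.integer(nArrays); rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (nArrays < 1L || rows < 1L || cols < 1L)
    stop("nArrays, rows and cols must all be >= 1")
  if (dotRadiusPx <= 0) stop("dotRadiusPx must be positive")
  if (pitchPx <= 2 * dotRadiusPx)
    stop("geometry error: pitchPx must exceed 2 * dotRadiusPx, ",
         "otherwise adjacent dots overlap")
  blockW <- as.integer(ceiling((cols - 1L) * pitchPx + pitchPx) + 1L)
  blockH <- as.integer(ceiling((rows - 1L) * pitchPx + pitchPx) + 1L)
  H <- blockH
  W <- blockW * nArrays
  mask <- matrix(FALSE, H, W)
  cy <- pitchPx / 2 + (seq_len(rows) - 1L) * pitchPx + 0.5
  for (a in seq_len(nArrays)) {
    off <- (a - 1L) * blockW
    cx <- off + pitchPx / 2 + (seq_len(cols) - 1L) * pitchPx + 0.5
    for (yy in cy) for (xx in cx) {
      bb <- .bbox(H, W, yy, xx, dotRadiusPx)
      mask[bb$ys, bb$xs] <- mask[bb$ys, bb$xs] |
        (outer((bb$ys - yy)^2, (bb$xs - xx)^2, "+") <= dotRadiusPx^2)
    }
  }
  list(mask = matrix(as.integer(mask), H, W),
       dotCount = nArrays * rows * cols)
}

# analytic ground truth from the spec alone (pre blur/noise)
.groundTruth <- function(spec, centres, thetaC, lMinUm) {
  npil <- spec@gridRows * spec@gridCols
  cov <- matrix(0, npil, spec@nSlices)
  ev <- spec@wrapEvents
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      cov[ev$pillar_index[i], ev$slice_start[i]:ev$slice_end[i]] <-
        ev$angular_coverage[i]
    }
  }
  maxContig <- vapply(seq_len(npil), function(p) {
    r <- rle(cov[p, ] > thetaC)
    if (!any(r$values)) 0 else max(r$lengths[r$values]) * spec@zStepUm
  }, numeric(1))
  fully <- maxContig > lMinUm
  wi <- if (spec@nNuclei > 0L) sum(fully) / spec@nNuclei else NA_real_
  new("FieldGroundTruth",
      perPillar = data.frame(
        pillar_index = seq_len(npil),
        centroid_y_px = centres[, "y"],
        centroid_x_px = centres[, "x"],
        true_diameter_um = spec@pillarDiameterUm,
        max_contig_um = maxContig,
        fully_wrapped = fully),
      coverage = cov,
      nNuclei = spec@nNuclei,
      expectedWI = wi,
      thetaC = thetaC, lMinUm = lMinUm)
}

# place nuclei centres by bounded rejection sampling, off-pillar and
# non-overlapping; error when the field is too crowded
.placeNuclei <- function(spec, centres, H, W) {
  n <- spec@nNuclei
  if (n == 0L) return(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("y", "x"))))
  nr <- spec@nucleusDiameterUm / 2 / spec@pixelSizeUm
  keepOut <- spec@pillarDiameterUm / 2 / spec@pixelSizeUm +
    spec@myelinThicknessUm / spec@pixelSizeUm + nr + 2
  placed <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("y", "x")))
  got <- 0L
  attempts <- 0L
  maxAttempts <- 500L * n + 500L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not place ", n, " nuclei: field too crowded after ",
           maxAttempts, " rejection-sampling attempts")
    y <- runif(1, 1 + nr, H - nr)
    x <- runif(1, 1 + nr, W - nr)
    if (any((centres[, "y"] - y)^2 + (centres[, "x"] - x)^2 < keepOut^2))
      next
    if (got > 0L &&
        any((placed[seq_len(got), 1L] - y)^2 +
            (placed[seq_len(got), 2L] - x)^2 < (2 * nr + 2)^2))
      next
    got <- got + 1L
    placed[got, ] <- c(y, x)
  }
  placed
}

#' Generate a synthetic three-channel confocal field with ground truth
#'
#' Rasterizes the field described by \code{spec}: the axon channel holds
#' filled pillar cross-sections at every grid node in every slice, the
#' myelin channel holds annular arcs (inner radius = pillar radius) at the
#' slices named by the wrap events, and the nuclei channel holds spherical
#' nuclei placed in the inter-pillar space. Gaussian blur and shot/read
#' noise are applied after rasterization; intensities are clipped to [0, 1]
#' and quantized to 16-bit levels. Ground truth is computed analytically
#' from the spec before blur/noise, so it is exact. Identical spec + seed
#' give bit-identical voxels.
#'
#' @param spec a [SyntheticFieldSpec-class].
#' @param thetaC,lMinUm thresholds used for the ground-truth fully-wrapped
#'   flag and expected wrapping index (defaults: coverage > 0.8 over a
#'   contiguous segment > 6 um).
#' @return list with \code{stack} (an [AxonStack-class]) and \code{truth}
#'   (a [FieldGroundTruth-class]).
#' @examples
#' fl <- generateField(noiseFree(syntheticFieldSpec(
#'   wrapEvents = wrapEvent(1, 1, 4, 1.0), nNuclei = 5)))
#' fl$truth
#' @export
generateField <- function(spec, thetaC = 0.8, lMinUm = 6) {
  validObject(spec)
  set.seed(spec@seed)
  dims <- .fieldDims(spec)
  H <- dims[["H"]]; W <- dims[["W"]]
  Z <- spec@nSlices
  centres <- .pillarCentres(spec)
  rPx <- spec@pillarDiameterUm / 2 / spec@pixelSizeUm
  tPx <- spec@myelinThicknessUm / spec@pixelSizeUm

  axon <- array(.BG_INTENSITY, dim = c(Z, H, W))
  myelin <- array(.BG_INTENSITY, dim = c(Z, H, W))
  nuclei <- array(.BG_INTENSITY, dim = c(Z, H, W))

  # pillar disks identical in every slice
  disk <- matrix(FALSE, H, W)
  for (p in seq_len(nrow(centres)))
    disk <- disk | .rasterDisk(H, W, centres[p, "y"], centres[p, "x"], rPx)
  for (z in seq_len(Z)) axon[z, , ][disk] <- .FG_INTENSITY

  ev <- spec@wrapEvents
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      p <- ev$pillar_index[i]
      arc <- .rasterArc(H, W, centres[p, "y"], centres[p, "x"],
                        rPx, rPx + tPx,
                        ev$angular_coverage[i], ev$angular_offset[i])
      for (z in ev$slice_start[i]:ev$slice_end[i])
        myelin[z, , ][arc] <- .FG_INTENSITY
    }
  }

  nucCentres <- .placeNuclei(spec, centres, H, W)
  if (nrow(nucCentres)) {
    nrUm <- spec@nucleusDiameterUm / 2
    zc <- runif(nrow(nucCentres), 1, Z)   # sphere centre in slice units
    for (k in seq_len(nrow(nucCentres))) {
      for (z in seq_len(Z)) {
        dzUm <- (z - zc[k]) * spec@zStepUm
        r2 <- nrUm^2 - dzUm^2
        if (r2 <= 0) next
        rSlicePx <- sqrt(r2) / spec@pixelSizeUm
        blob <- .rasterDisk(H, W, nucCentres[k, "y"], nucCentres[k, "x"],
                            rSlicePx)
        nuclei[z, , ][blob] <- .FG_INTENSITY
      }
    }
  }

  truth <- .groundTruth(spec, centres, thetaC, lMinUm)

  degrade <- function(arr) {
    if (spec@blurSigmaUm > 0) {
      sPx <- spec@blurSigmaUm / spec@pixelSizeUm
      for (z in seq_len(Z))
        arr[z, , ] <- EBImage::gblur(arr[z, , ], sigma = sPx)
    }
    if (spec@poisson)
      arr[] <- rpois(length(arr), pmax(arr, 0) * .PHOTON_BUDGET) /
        .PHOTON_BUDGET
    if (spec@gaussianSd > 0)
      arr[] <- arr + rnorm(length(arr), 0, spec@gaussianSd)
    arr[] <- pmin(pmax(arr, 0), 1)
    arr[] <- round(arr * 65535) / 65535
    arr
  }
  axon <- degrade(axon); myelin <- degrade(myelin); nuclei <- degrade(nuclei)

  voxels <- array(0, dim = c(3L, Z, H, W))
  voxels[1L, , , ] <- axon
  voxels[2L, , , ] <- myelin
  voxels[3L, , , ] <- nuclei
  stack <- AxonStack(voxels, c(axon = 1L, myelin = 2L, nuclei = 3L),
                     spec@pixelSizeUm, spec@zStepUm,
                     fieldId = paste0("synthetic-", spec@seed))
  list(stack = stack, truth = truth)
}

#' Closed-form spherical Hertzian contact force
#'
#' \eqn{F(\delta) = (4/3) (E / (1 - \nu^2)) \sqrt{R}\, \delta^{3/2}} for a
#' rigid sphere of radius R indenting an elastic half-space of Young's
#' modulus E and Poisson ratio \eqn{\nu}.
#'
#' @param depth indentation depth(s), metres.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @param probeRadius sphere radius, metres.
#' @return force(s), newtons.
#' @export
hertzForce <- function(depth, E, nu, probeRadius) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(probeRadius) * depth^1.5
}

#' Generate a synthetic AFM force-indentation curve
#'
#' Samples the spherical Hertzian contact force on a uniform depth grid and
#' adds zero-mean Gaussian force noise. Seed-reproducible.
#'
#' @param E Young's modulus (Pa, > 0).
#' @param nu Poisson ratio in [0, 0.5] (default 0.5, incompressible
#'   hydrogel).
#' @param probeRadius probe radius (m, > 0; default 0.75 um, a 1.5 um
#'   spherical probe).
#' @param depthMax maximum indentation depth (m; default 200 nm).
#' @param nPoints number of samples (>= 10).
#' @param noiseSd additive force noise sd (N); 0 gives the exact closed
#'   form.
#' @param seed integer RNG seed.
#' @param springConstant cantilever spring constant (N/m), carried as
#'   metadata.
#' @param label sample label.
#' @return a [ForceCurve-class].
#' @examples
#' fc <- generateForceCurve(780, noiseSd = 0)
#' fitHertz(fc)
#' @export
generateForceCurve <- function(E, nu = 0.5, probeRadius = 0.75e-6,
                               depthMax = 200e-9, nPoints = 100,
                               noiseSd = 0, seed = 1L,
                               springConstant = 0.1, label = "") {
  if (E <= 0) stop("non-physical input: E must be positive")
  if (probeRadius <= 0) stop("non-physical input: probeRadius must be positive")
  if (nu < 0 || nu > 0.5) stop("nu must lie in [0, 0.5]")
  if (nPoints < 10L) stop("nPoints must be >= 10")
  depth <- seq(0, depthMax, length.out = nPoints)
  force <- hertzForce(depth, E, nu, probeRadius)
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    force <- force + rnorm(nPoints, 0, noiseSd)
  }
  new("ForceCurve", depth = depth, force = force,
      probeRadius = probeRadius, springConstant = springConstant,
      label = as.character(label))
}

#' Randomized synthetic field specs for recovery studies
#'
#' Study-design helper producing fields with randomized wrap events and
#' nuclei counts. Each pillar independently receives a wrap event with
#' probability 0.7; angular coverage is drawn from
#' \{0.30, 0.50, 0.70, 0.90, 1.00\} (both sides of the 0.8 decision
#' boundary, kept more than one outline-pixel-equivalent away from it so the
#' ground-truth label is well defined on the pixel raster), the axial span
#' uniformly from 1..6 slices at a uniform start, the angular offset
#' uniformly on [0, 2*pi), and the nuclei count uniformly from 4..8 — about
#' as many non-overlapping 8 um nuclei as the inter-pillar space of a
#' 60 x 60 um field accommodates.
#'
#' @param seed integer seed (drives both the randomized design and the
#'   rendering noise).
#' @param gridRows,gridCols pillar grid size.
#' @param ... further arguments passed to [syntheticFieldSpec()]
#'   (e.g. noise settings).
#' @return a [SyntheticFieldSpec-class].
#' @export
randomFieldSpec <- function(seed, gridRows = 3, gridCols = 3, ...) {
  set.seed(as.integer(seed))
  npil <- gridRows * gridCols
  covLevels <- c(0.30, 0.50, 0.70, 0.90, 1.00)
  evs <- list()
  nSlices <- 8L
  for (p in seq_len(npil)) {
    if (runif(1) > 0.7) next
    span <- sample(1:6, 1)
    start <- sample(seq_len(nSlices - span + 1L), 1)
    evs[[length(evs) + 1L]] <- wrapEvent(
      p, start, start + span - 1L,
      sample(covLevels, 1), runif(1, 0, 2 * pi))
  }
  wrapEvents <- if (length(evs)) do.call(rbind, evs) else emptyWrapEvents()
  nNuclei <- sample(4:8, 1)
  syntheticFieldSpec(gridRows = gridRows, gridCols = gridCols,
                     nSlices = nSlices,
                     wrapEvents = wrapEvents, nNuclei = nNuclei,
                     seed = seed, ...)
}

#' Write / read a field spec as JSON
#'
#' @param spec a [SyntheticFieldSpec-class].
#' @param path output / input file path.
#' @return \code{readFieldSpec}: a [SyntheticFieldSpec-class];
#'   \code{writeFieldSpec}: \code{path}, invisibly.
#' @export
writeFieldSpec <- function(spec, path) {
  x <- list(
    grid_rows = spec@gridRows, grid_cols = spec@gridCols,
    spacing_um = spec@spacingUm, pillar_diameter_um = spec@pillarDiameterUm,
    n_slices = spec@nSlices, z_step_um = spec@zStepUm,
    pixel_size_um = spec@pixelSizeUm,
    wrap_events = spec@wrapEvents,
    myelin_thickness_um = spec@myelinThicknessUm,
    n_nuclei = spec@nNuclei, nucleus_diameter_um = spec@nucleusDiameterUm,
    blur_sigma_um = spec@blurSigmaUm,
    noise_model = list(gaussian_sd = spec@gaussianSd,
                       poisson = spec@poisson),
    seed = spec@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFieldSpec
#' @export
readFieldSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- if (is.data.frame(x$wrap_events) && nrow(x$wrap_events))
    x$wrap_events else emptyWrapEvents()
  syntheticFieldSpec(
    gridRows = x$grid_rows, gridCols = x$grid_cols,
    spacingUm = x$spacing_um, pillarDiameterUm = x$pillar_diameter_um,
    nSlices = x$n_slices, zStepUm = x$z_step_um,
    pixelSizeUm = x$pixel_size_um, wrapEvents = ev,
    myelinThicknessUm = x$myelin_thickness_um,
    nNuclei = x$n_nuclei, nucleusDiameterUm = x$nucleus_diameter_um,
    blurSigmaUm = x$blur_sigma_um,
    gaussianSd = x$noise_model$gaussian_sd,
    poisson = x$noise_model$poisson,
    seed = x$seed)
}

#' Write ground truth as a per-pillar CSV
#'
#' @param truth a [FieldGroundTruth-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  write.csv(truth@perPillar, path, row.names = FALSE)
  invisible(path)
}
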