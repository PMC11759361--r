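# Channel thresholding, pillar detection with z-linkage, nuclei counting and
# pillar diameter measurement.

# Otsu threshold on the pooled 3-D histogram (one threshold per channel, not
# per slice): the channel's voxels are flattened into a single frame so
# EBImage's Otsu sees the pooled distribution.
.pooledOtsu <- function(vol) {
  v <- as.vector(vol)
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = c(0, 1))
}

#' Threshold one channel to a binary volume
#'
#' For \code{method = "otsu"} a single Otsu threshold is computed on the
#' pooled 3-D histogram of the channel (not slice by slice) and applied to
#' every voxel. \code{method = "robust-otsu"} takes the maximum of the
#' pooled Otsu threshold and a robust background floor
#' (\code{median + 6 * mad} of the channel): two-class Otsu degenerates
#' when the foreground occupies a tiny fraction of the voxels (it then
#' splits the background noise in half), and the floor guards against
#' exactly that while leaving sane Otsu thresholds untouched — the
#' recommended method for sparse stains such as MBP on lightly wrapped
#' fields. A fixed threshold can be given as \code{method = "fixed"} with
#' \code{value}. The chosen threshold is recorded in the result's
#' attributes.
#'
#' @param stack an [AxonStack-class].
#' @param role channel role to threshold.
#' @param method \code{"otsu"} (default), \code{"robust-otsu"} or
#'   \code{"fixed"}.
#' @param value fixed threshold (required for \code{method = "fixed"}).
#' @return logical 3-D array (Z, Y, X), voxels strictly above the threshold;
#'   attributes \code{threshold} and \code{method} record what was applied.
#' @export
thresholdChannel <- function(stack, role,
                             method = c("otsu", "robust-otsu", "fixed"),
                             value = NULL) {
  method <- match.arg(method)
  vol <- channelData(stack, role)
  if (method %in% c("otsu", "robust-otsu")) {
    rng <- range(vol)
    if (rng[1L] == rng[2L])
      stop("channel '", role, "' has constant intensity; Otsu is undefined. ",
           "Use method = 'fixed' with an explicit threshold.")
    thr <- .pooledOtsu(vol)
    if (method == "robust-otsu")
      thr <- max(thr, median(vol) + 6 * stats::mad(vol))
  } else {
    if (is.null(value)) stop("method = 'fixed' requires a threshold value")
    thr <- as.numeric(value)
  }
  mask <- vol > thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

# label one slice; returns list of components, each with centroid (y, x),
# area, pixel matrix and a border flag
.sliceComponents <- function(sliceMask, minAreaPx) {
  H <- nrow(sliceMask); W <- ncol(sliceMask)
  lab <- EBImage::bwlabel(EBImage::Image(sliceMask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L)
  ys <- ((idx - 1L) %% H) + 1L
  xs <- ((idx - 1L) %/% H) + 1L
  lv <- lab[idx]
  out <- vector("list", n)
  keep <- logical(n)
  for (j in seq_len(n)) {
    sel <- lv == j
    a <- sum(sel)
    if (a < minAreaPx) next
    y <- ys[sel]; x <- xs[sel]
    keep[j] <- TRUE
    out[[j]] <- list(centroid = c(y = mean(y), x = mean(x)),
                     area = a,
                     pixels = cbind(y = y, x = x),
                     border = any(y == 1L | y == H | x == 1L | x == W))
  }
  out[keep]
}

#' Detect pillars and link them through z
#'
#' Per-slice connected components of the axon mask with area at least
#' \code{minAreaPx} are linked greedily across adjacent slices by nearest
#' centroid within \code{maxLinkDistPx}; unmatched components start new
#' traces. Traces touching the image border are flagged and, under the
#' default \code{borderPolicy = "exclude"}, removed. Traces present in fewer
#' than \code{minSliceFrac} of the slices are dropped as debris (pillars
#' span the full imaged height). Pillar ids are assigned deterministically:
#' traces sorted row-major (y, then x) by first-slice centroid.
#'
#' @param axonMask logical 3-D array (Z, Y, X) from [thresholdChannel()].
#' @param minAreaPx minimum per-slice component area (pixels).
#' @param maxLinkDistPx maximum centroid displacement between consecutive
#'   slices for linkage (pixels).
#' @param borderPolicy \code{"exclude"} (default) or \code{"keep"} traces
#'   touching the image border.
#' @param minSliceFrac minimum fraction of slices a trace must appear in
#'   (default 0.5).
#' @return list of [PillarTrace-class], ordered by pillar id; empty mask
#'   gives an empty list.
#' @export
detectPillars <- function(axonMask, minAreaPx = 9, maxLinkDistPx = 10,
                          borderPolicy = c("exclude", "keep"),
                          minSliceFrac = 0.5) {
  borderPolicy <- match.arg(borderPolicy)
  Z <- dim(axonMask)[1L]
  traces <- list()   # each: list(z=, centroids=, areas=, pixels=, border=)
  active <- integer(0)   # indices into traces linkable to the next slice
  for (z in seq_len(Z)) {
    comps <- .sliceComponents(axonMask[z, , ], minAreaPx)
    if (!length(comps)) { active <- integer(0); next }
    newActive <- integer(0)
    if (length(active)) {
      lastC <- do.call(rbind, lapply(traces[active], function(tr)
        tr$centroids[nrow(tr$centroids), ]))
      compC <- do.call(rbind, lapply(comps, `[[`, "centroid"))
      d <- sqrt(outer(lastC[, 1L], compC[, 1L], "-")^2 +
                outer(lastC[, 2L], compC[, 2L], "-")^2)
      # greedy by ascending distance
      pairs <- which(d <= maxLinkDistPx, arr.ind = TRUE)
      takenT <- logical(length(active)); takenC <- logical(length(comps))
      if (nrow(pairs)) {
        pairs <- pairs[order(d[pairs]), , drop = FALSE]
        for (r in seq_len(nrow(pairs))) {
          ti <- pairs[r, 1L]; ci <- pairs[r, 2L]
          if (takenT[ti] || takenC[ci]) next
          takenT[ti] <- TRUE; takenC[ci] <- TRUE
          gi <- active[ti]
          cm <- comps[[ci]]
          traces[[gi]]$z <- c(traces[[gi]]$z, z)
          traces[[gi]]$centroids <- rbind(traces[[gi]]$centroids,
                                          cm$centroid)
          traces[[gi]]$areas <- c(traces[[gi]]$areas, cm$area)
          traces[[gi]]$pixels <- c(traces[[gi]]$pixels, list(cm$pixels))
          traces[[gi]]$border <- traces[[gi]]$border || cm$border
          newActive <- c(newActive, gi)
        }
      }
      comps <- comps[!takenC]
    }
    for (cm in comps) {
      traces[[length(traces) + 1L]] <- list(
        z = z, centroids = matrix(cm$centroid, 1L, 2L,
                                  dimnames = list(NULL, c("y", "x"))),
        areas = cm$area, pixels = list(cm$pixels), border = cm$border)
      newActive <- c(newActive, length(traces))
    }
    active <- newActive
  }
  if (!length(traces)) return(list())
  # debris + border policy
  keep <- vapply(traces, function(tr)
    length(tr$z) >= minSliceFrac * Z, logical(1))
  if (borderPolicy == "exclude")
    keep <- keep & !vapply(traces, `[[`, logical(1), "border")
  traces <- traces[keep]
  if (!length(traces)) return(list())
  first <- t(vapply(traces, function(tr) tr$centroids[1L, ], numeric(2)))
  ord <- order(round(first[, 1L]), round(first[, 2L]))
  traces <- traces[ord]
  lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    cen <- tr$centroids
    dimnames(cen) <- list(NULL, c("y", "x"))
    new("PillarTrace", pillarId = i, z = as.integer(tr$z),
        centroids = cen, areas = as.integer(tr$areas),
        pixels = tr$pixels,
        complete = length(tr$z) == Z,
        borderTouching = tr$border)
  })
}

#' Count nuclei on a z maximum projection
#'
#' The nuclei mask is max-projected over z and connected components with
#' area at least \code{minAreaPx} are counted. No declumping is attempted:
#' the wrapping index normalizes by a plain nuclei count.
#'
#' @param nucleiMask logical 3-D array (Z, Y, X).
#' @param minAreaPx minimum projected component area in pixels (default the
#'   area of a 4 um disk at 0.31 um/px).
#' @return integer count.
#' @export
countNuclei <- function(nucleiMask, minAreaPx = round(pi * (2 / 0.31)^2)) {
  proj <- colSums(nucleiMask) > 0   # z max-projection (any over dim 1)
  if (!any(proj)) return(0L)
  lab <- EBImage::bwlabel(EBImage::Image(proj * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  areas <- tabulate(lab[lab > 0L])
  sum(areas >= minAreaPx)
}

#' Measure a pillar's equivalent-circle diameter
#'
#' \eqn{d = 2 \sqrt{A/\pi} \cdot s} where A is the median cross-section
#' area over the trace's slices (pixels) and s the pixel size (um/px).
#'
#' @param trace a [PillarTrace-class] with at least one slice entry.
#' @param pixelSizeUm pixel size (um/px).
#' @return diameter in micrometres.
#' @export
measureDiameter <- function(trace, pixelSizeUm) {
  if (!is(trace, "PillarTrace") || length(trace@areas) == 0L)
    stop("measureDiameter needs a trace with at least one slice entry")
  2 * sqrt(median(trace@areas) / pi) * pixelSizeUm
}
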