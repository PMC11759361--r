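# Reading and writing calibrated multichannel z-stacks (multi-page TIFF with
# a JSON calibration sidecar) and the plate manifest.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write an AxonStack as a multi-page TIFF
#'
#' Pages are ordered channel-major then z (all slices of channel 1, then
#' channel 2, ...), matching the (C, Z, Y, X) voxel layout. Intensities must
#' lie in [0, 1] and contain no NaN. 8- and 16-bit output is lossless for
#' intensities on the corresponding integer grid (the synthetic generator
#' quantizes to 16-bit levels); 32-bit output stores IEEE float32.
#' Calibration, channel roles and labels are written to a JSON sidecar
#' (\code{<path>.json}) so the round trip preserves metadata bit-exactly.
#'
#' @param stack an [AxonStack-class].
#' @param path output TIFF path.
#' @param bitsPerSample 8, 16 (default) or 32.
#' @return \code{path}, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path, bitsPerSample = 16L) {
  validObject(stack)
  if (anyNA(stack@voxels) || any(!is.finite(stack@voxels)))
    stop("stack contains NaN or non-finite voxels; refusing to write")
  if (min(stack@voxels) < 0 || max(stack@voxels) > 1)
    stop("voxel intensities must lie in [0, 1]")
  if (!bitsPerSample %in% c(8L, 16L, 32L))
    stop("bitsPerSample must be 8, 16 or 32")
  d <- dim(stack@voxels)
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (ch in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      k <- k + 1L
      m <- stack@voxels[ch, z, , , drop = FALSE]
      dim(m) <- d[3:4]
      pages[[k]] <- m
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to '", path, "': ",
         attr(ok, "condition")$message)
  meta <- list(n_channels = d[1L], n_slices = d[2L],
               channel_roles = as.list(stack@channelRoles),
               pixel_size_um = stack@pixelSizeUm,
               z_step_um = stack@zStepUm,
               field_id = stack@fieldId, well_id = stack@wellId,
               condition = stack@condition)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel z-stack from TIFF
#'
#' Reads a single- or multi-page TIFF written page order channel-major then
#' z. Metadata comes from the JSON sidecar when present; explicit arguments
#' always override file metadata, with a warning when they disagree (exported
#' TIFFs frequently carry absent or corrupted physical calibration).
#'
#' @param path TIFF file path.
#' @param channelMap named vector mapping roles \code{axon}, \code{myelin},
#'   \code{nuclei} to channel indices; \code{NULL} to take it from the
#'   sidecar.
#' @param pixelSizeUm,zStepUm explicit calibration overrides; \code{NULL}
#'   to take them from the sidecar.
#' @param nChannels number of channels; \code{NULL} to take it from the
#'   sidecar, falling back to \code{max(channelMap)}.
#' @return a validated [AxonStack-class].
#' @export
readStack <- function(path, channelMap = NULL, pixelSizeUm = NULL,
                      zStepUm = NULL, nChannels = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file '", path, "'")
  pages <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("unreadable TIFF '", path, "'")
  meta <- NULL
  if (file.exists(.sidecarPath(path)))
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)

  pick <- function(explicit, stored, what) {
    if (is.null(explicit)) {
      if (is.null(stored)) stop("no ", what,
                                " in sidecar and none given explicitly")
      stored
    } else {
      if (!is.null(stored) && !isTRUE(all.equal(unname(unlist(stored)),
                                                unname(unlist(explicit)))))
        warning("explicit ", what, " overrides file metadata")
      explicit
    }
  }
  roles <- pick(channelMap, meta$channel_roles, "channel map")
  roles <- unlist(roles)
  storage.mode(roles) <- "integer"
  need <- c("axon", "myelin", "nuclei")
  if (!all(need %in% names(roles)))
    stop("missing role: channel map must cover ",
         paste(setdiff(need, names(roles)), collapse = ", "))
  px <- as.numeric(pick(pixelSizeUm, meta$pixel_size_um, "pixel size"))
  zs <- as.numeric(pick(zStepUm, meta$z_step_um, "z step"))
  C <- if (!is.null(nChannels)) as.integer(nChannels)
       else if (!is.null(meta$n_channels)) as.integer(meta$n_channels)
       else max(roles)
  nPages <- length(pages)
  if (nPages %% C != 0L)
    stop("page count ", nPages, " is not a multiple of ", C, " channels")
  Z <- nPages %/% C
  if (max(roles) > C) stop("missing role: channel index exceeds channel count")
  pg <- pages[[1L]]
  if (length(dim(pg)) > 2L) pg <- pg[, , 1L]   # tolerate grayscale-as-RGB
  H <- nrow(pg); W <- ncol(pg)
  voxels <- array(0, dim = c(C, Z, H, W))
  k <- 0L
  for (ch in seq_len(C)) {
    for (z in seq_len(Z)) {
      k <- k + 1L
      m <- pages[[k]]
      if (length(dim(m)) > 2L) m <- m[, , 1L]
      if (nrow(m) != H || ncol(m) != W)
        stop("shape mismatch across channels/slices in '", path, "'")
      voxels[ch, z, , ] <- m
    }
  }
  AxonStack(voxels, roles, px, zs,
            fieldId = if (!is.null(meta$field_id)) meta$field_id else "",
            wellId = if (!is.null(meta$well_id)) meta$well_id else "",
            condition = if (!is.null(meta$condition)) meta$condition else "")
}

#' Load and validate a plate manifest
#'
#' The manifest is a CSV with header columns \code{well_id},
#' \code{field_id}, \code{condition}, \code{path}, one row per imaged field.
#' (well, field) pairs must be unique and every referenced file must exist;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param checkPaths verify that every referenced stack file exists
#'   (default TRUE).
#' @return data.frame with the four columns, paths resolved.
#' @export
loadManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path)) stop("no such manifest: '", path, "'")
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "field_id", "condition", "path")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest is missing required columns: ",
         paste(missing, collapse = ", "))
  key <- paste(m$well_id, m$field_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop("duplicate (well_id, field_id) in manifest at row ", dup,
         ": (", m$well_id[dup], ", ", m$field_id[dup], ")")
  }
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                file.path(base, m$path))
  if (checkPaths) {
    bad <- which(!file.exists(abs))
    if (length(bad))
      stop("manifest row ", bad[1L], " references a nonexistent file: '",
           m$path[bad[1L]], "'")
  }
  m$path <- abs
  m[, need]
}
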