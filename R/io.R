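## Multi-page TIFF input/output, page-layout handling and visualization
## plumbing. Raw SIM exports from different acquisition software order
## their pages differently; a LayoutSpec (axis-order string over
## {c, t, z, a, p}, fastest-varying axis last, plus per-axis counts)
## describes the page order so any grayscale multi-page TIFF can be
## rearranged into the canonical (channel, time, z, angle, phase, y, x)
## stack. Float pages are stored normalized to [0, 1]; the original
## intensity range and all parameters travel in a JSON sidecar.

#' Page-layout specification for multi-page TIFFs
#'
#' @param order string over the axis letters `c` (channel), `t` (time),
#'   `z`, `a` (angle), `p` (phase); the last letter varies fastest from
#'   page to page. Each axis at most once.
#' @param counts named integer vector giving the extent of every axis in
#'   `order`.
#' @return list of class `"LayoutSpec"` with `order` and `counts`.
#' @examples
#' layoutSpec("ap", c(a = 3, p = 3))   # phase fastest, 9 pages
#' @export
layoutSpec <- function(order, counts) {
  ax <- strsplit(order, "")[[1]]
  if (!all(ax %in% c("c", "t", "z", "a", "p")))
    stopf("layout axes must be among c, t, z, a, p; got '%s'", order)
  if (anyDuplicated(ax)) stopf("every axis may appear at most once")
  if (!all(ax %in% names(counts)))
    stopf("counts must name every axis in '%s'", order)
  structure(list(order = ax, counts = as.integer(counts[ax])),
            class = "LayoutSpec")
}

#' Read a raw SIM stack from a multi-page TIFF
#'
#' Pages are reordered into the canonical
#' `(channel, time, z, angle, phase, y, x)` axes according to the layout.
#' Integer pages are read at their stored bit depth and converted to
#' numeric; values must be finite. RGB input is rejected.
#'
#' @param path TIFF file path.
#' @param layout a [layoutSpec()] describing the page order.
#' @param optical an [OpticalModel-class] for the acquisition.
#' @param metadata named list of acquisition tags; if a JSON sidecar
#'   written by [writeStack()] exists next to `path`, its recorded
#'   intensity scale is applied automatically.
#' @return a [SIMRawStack-class].
#' @export
readStack <- function(path, layout, optical, metadata = list()) {
  info <- tiff::readTIFF(path, payload = FALSE)
  # 32-bit pages are floats (read as stored); integer pages are read at
  # their raw bit depth rather than rescaled to [0, 1]
  isFloat <- info$bits.per.sample[1] == 32L
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !isFloat)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stopf("RGB/multi-sample TIFF input is not supported; supply grayscale pages")
  expected <- prod(layout$counts)
  if (length(pages) != expected)
    stopf("page-count mismatch: layout expects %d pages, file has %d",
          expected, length(pages))
  scale <- 1
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$intensity_scale)) scale <- sc$intensity_scale
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  counts <- stats::setNames(rep(1L, 5), c("c", "t", "z", "a", "p"))
  counts[layout$order] <- layout$counts
  data <- array(0, c(counts, ny, nx))
  nax <- length(layout$order)
  for (pg in seq_along(pages)) {
    rem <- pg - 1L
    idx <- counts * 0L + 1L
    for (ai in rev(seq_len(nax))) {    # last axis varies fastest
      n <- layout$counts[ai]
      idx[layout$order[ai]] <- rem %% n + 1L
      rem <- rem %/% n
    }
    data[idx["c"], idx["t"], idx["z"], idx["a"], idx["p"], , ] <-
      as.numeric(pages[[pg]]) * scale
  }
  if (!all(is.finite(data))) stopf("non-finite intensities in '%s'", path)
  data[data < 0] <- 0
  simRawStack(data, optical, metadata)
}

#' Write a raw SIM stack as a multi-page TIFF with JSON sidecar
#'
#' Pages are written in canonical order with phase varying fastest
#' (layout string `"ctzap"`). Intensities are normalized to `[0, 1]` for
#' 32-bit float storage; the scale factor, layout and optical metadata go
#' into `<path without extension>.json`.
#'
#' @param raw a [SIMRawStack-class].
#' @param path output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
writeStack <- function(raw, path) {
  d <- dim(raw@data)
  # power-of-two scale: division and re-multiplication are exact in
  # binary floating point, so write/read cycles are stable
  mx <- max(raw@data)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  pages <- vector("list", prod(d[1:5]))
  pg <- 0L
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3]))
    for (ai in seq_len(d[4])) for (ji in seq_len(d[5])) {
      pg <- pg + 1L
      pages[[pg]] <- raw@data[ci, ti, zi, ai, ji, , ] / scale
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(intensity_scale = scale,
         layout = list(order = "ctzap", counts = as.list(d[1:5])),
         pixel_nm = raw@optical@pixelNm,
         wavelength_nm = raw@optical@wavelengthNm, na = raw@optical@na,
         metadata = raw@metadata),
    sidecar, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(sidecar)
}

#' Write a reconstruction result with provenance sidecar
#'
#' Writes `<pathPrefix>.tif` (32-bit float, normalized to `[0, 1]`) and
#' `<pathPrefix>.json` holding the intensity scale, the effective pixel
#' size (`pixel_nm / upsample`) and the full parameter/settings provenance
#' needed to reproduce the reconstruction.
#'
#' @param result a [ReconstructionResult-class].
#' @param pathPrefix output path without extension.
#' @return invisibly, a character vector of the two file paths.
#' @export
writeOutputs <- function(result, pathPrefix) {
  tifPath <- paste0(pathPrefix, ".tif")
  jsonPath <- paste0(pathPrefix, ".json")
  mx <- max(result@srImage)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  tiff::writeTIFF(result@srImage / scale, tifPath, bits.per.sample = 32L)
  jsonlite::write_json(
    c(list(intensity_scale = scale, pixel_nm = result@pixelNm),
      result@provenance),
    jsonPath, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(c(tif = tifPath, json = jsonPath))
}

#' Rebuild parameters and settings from a provenance sidecar
#'
#' Re-ingests the JSON sidecar written by [writeOutputs()] so a
#' reconstruction can be reproduced exactly without re-estimating the
#' illumination.
#'
#' @param path sidecar JSON path.
#' @return list with `params` ([IlluminationParams-class]) and `settings`
#'   ([ReconSettings-class]).
#' @export
readProvenance <- function(path) {
  pv <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- new("IlluminationParams",
                k0 = matrix(unlist(pv$k0), ncol = 2,
                            dimnames = list(NULL, c("ky", "kx"))),
                phases = matrix(unlist(pv$phases), nrow = nrow(matrix(unlist(pv$k0), ncol = 2))),
                m = as.numeric(pv$m),
                quality = as.numeric(ifelse(is.na(pv$quality), 0, pv$quality)))
  settings <- reconSettings(
    wienerW = pv$wiener_w, apodization = pv$apodization,
    upsample = pv$upsample, notchDc = isTRUE(pv$notch_dc),
    intensityCorrection = pv$intensity_correction,
    dcSigmaPx = if (is.null(pv$dc_sigma_px) || is.na(pv$dc_sigma_px))
      NA_real_ else pv$dc_sigma_px,
    dcCombine = pv$dc_combine,
    dcOpenRadiusPx = if (is.null(pv$dc_open_radius_px) ||
                           is.na(pv$dc_open_radius_px)) NA_real_
                     else pv$dc_open_radius_px)
  list(params = params, settings = settings)
}

#' Depth-coded maximum intensity projection
#'
#' For every (y, x) the maximum intensity over z and the z index of that
#' maximum are computed; the hue encodes the plane of the maximum and the
#' value its normalized intensity.
#'
#' @param srStack 3-d array `(z, y, x)` with at least 2 planes.
#' @param hueRange hue endpoints (HSV, in `[0, 1]`) mapped to the first
#'   and last z plane.
#' @return list: `rgb` array `(y, x, 3)` in `[0, 1]`, `depthMap` matrix of
#'   argmax z indices, `mip` the maximum-intensity projection.
#' @export
depthCodeProjection <- function(srStack, hueRange = c(0.7, 0)) {
  d <- dim(srStack)
  if (length(d) != 3) stopf("srStack must be a 3-d (z, y, x) array")
  nz <- d[1]
  if (nz < 2)
    stopf("depth coding needs >= 2 z planes; use a plain projection for one")
  mip <- apply(srStack, c(2, 3), max)
  depth <- apply(srStack, c(2, 3), which.max)
  hue <- hueRange[1] + (depth - 1) / (nz - 1) * (hueRange[2] - hueRange[1])
  val <- if (max(mip) > 0) mip / max(mip) else mip
  cols <- grDevices::hsv(h = as.vector(hue), s = 1, v = pmin(as.vector(val), 1))
  rgbm <- grDevices::col2rgb(cols) / 255
  rgb <- array(0, c(d[2], d[3], 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(rgbm[ch, ], d[2], d[3])
  list(rgb = rgb, depthMap = depth, mip = mip)
}
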