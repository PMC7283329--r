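# Reflectance calibration, grain segmentation, per-sample spectrum extraction.

#' Hyperspectral cube container
#'
#' @param values rows x cols x bands numeric array of reflectance.
#' @param wavelengths strictly increasing band centers in nm, within
#'   \[390, 1010\].
#' @return object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(values, wavelengths) {
  if (!is.array(values) || length(dim(values)) != 3L)
    gs_stop("values must be a rows x cols x bands array", class = "config_error")
  if (dim(values)[3] != length(wavelengths))
    gs_stop("band count must match wavelength count", class = "config_error")
  if (is.unsorted(wavelengths, strictly = TRUE))
    gs_stop("wavelengths must be strictly increasing", class = "config_error")
  if (min(wavelengths) < 390 || max(wavelengths) > 1010)
    gs_stop("wavelengths must lie within [390, 1010] nm", class = "config_error")
  structure(list(values = values, wavelengths = as.numeric(wavelengths)),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("hyperspectral_cube: %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Per-sample spectra table
#'
#' @param spectra samples x bands numeric matrix of reflectance.
#' @param wavelengths band centers in nm.
#' @param sample_ids sample identifiers.
#' @return object of class `spectra_table`.
#' @export
spectra_table <- function(spectra, wavelengths, sample_ids = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    gs_stop("spectra columns must match wavelength count", class = "config_error")
  if (!all(is.finite(spectra)))
    gs_stop("spectra must be finite", class = "config_error")
  if (is.null(sample_ids)) sample_ids <- rownames(spectra) %||% sprintf("S%d", seq_len(nrow(spectra)))
  rownames(spectra) <- sample_ids
  colnames(spectra) <- format(wavelengths, trim = TRUE)
  structure(list(spectra = spectra, wavelengths = as.numeric(wavelengths),
                 sample_ids = sample_ids),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("spectra_table: %d samples x %d bands (%g-%g nm)\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' White/dark reflectance calibration
#'
#' Converts raw counts to relative reflectance per pixel and band:
#' I = (I0 - D) / (W - D), where I0 is the raw image, W the white-reference
#' and D the dark-current image. The scale runs from 0 (no reflectance) to 1
#' (100% of the white reference); values outside \[0, 1\] are kept unless a
#' clip range is supplied, since derivative preprocessing is sensitive to
#' artificial flat regions.
#'
#' @param raw rows x cols x bands array of raw counts.
#' @param white,dark reference arrays, same shape as `raw` (a matrix or a
#'   scalar is broadcast across bands/pixels).
#' @param wavelengths band centers in nm.
#' @param clip optional length-2 numeric range to clip to (default none).
#' @return a [hyperspectral_cube()] of relative reflectance.
#' @export
calibrate <- function(raw, white, dark, wavelengths, clip = NULL) {
  broadcast <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L) return(x)
    array(x, dim = dim(raw))
  }
  white <- broadcast(white); dark <- broadcast(dark)
  if (!all(dim(white) == dim(raw)) || !all(dim(dark) == dim(raw)))
    gs_stop("reference shapes must match the raw cube", class = "calibration_error")
  denom <- white - dark
  bad <- which(denom <= 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(raw))
    gs_stop(sprintf("white - dark <= 0 first at pixel (%d, %d), band %d",
                    idx[1], idx[2], idx[3]), class = "calibration_error")
  }
  values <- (raw - dark) / denom
  if (!is.null(clip)) values <- pmin(pmax(values, clip[1]), clip[2])
  hyperspectral_cube(values, wavelengths)
}

nearest_band <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

#' Segment grain pixels from background
#'
#' Thresholds the band nearest `roi_wavelength` (default 750 nm, the band of
#' highest grain intensity), removes connected components below `min_area`,
#' and labels the survivors. If `sample_map` is supplied (a data.frame with
#' `sample_id`, `row`, `col` grain centroids), each component is assigned the
#' sample of the nearest centroid; otherwise components keep their own labels.
#'
#' @param cube a [hyperspectral_cube()].
#' @param roi_wavelength nm of the thresholding band.
#' @param min_area minimum connected-component area in pixels.
#' @param threshold fixed reflectance threshold; `NULL` (default) uses Otsu's
#'   method on the ROI band.
#' @param sample_map optional grain-to-sample map (see [render_scene()]).
#' @return list of class `grain_mask`: `mask` (logical matrix), `labels`
#'   (integer matrix, 0 outside the mask), `sample_ids` (label -> sample),
#'   `threshold` used.
#' @export
segment_grains <- function(cube, roi_wavelength = 750, min_area = 50,
                           threshold = NULL, sample_map = NULL) {
  wl <- cube$wavelengths
  if (roi_wavelength < min(wl) || roi_wavelength > max(wl))
    gs_stop("roi_wavelength outside the cube's range", class = "segmentation_error")
  band <- cube$values[, , nearest_band(wl, roi_wavelength)]
  if (is.null(threshold)) {
    rng <- range(band)
    if (rng[2] <= rng[1])
      gs_stop("ROI band is constant; nothing to segment", class = "segmentation_error")
    scaled <- (band - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
  }
  mask <- band > threshold
  if (!any(mask)) gs_stop("empty mask after thresholding", class = "segmentation_error")
  comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(comp)), nrow(band), ncol(band))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  if (!length(keep))
    gs_stop("no component reaches min_area = ", min_area, class = "segmentation_error")
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  mask <- lab > 0L
  sample_ids <- as.character(seq_along(keep))
  if (!is.null(sample_map)) {
    for (k in seq_along(keep)) {
      px <- which(lab == k, arr.ind = TRUE)
      ctr <- colMeans(px)
      d2 <- (sample_map$row - ctr[1])^2 + (sample_map$col - ctr[2])^2
      sample_ids[k] <- sample_map$sample_id[which.min(d2)]
    }
  }
  structure(list(mask = mask, labels = lab, sample_ids = sample_ids,
                 threshold = threshold),
            class = "grain_mask")
}

#' Extract per-sample mean spectra
#'
#' Averages the calibrated spectrum over each sample's masked pixels;
#' components sharing a sample id (multiple grains per sample) are pooled.
#'
#' @param cube a [hyperspectral_cube()].
#' @param mask a `grain_mask` from [segment_grains()].
#' @return a [spectra_table()], one row per distinct sample id.
#' @export
extract_spectra <- function(cube, mask) {
  if (!any(mask$mask)) gs_stop("mask is empty", class = "extraction_error")
  d <- dim(cube$values)
  mat <- matrix(cube$values, d[1] * d[2], d[3])
  labs <- as.vector(mask$labels)
  uniq <- unique(mask$sample_ids)
  out <- matrix(0, length(uniq), d[3])
  for (i in seq_along(uniq)) {
    comp <- which(mask$sample_ids == uniq[i])
    px <- which(labs %in% comp)
    if (!length(px))
      gs_stop("sample ", uniq[i], " has zero masked pixels", class = "extraction_error")
    out[i, ] <- colMeans(mat[px, , drop = FALSE])
  }
  spectra_table(out, cube$wavelengths, uniq)
}
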