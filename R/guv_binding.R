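# GUV equilibrium binding: semi-automatic rim quantification. The user marks
# a GUV with a line from its centre to its edge; the pipeline crops a square
# around it, normalizes and blurs, segments every slice with a
# marker-controlled watershed seeded at the line origin (background seeded at
# the crop corners), picks the slice with the largest segmented area as the
# middle section, and reports the median raw intensity along a 3-pixel-wide
# contour of that section.

#' GUV selection line
#'
#' A user-supplied line from the centre of a GUV to its edge, on a chosen
#' frame, replacing the interactive drawing step with reproducible
#' coordinates.
#'
#' @param y0,x0 Line start (the GUV centre), 1-based pixel coordinates.
#' @param y1,x1 Line end (the GUV edge).
#' @return An object of class `guv_selection`.
#' @export
guv_selection <- function(y0, x0, y1, x1) {
  len <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  if (len < 3) stop("selection line must be at least 3 px long")
  structure(list(y0 = y0, x0 = x0, y1 = y1, x1 = x1, length_px = len),
            class = "guv_selection")
}

#' Crop a selected GUV from a stack
#'
#' Square crop centred on the line's start point with half-width
#' `ceiling(1.5 * line length)`, clipped to the image bounds; all z-slices
#' and frames are retained. The seed-point position within the crop is
#' recorded for segmentation.
#'
#' @param stack An [image_stack()].
#' @param sel A [guv_selection()] (or numeric c(y0, x0, y1, x1)).
#' @return Cropped [image_stack()] with attributes `seed_yx` and `origin_yx`.
#' @export
crop_guv <- function(stack, sel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.numeric(sel)) sel <- guv_selection(sel[1], sel[2], sel[3], sel[4])
  d <- dim(stack$data)
  ny <- d[4]; nx <- d[5]
  if (sel$y0 < 1 || sel$y0 > ny || sel$x0 < 1 || sel$x0 > nx ||
      sel$y1 < 1 || sel$y1 > ny || sel$x1 < 1 || sel$x1 > nx) {
    stop("selection line endpoints must lie inside the image")
  }
  hw <- ceiling(1.5 * sel$length_px)
  y0 <- round(sel$y0); x0 <- round(sel$x0)
  rows <- max(1L, y0 - hw):min(ny, y0 + hw - 1L)
  cols <- max(1L, x0 - hw):min(nx, x0 + hw - 1L)
  if (length(rows) < 8L || length(cols) < 8L) stop("crop smaller than 8x8 px")
  data <- stack$data[, , , rows, cols, drop = FALSE]
  out <- image_stack(data, stack$calibration, stack$channel_roles)
  attr(out, "seed_yx") <- c(y0 - rows[1] + 1L, x0 - cols[1] + 1L)
  attr(out, "origin_yx") <- c(rows[1], cols[1])
  out
}

#' Preprocess a GUV crop for segmentation
#'
#' Percentile intensity normalization to `[0, 1]` followed by a 3D Gaussian
#' blur (sigma 3 px laterally, scaled by the axial anisotropy in z). The
#' result is used for segmentation only; rim medians are always measured on
#' the raw crop.
#'
#' @param crop Cropped stack from [crop_guv()].
#' @param sigma_px Blur sigma in pixels (default 3).
#' @param percentiles Normalization percentiles.
#' @param channel Channel to process.
#' @return Stack of the processed channel (single channel), with the crop's
#'   `seed_yx` attribute carried over.
#' @export
preprocess_guv <- function(crop, sigma_px = 3, percentiles = c(0.001, 0.999),
                           channel = 1) {
  stopifnot(inherits(crop, "image_stack"))
  d <- dim(crop$data)
  out <- array(0, c(d[1], 1, d[3], d[4], d[5]))
  for (t in seq_len(d[1])) {
    v <- frame_volume(crop, t, channel)
    v <- normalize_percentile(v, percentiles)
    v <- gaussian_blur3d(v, sigma_px, crop$calibration)
    out[t, 1, , , ] <- aperm(v, c(3, 1, 2))
  }
  res <- image_stack(out, crop$calibration, "probe")
  attr(res, "seed_yx") <- attr(crop, "seed_yx")
  res
}

#' Segment a GUV on every slice and find the middle section
#'
#' Marker-controlled watershed per slice: the object marker is a small disc
#' at the selection-line origin, the background marker sits at the crop
#' corners, and `EBImage::propagate` partitions the slice along the
#' intensity manifold so the basin boundary locks onto the bright rim. The
#' slice with the largest segmented area is the middle section; ties break
#' to the lowest slice index. A basin that floods essentially the whole
#' slice is treated as a failed slice (area 0).
#'
#' @param crop_pp Preprocessed crop from [preprocess_guv()].
#' @param t Frame index.
#' @param seed_yx Seed pixel (defaults to the crop's recorded seed).
#' @return Object of class `guv_segmentation`: list with `mask` (Y,X,Z
#'   logical), `areas_px` per slice and `middle_slice`.
#' @export
segment_guv <- function(crop_pp, t = 1, seed_yx = attr(crop_pp, "seed_yx")) {
  stopifnot(inherits(crop_pp, "image_stack"))
  if (is.null(seed_yx)) stop("no seed point available; pass seed_yx")
  v <- frame_volume(crop_pp, t, 1)
  d <- dim(v)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  seeds <- matrix(0L, ny, nx)
  sy <- seq(max(1, seed_yx[1] - 2), min(ny, seed_yx[1] + 2))
  sx <- seq(max(1, seed_yx[2] - 2), min(nx, seed_yx[2] + 2))
  seeds[sy, sx] <- 1L
  cs <- 3L # corner background markers
  for (ci in list(c(1L, 1L), c(1L, nx - cs + 1L), c(ny - cs + 1L, 1L),
                  c(ny - cs + 1L, nx - cs + 1L))) {
    seeds[ci[1]:(ci[1] + cs - 1L), ci[2]:(ci[2] + cs - 1L)] <- 2L
  }
  th <- otsu_threshold(v) # rim-evidence threshold for basin validation
  mask <- array(FALSE, d)
  areas <- integer(nz)
  for (z in seq_len(nz)) {
    sl <- v[, , z]
    seg <- EBImage::propagate(EBImage::Image(sl), EBImage::Image(seeds))
    m <- as.matrix(EBImage::imageData(seg)) == 1
    if (sum(m) > 0.8 * ny * nx) m[] <- FALSE # flooded: no rim found
    near <- m | (as.matrix(EBImage::dilate(matrix(as.numeric(m), ny, nx),
                                           EBImage::makeBrush(5, "disc"))) > 0.5)
    if (sum(sl[near] > th) < 9L) m[] <- FALSE # basin without rim signal
    if (any(m)) {
      m <- as.matrix(EBImage::fillHull(matrix(as.numeric(m), ny, nx))) > 0.5
    }
    mask[, , z] <- m
    areas[z] <- sum(m)
  }
  if (all(areas == 0L)) stop("GUV not found: no slice produced a segmented area")
  structure(list(mask = mask, areas_px = areas,
                 middle_slice = which.max(areas)),
            class = "guv_segmentation")
}

#' Measure the rim-contour median intensity of a GUV middle section
#'
#' Draws a `contour_width_px`-wide contour along the segmented GUV boundary
#' on the middle slice and reports the median of the raw intensities along
#' it. The watershed boundary after blurring can sit on either flank of the
#' membrane's intensity crest, so the contour band is allowed to shift by up
#' to `snap_px` pixels across the boundary and settles on the brightest
#' position (the membrane). If erosion empties the mask (object thinner
#' than twice the width), the full mask is used and a warning is issued.
#'
#' @param seg A [segment_guv()] result.
#' @param crop The raw crop ([crop_guv()] output) supplying intensities.
#' @param contour_width_px Contour width in pixels (default 3).
#' @param snap_px Maximum contour shift across the boundary (default 3).
#' @param t Frame index.
#' @param channel Intensity channel.
#' @return Object of class `rim_measurement`: list with `middle_slice`,
#'   `rim_median`, `contour_px` (pixel count) and `normalized_rim` (NA until
#'   [normalize_rim()]).
#' @export
measure_rim <- function(seg, crop, contour_width_px = 3, snap_px = 3, t = 1,
                        channel = 1) {
  stopifnot(inherits(seg, "guv_segmentation"), inherits(crop, "image_stack"))
  z <- seg$middle_slice
  m <- seg$mask[, , z]
  if (!any(m)) stop("middle slice has an empty mask")
  raw <- frame_volume(crop, t, channel)[, , z]
  # candidate bands at signed offsets from the segmentation boundary
  offset_mask <- function(j) {
    mm <- matrix(as.numeric(m), nrow(m), ncol(m))
    if (j == 0) return(m)
    brush <- EBImage::makeBrush(2L * abs(j) + 1L, "disc")
    out <- if (j > 0) EBImage::erode(mm, brush) else EBImage::dilate(mm, brush)
    as.matrix(out) > 0.5
  }
  best <- NULL
  for (j in seq(-snap_px, snap_px)) {
    band <- offset_mask(j) & !offset_mask(j + contour_width_px)
    if (!any(band)) next
    med <- stats::median(raw[band])
    if (is.null(best) || med > best$med) best <- list(band = band, med = med)
  }
  if (is.null(best)) {
    warning("erosion emptied the mask; using the full mask as contour")
    best <- list(band = m, med = stats::median(raw[m]))
  }
  structure(list(middle_slice = z,
                 rim_median = best$med,
                 contour_px = sum(best$band),
                 normalized_rim = NA_real_),
            class = "rim_measurement")
}

# width-px inner contour band of a binary mask (mask minus its erosion)
contour_band <- function(mask, width_px) {
  er <- as.matrix(EBImage::erode(
    matrix(as.numeric(mask), nrow(mask), ncol(mask)),
    EBImage::makeBrush(2L * as.integer(width_px) + 1L, "disc")
  )) > 0.5
  mask & !er
}

#' Normalize a rim measurement by a purification-batch reference
#'
#' Divides the raw rim median by the fluorescence signal of a 1 uM protein
#' solution from the same purification batch, making rim binding comparable
#' across batches.
#'
#' @param m A [measure_rim()] result.
#' @param reference_signal Reference fluorescence (> 0).
#' @return The measurement with `normalized_rim` filled in.
#' @export
normalize_rim <- function(m, reference_signal) {
  stopifnot(inherits(m, "rim_measurement"))
  if (!is.finite(reference_signal) || reference_signal <= 0) {
    stop("reference_signal must be > 0")
  }
  m$normalized_rim <- m$rim_median / reference_signal
  m
}

#' @export
print.rim_measurement <- function(x, ...) {
  cat(sprintf("rim_measurement: middle slice %d, rim median %.4g (%d contour px)",
              x$middle_slice, x$rim_median, x$contour_px))
  if (!is.na(x$normalized_rim)) cat(sprintf(", normalized %.4g", x$normalized_rim))
  cat("\n")
  invisible(x)
}

#' End-to-end GUV rim quantification
#'
#' Convenience wrapper chaining [crop_guv()], [preprocess_guv()],
#' [segment_guv()], [measure_rim()] and (optionally) [normalize_rim()].
#'
#' @param stack An [image_stack()].
#' @param sel A [guv_selection()] or c(y0, x0, y1, x1).
#' @param reference_signal Optional 1 uM batch reference.
#' @param config Configuration list (see [default_config()]).
#' @param t Frame index.
#' @return A `rim_measurement`.
#' @export
quantify_guv <- function(stack, sel, reference_signal = NULL,
                         config = default_config(), t = 1) {
  crop <- crop_guv(stack, sel)
  pp <- preprocess_guv(crop, sigma_px = config$guv$blur_sigma_px,
                       percentiles = config$guv$norm_percentiles)
  seg <- segment_guv(pp, t = t)
  m <- measure_rim(seg, crop, contour_width_px = config$guv$contour_width_px, t = t)
  if (!is.null(reference_signal)) m <- normalize_rim(m, reference_signal)
  m
}
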