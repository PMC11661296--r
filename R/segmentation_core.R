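# Shared segmentation primitives. EBImage supplies the 2D building blocks
# (gblur, otsu, erode, opening, bwlabel, propagate); the functions here add
# the 3D glue: separable z-blur, across-slice component merging and a
# marker-controlled watershed that carries labels between adjacent slices.

#' Otsu threshold of an arbitrary-range intensity array
#' @param x Numeric array or matrix.
#' @return Threshold on the intensity scale of `x`.
#' @keywords internal
otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(r[1])
  v <- (as.numeric(x) - r[1]) / diff(r)
  th <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)))
  th * diff(r) + r[1]
}

#' 3D Gaussian blur with axial sigma scaled by voxel anisotropy
#'
#' Applies an isotropic 2D Gaussian per slice, then a 1D Gaussian along z
#' with `sigma_z = sigma * dx / dz` so the blur is (approximately) isotropic
#' in physical space.
#'
#' @param vol Y,X,Z array.
#' @param sigma Lateral standard deviation in pixels.
#' @param calibration A [pixel_calibration()] supplying the anisotropy.
#' @return Blurred array, same dimensions.
#' @export
gaussian_blur3d <- function(vol, sigma, calibration = pixel_calibration()) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  nonneg <- min(vol) >= 0
  out <- as.array(EBImage::gblur(EBImage::Image(vol), sigma = sigma))
  dim(out) <- d
  if (nonneg) out[out < 0] <- 0 # FFT ringing can undershoot slightly
  sigma_z <- sigma * calibration$dx / calibration$dz
  if (d[3] > 1 && sigma_z > 0.05) {
    half <- max(1L, ceiling(3 * sigma_z))
    k <- stats::dnorm(-half:half, sd = sigma_z)
    k <- k / sum(k)
    acc <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      zsrc <- pmin(pmax(seq_len(d[3]) + off, 1L), d[3]) # replicate boundary
      acc <- acc + k[j] * out[, , zsrc, drop = FALSE]
    }
    out <- acc
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2D image as the grayscale morphological
#' opening with a disc structuring element of the given radius (the virtual
#' ball rolled under the intensity surface) and subtracts it, clipping at
#' zero. A constant image maps to (exactly) zero.
#'
#' @param img Y,X matrix.
#' @param radius Ball radius in pixels (default 50).
#' @return Background-subtracted matrix, non-negative.
#' @export
rolling_ball <- function(img, radius = 50) {
  lo <- min(img); hi <- max(img)
  if (hi - lo < .Machine$double.eps) return(img * 0)
  v <- (img - lo) / (hi - lo) # EBImage grayscale morphology works on [0,1]
  bg <- EBImage::opening(v, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc"))
  pmax(v - as.matrix(bg), 0) * (hi - lo)
}

#' Percentile intensity normalization
#'
#' Rescales intensities to `[0, 1]` between the given lower/upper quantiles
#' (robust to hot pixels), clipping outside. A constant input degenerates to
#' all zeros, which is reported via a warning rather than an error.
#'
#' @param x Numeric array.
#' @param percentiles Lower and upper quantiles (default 0.1% and 99.9%).
#' @return Array rescaled to `[0, 1]`.
#' @export
normalize_percentile <- function(x, percentiles = c(0.001, 0.999)) {
  q <- stats::quantile(x, percentiles, names = FALSE)
  if (diff(q) < .Machine$double.eps) {
    warning("constant image: percentile normalization degenerates to zeros")
    return(x * 0)
  }
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

#' 3D connected-component labeling
#'
#' Per-slice `EBImage::bwlabel` followed by union-find merging of labels
#' that overlap between adjacent z-slices.
#'
#' @param mask Logical (or 0/1) Y,X,Z array.
#' @return Integer label array, labels 1..n, 0 background.
#' @export
label3d <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  mask <- array(as.numeric(mask != 0), d)
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    l <- as.matrix(EBImage::bwlabel(mask[, , z]))
    storage.mode(l) <- "integer"
    l[l > 0L] <- l[l > 0L] + offset
    lab[, , z] <- l
    offset <- max(offset, max(l))
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (d[3] > 1L) {
    for (z in seq_len(d[3] - 1L)) {
      a <- lab[, , z]; b <- lab[, , z + 1L]
      sel <- a > 0L & b > 0L
      if (!any(sel)) next
      pairs <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Marker-controlled watershed on a volume
#'
#' Assigns every voxel of `mask` to a marker by per-slice intensity-based
#' propagation (`EBImage::propagate`), carrying labels from the already
#' assigned neighbouring slice into slices that lack their own markers, so
#' that a marker claims a full 3D region.
#'
#' @param vol Y,X,Z intensity array steering the propagation.
#' @param markers Integer Y,X,Z marker label array.
#' @param mask Logical Y,X,Z foreground mask constraining the assignment.
#' @return Integer label array.
#' @export
watershed3d <- function(vol, markers, mask) {
  d <- dim(vol)
  if (length(d) == 2L) {
    d <- c(d, 1L)
    dim(vol) <- d; dim(markers) <- d; dim(mask) <- d
  }
  out <- array(0L, d)
  counts <- vapply(seq_len(d[3]), function(z) sum(markers[, , z] > 0L), integer(1))
  if (all(counts == 0L)) return(out)
  z0 <- which.max(counts)
  order_z <- c(z0, seq(z0 + 1L, length.out = max(0L, d[3] - z0)),
               seq(z0 - 1L, length.out = max(0L, z0 - 1L), by = -1L))
  for (z in order_z) {
    m2 <- mask[, , z]
    if (!any(m2)) next
    seeds <- markers[, , z]
    zn <- if (z > z0) z - 1L else if (z < z0) z + 1L else NA_integer_
    if (!is.na(zn)) {
      carry <- out[, , zn]
      take <- seeds == 0L & carry > 0L & m2
      seeds[take] <- carry[take]
    }
    if (!any(seeds > 0L)) next
    seg <- EBImage::propagate(
      EBImage::Image(vol[, , z]),
      EBImage::Image(seeds),
      mask = EBImage::Image(matrix(as.numeric(m2), d[1], d[2]))
    )
    seg <- as.matrix(EBImage::imageData(seg))
    storage.mode(seg) <- "integer"
    out[, , z] <- seg
  }
  out
}

# Per-slice binary erosion with a disc brush of the given radius.
erode_slices <- function(mask, radius_px) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  mask <- array(as.numeric(mask != 0), d)
  if (radius_px < 1) return(mask > 0)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, "disc")
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    out[, , z] <- as.matrix(EBImage::erode(mask[, , z], brush)) > 0.5
  }
  out
}

# Masked-object thresholding + marker-controlled watershed chain shared by
# nucleus and luminal-ER segmentation. Global Otsu foreground; per-component
# local Otsu refinement (kept only when it retains >= refine_keep_fraction of
# the component, see vignette); markers by geometric erosion with a
# per-component fallback; watershed constrained to the refined mask.
segment_masked_watershed <- function(vol, min_volume, marker_erode_px,
                                     refine_keep_fraction = 0.6) {
  d <- dim(vol)
  if (length(d) == 2L) {
    dim(vol) <- c(d, 1L)
    d <- dim(vol)
  }
  th <- otsu_threshold(vol)
  mask <- vol > th
  if (!any(mask)) return(array(0L, d))
  comps <- label3d(mask)
  ncomp <- max(comps)
  refined <- mask
  for (i in seq_len(ncomp)) {
    sel <- comps == i
    nsel <- sum(sel)
    if (nsel < 4L) next
    # local re-threshold over the component's padded bounding box, so the
    # local Otsu separates object from local background rather than
    # splitting the object's own intensity distribution
    idx <- which(sel)
    yy <- (idx - 1L) %% d[1] + 1L
    xx <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
    zz <- (idx - 1L) %/% (d[1] * d[2]) + 1L
    pad <- 5L
    box <- vol[max(1L, min(yy) - pad):min(d[1], max(yy) + pad),
               max(1L, min(xx) - pad):min(d[2], max(xx) + pad),
               min(zz):max(zz), drop = FALSE]
    lth <- otsu_threshold(box)
    keep <- sel & vol > lth
    if (sum(keep) >= refine_keep_fraction * nsel) {
      refined[sel] <- keep[sel]
    }
  }
  markers <- label3d(erode_slices(refined, marker_erode_px))
  # every global component must own at least one marker
  for (i in seq_len(ncomp)) {
    sel <- comps == i
    if (!any(markers[sel] > 0L)) {
      nm <- max(markers) + 1L
      core <- erode_slices(sel & refined, max(1L, marker_erode_px %/% 2L))
      if (!any(core)) core <- sel & refined
      if (!any(core)) core <- sel
      markers[core] <- nm
    }
  }
  labels <- watershed3d(vol, markers, refined)
  prune_labels(labels, min_volume)
}

# Remove objects below min_volume voxels and relabel consecutively.
prune_labels <- function(labels, min_volume) {
  if (max(labels) == 0L) return(labels)
  tab <- tabulate(labels[labels > 0L])
  keep <- which(tab >= min_volume)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- relab[labels[pos]]
  labels
}
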