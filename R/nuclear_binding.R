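# Nuclear-membrane binding: fully automatic 3D nucleus segmentation,
# frame-to-frame tracking, and per-nucleus membrane/nucleoplasm intensity
# ratio time series, with the ratiometric lamin-normalized variant.

#' Preprocess a time lapse for nucleus segmentation
#'
#' Per frame: percentile intensity normalization, 3D Gaussian blur (sigma
#' 1 px, axially scaled) and rolling-ball background subtraction (2D per
#' slice) with non-negative clipping. The processed stack is used for
#' segmentation only; binding ratios are measured on raw intensities.
#'
#' @param stack An [image_stack()] with a probe channel.
#' @param channel Channel to process (default the `"probe"` role).
#' @param blur_sigma_px Gaussian sigma in pixels.
#' @param rolling_ball_radius_px Ball radius in pixels.
#' @param percentiles Normalization percentiles.
#' @return Single-channel processed [image_stack()].
#' @export
preprocess_nuclei <- function(stack, channel = "probe", blur_sigma_px = 1,
                              rolling_ball_radius_px = 50,
                              percentiles = c(0.001, 0.999)) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  out <- array(0, c(d[1], 1, d[3], d[4], d[5]))
  for (t in seq_len(d[1])) {
    v <- frame_volume(stack, t, channel)
    v <- normalize_percentile(v, percentiles)
    v <- gaussian_blur3d(v, blur_sigma_px, stack$calibration)
    for (z in seq_len(d[3])) {
      v[, , z] <- rolling_ball(v[, , z], rolling_ball_radius_px)
    }
    out[t, 1, , , ] <- aperm(v, c(3, 1, 2))
  }
  image_stack(out, stack$calibration, "probe")
}

#' Segment nuclei in one 3D frame
#'
#' Masked-object thresholding followed by a marker-controlled watershed:
#' a global Otsu threshold yields the foreground mask; each connected
#' component is re-thresholded locally (kept only when the refinement
#' retains most of the component); watershed markers come from a geometric
#' erosion of the mask (with a per-component fallback), which separates
#' touching nuclei; and per-slice intensity propagation assigns every voxel
#' to a marker. Objects below `min_volume` voxels are removed.
#'
#' @param frame Y,X,Z intensity array (a preprocessed frame volume), or an
#'   [image_stack()] whose frame `t` is taken.
#' @param min_volume Minimum object volume in voxels (default 200).
#' @param marker_erode_px Marker erosion radius in pixels (default 7).
#' @param refine_keep_fraction Guard for the local re-threshold (see
#'   Details in the vignette).
#' @param t Frame index when `frame` is a stack.
#' @return Integer Y,X,Z label array (0 background); an empty frame yields
#'   all zeros.
#' @export
segment_nuclei <- function(frame, min_volume = 200, marker_erode_px = 7,
                           refine_keep_fraction = 0.6, t = 1) {
  if (inherits(frame, "image_stack")) frame <- frame_volume(frame, t, 1)
  if (max(frame) - min(frame) < .Machine$double.eps) {
    d <- dim(frame)
    if (length(d) == 2L) d <- c(d, 1L)
    return(array(0L, d))
  }
  segment_masked_watershed(frame, min_volume, marker_erode_px,
                           refine_keep_fraction)
}

#' Track segmented nuclei over time
#'
#' Greedy nearest-neighbour centroid linking between consecutive frames in
#' physical (micrometre) coordinates. Links longer than `max_displacement_um`
#' are forbidden; unlinked objects start new tracks; tracks shorter than
#' `min_length` frames are dropped.
#'
#' @param labels_list List of per-frame Y,X,Z label arrays.
#' @param calibration A [pixel_calibration()].
#' @param max_displacement_um Maximum frame-to-frame displacement (default
#'   50 um, the bound the acquisition design guarantees).
#' @param min_length Minimum track length in frames (default 3).
#' @return A `nucleus_tracks` data.frame with columns `track`, `frame`,
#'   `label`, `y_um`, `x_um`, `z_um`.
#' @export
track_nuclei <- function(labels_list, calibration = pixel_calibration(),
                         max_displacement_um = 50, min_length = 3) {
  if (!length(labels_list)) {
    return(structure(data.frame(track = integer(0), frame = integer(0),
                                label = integer(0), y_um = numeric(0),
                                x_um = numeric(0), z_um = numeric(0)),
                     class = c("nucleus_tracks", "data.frame")))
  }
  cents <- lapply(labels_list, label_centroids_um, calibration = calibration)
  rows <- list()
  next_track <- 1L
  active <- data.frame(track = integer(0), y = numeric(0), x = numeric(0),
                       z = numeric(0))
  for (t in seq_along(cents)) {
    cc <- cents[[t]]
    assigned <- rep(NA_integer_, nrow(cc))
    if (nrow(active) && nrow(cc)) {
      dmat <- outer(seq_len(nrow(active)), seq_len(nrow(cc)),
                    Vectorize(function(i, j) {
                      sqrt((active$y[i] - cc$y_um[j])^2 +
                           (active$x[i] - cc$x_um[j])^2 +
                           (active$z[i] - cc$z_um[j])^2)
                    }))
      ord <- order(dmat)
      used_a <- logical(nrow(active)); used_c <- logical(nrow(cc))
      for (k in ord) {
        if (dmat[k] > max_displacement_um) break
        i <- (k - 1L) %% nrow(active) + 1L
        j <- (k - 1L) %/% nrow(active) + 1L
        if (used_a[i] || used_c[j]) next
        used_a[i] <- TRUE; used_c[j] <- TRUE
        assigned[j] <- active$track[i]
      }
    }
    for (j in seq_len(nrow(cc))) {
      if (is.na(assigned[j])) {
        assigned[j] <- next_track
        next_track <- next_track + 1L
      }
    }
    if (nrow(cc)) {
      rows[[t]] <- data.frame(track = assigned, frame = t, label = cc$label,
                              y_um = cc$y_um, x_um = cc$x_um, z_um = cc$z_um)
      active <- data.frame(track = assigned, y = cc$y_um, x = cc$x_um,
                           z = cc$z_um)
    } else {
      active <- active[0, ]
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track = integer(0), frame = integer(0),
                                      label = integer(0), y_um = numeric(0),
                                      x_um = numeric(0), z_um = numeric(0))
  len <- table(out$track)
  keep <- as.integer(names(len)[len >= min_length])
  out <- out[out$track %in% keep, , drop = FALSE]
  out$track <- match(out$track, sort(unique(out$track)))
  rownames(out) <- NULL
  structure(out, class = c("nucleus_tracks", "data.frame"))
}

label_centroids_um <- function(labels, calibration) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!length(ids)) {
    return(data.frame(label = integer(0), y_um = numeric(0), x_um = numeric(0),
                      z_um = numeric(0)))
  }
  d <- dim(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  yy <- (idx - 1L) %% d[1]
  xx <- ((idx - 1L) %/% d[1]) %% d[2]
  zz <- (idx - 1L) %/% (d[1] * d[2])
  data.frame(
    label = ids,
    y_um = tapply(yy, lab, mean)[as.character(ids)] * calibration$dy,
    x_um = tapply(xx, lab, mean)[as.character(ids)] * calibration$dx,
    z_um = tapply(zz, lab, mean)[as.character(ids)] * calibration$dz,
    row.names = NULL
  )
}

#' Measure nuclear-membrane binding ratios along tracks
#'
#' For every tracked nucleus and frame: the z-slice with the largest
#' segmented area is the representative middle section (ties break to the
#' lowest index); a `contour_width_px`-wide "membrane contour" is drawn just
#' inside the segmented boundary, and a same-width "background contour" ring
#' is placed in the nucleoplasm at half the object's equivalent radius. The
#' binding ratio is the median raw probe intensity along the membrane
#' contour divided by the median along the background contour, and
#' `ratio_norm` divides each track's ratio by its value at the first frame
#' (exactly 1 there). With a lamin channel, the ratiometric readout divides
#' the probe membrane-contour median by the lamin membrane-contour median.
#' Frames whose background ring is empty are flagged as missing (NA), never
#' fabricated.
#'
#' @param tracks A [track_nuclei()] result.
#' @param stack The raw [image_stack()].
#' @param labels_list Per-frame label arrays used for the tracking.
#' @param probe_channel Channel index or role of the probe.
#' @param lamin_channel Optional channel index or role of the nuclear-
#'   envelope reference.
#' @param contour_width_px Contour width (default 3).
#' @param ring_fraction Background-ring radius as a fraction of the
#'   equivalent radius (default 0.5).
#' @return A `binding_time_series` data.frame: one row per track per frame
#'   with `membrane_median`, `background_median`, `ratio`, `ratio_norm` and
#'   (optionally) `ratiometric`.
#' @export
measure_nm_binding <- function(tracks, stack, labels_list,
                               probe_channel = "probe", lamin_channel = NULL,
                               contour_width_px = 3, ring_fraction = 0.5) {
  stopifnot(inherits(tracks, "nucleus_tracks"), inherits(stack, "image_stack"))
  dt <- stack$calibration$dt
  res <- list()
  for (tr in sort(unique(tracks$track))) {
    sub <- tracks[tracks$track == tr, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      fr <- sub$frame[i]; lb <- sub$label[i]
      lab3 <- labels_list[[fr]]
      mask3 <- lab3 == lb
      areas <- apply(mask3, 3, sum)
      z <- which.max(areas) # ties -> lowest index
      m2 <- mask3[, , z]
      membrane <- contour_band(m2, contour_width_px)
      if (!any(membrane)) membrane <- m2
      ring <- interior_ring(m2, ring_fraction, contour_width_px)
      raw <- frame_volume(stack, fr, probe_channel)[, , z]
      mem_med <- stats::median(raw[membrane])
      bg_med <- if (any(ring)) stats::median(raw[ring]) else NA_real_
      ratiometric <- NA_real_
      if (!is.null(lamin_channel)) {
        lam <- frame_volume(stack, fr, lamin_channel)[, , z]
        lam_med <- stats::median(lam[membrane])
        ratiometric <- if (lam_med > 0) mem_med / lam_med else NA_real_
      }
      res[[length(res) + 1L]] <- data.frame(
        track = tr, frame = fr, time = (fr - 1) * dt, middle_slice = z,
        membrane_median = mem_med, background_median = bg_med,
        ratio = if (!is.na(bg_med) && bg_med > 0) mem_med / bg_med else NA_real_,
        ratiometric = ratiometric
      )
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no track rows to measure")
  out$ratio_norm <- NA_real_
  for (tr in unique(out$track)) {
    sel <- out$track == tr
    r0 <- out$ratio[sel][1]
    if (!is.na(r0) && r0 > 0) out$ratio_norm[sel] <- out$ratio[sel] / r0
  }
  if (is.null(lamin_channel)) out$ratiometric <- NULL
  rownames(out) <- NULL
  structure(out, class = c("binding_time_series", "data.frame"))
}

# width_px-wide ring at ring_fraction of the equivalent radius, fully in the
# nucleoplasm: placed within the hole-filled mask, since a dim nucleoplasm
# can drop out of the intensity mask while still being enclosed by the rim
interior_ring <- function(mask, ring_fraction, width_px) {
  if (!any(mask)) return(mask & FALSE)
  mask <- as.matrix(EBImage::fillHull(
    matrix(as.numeric(mask), nrow(mask), ncol(mask))
  )) > 0.5
  a <- sum(mask)
  r_eq <- sqrt(a / pi)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  yy <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  xx <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  ring <- abs(dist - ring_fraction * r_eq) <= width_px / 2
  interior <- !contour_band(mask, width_px) & mask
  ring & interior
}

#' Intensity profile along a line
#'
#' Samples an image by bilinear interpolation at unit-pixel spacing along a
#' segment (endpoints inclusive, so a 20 px line yields 21 samples), with
#' optional averaging over a perpendicular width.
#'
#' @param img Y,X matrix (a slice or projection).
#' @param from,to Endpoints c(y, x), 1-based pixel coordinates, in bounds.
#' @param width Averaging width in pixels (default 1).
#' @param calibration A [pixel_calibration()] converting distance to um.
#' @return data.frame with columns `distance_um`, `intensity`.
#' @export
line_profile <- function(img, from, to, width = 1,
                         calibration = pixel_calibration()) {
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("zero-length line")
  if (any(c(from, to) < 1) || from[1] > nrow(img) || to[1] > nrow(img) ||
      from[2] > ncol(img) || to[2] > ncol(img)) {
    stop("line endpoints must lie inside the image")
  }
  n <- floor(len) + 1L
  tt <- seq(0, len, length.out = n)
  uy <- (to[1] - from[1]) / len; ux <- (to[2] - from[2]) / len
  py <- -ux; px <- uy # perpendicular unit vector
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(1, width))
  vals <- sapply(tt, function(s) {
    mean(sapply(offs, function(o) {
      bilinear(img, from[1] + s * uy + o * py, from[2] + s * ux + o * px)
    }))
  })
  data.frame(distance_um = tt * calibration$dx, intensity = vals)
}

bilinear <- function(img, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  y0 <- min(max(y0, 1L), nrow(img) - 1L)
  x0 <- min(max(x0, 1L), ncol(img) - 1L)
  fy <- y - y0; fx <- x - x0
  img[y0, x0] * (1 - fy) * (1 - fx) + img[y0 + 1, x0] * fy * (1 - fx) +
    img[y0, x0 + 1] * (1 - fy) * fx + img[y0 + 1, x0 + 1] * fy * fx
}

#' @export
plot.binding_time_series <- function(x, ..., col = NULL) {
  tracks <- sort(unique(x$track))
  if (is.null(col)) col <- grDevices::hcl.colors(max(2L, length(tracks)), "Dark 3")
  graphics::plot(range(x$time), range(x$ratio_norm, na.rm = TRUE), type = "n",
                 xlab = "time (min)", ylab = "ratio / ratio(t0)", ...)
  for (i in seq_along(tracks)) {
    sub <- x[x$track == tracks[i], ]
    graphics::lines(sub$time, sub$ratio_norm, col = col[i])
  }
  invisible(x)
}
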