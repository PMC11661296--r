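# ER morphology: segmentation of the ER from luminal or membrane labels on a
# 2D analysis plane, per-FOV median object area and circularity
# (4*pi*A/P^2), and fold changes over time normalized to t = 0.

#' Segment ER from a luminal label
#'
#' Same masked-object-threshold + marker-controlled-watershed chain as
#' nucleus segmentation, at ER scale (small minimum volume, light marker
#' erosion).
#'
#' @param frame Y,X matrix (analysis plane) or Y,X,Z array.
#' @param min_volume Minimum object size in pixels (default 10).
#' @param marker_erode_px Marker erosion radius (default 0: the refined
#'   components themselves seed the watershed).
#' @return Integer label array matching `frame`.
#' @export
segment_er_luminal <- function(frame, min_volume = 10, marker_erode_px = 0) {
  if (inherits(frame, "image_stack")) frame <- frame_volume(frame, 1, "er_luminal")
  d2 <- length(dim(frame)) == 2L
  if (max(frame) - min(frame) < .Machine$double.eps) {
    out <- array(0L, dim(frame))
    return(if (d2) out else out)
  }
  out <- segment_masked_watershed(frame, min_volume, marker_erode_px,
                                  refine_keep_fraction = 0.6)
  if (d2) dim(out) <- dim(frame)
  out
}

#' Segment ER from a membrane label with a filament (tubularity) filter
#'
#' Multiscale Hessian ridge response: at each scale the scale-normalized
#' Hessian eigenvalues are combined into a vesselness measure that is high
#' on bright elongated (tubular) structures and suppressed on blobs; the
#' pixelwise maximum over scales is thresholded by Otsu and connected
#' components are labeled.
#'
#' @param frame Y,X matrix (analysis plane).
#' @param sigmas_px Scales of the ridge filter in pixels (default 1 and 2).
#' @param beta Blob-suppression sensitivity (default 0.5).
#' @param min_size Minimum component size in pixels (default 5).
#' @return Integer Y,X label matrix.
#' @export
segment_er_membrane <- function(frame, sigmas_px = c(1, 2), beta = 0.5,
                                min_size = 5) {
  if (inherits(frame, "image_stack")) frame <- frame_volume(frame, 1, "er_membrane")[, , 1]
  resp <- ridge_response(frame, sigmas_px, beta)
  if (max(resp) <= 0) return(matrix(0L, nrow(frame), ncol(frame)))
  th <- otsu_threshold(resp)
  mask <- resp > th
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nrow(frame), ncol(frame))))
  storage.mode(lab) <- "integer"
  lab <- prune_labels(array(lab, c(dim(lab), 1L)), min_size)
  matrix(lab, nrow(frame), ncol(frame))
}

#' Multiscale Hessian ridge (vesselness) response
#'
#' @inheritParams segment_er_membrane
#' @return Y,X matrix of the maximum vesselness over scales.
#' @export
ridge_response <- function(frame, sigmas_px = c(1, 2), beta = 0.5) {
  ny <- nrow(frame); nx <- ncol(frame)
  best <- matrix(0, ny, nx)
  for (s in sigmas_px) {
    g <- as.matrix(EBImage::gblur(EBImage::Image(frame), sigma = s))
    hxx <- shift2(g, 0, 1) - 2 * g + shift2(g, 0, -1)
    hyy <- shift2(g, 1, 0) - 2 * g + shift2(g, -1, 0)
    hxy <- (shift2(g, 1, 1) - shift2(g, 1, -1) - shift2(g, -1, 1) +
              shift2(g, -1, -1)) / 4
    # scale normalization (gamma = 2)
    hxx <- hxx * s^2; hyy <- hyy * s^2; hxy <- hxy * s^2
    tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    l1 <- (hxx + hyy) / 2 + tmp
    l2 <- (hxx + hyy) / 2 - tmp
    # order by magnitude: |la| <= |lb|
    swap <- abs(l1) > abs(l2)
    la <- ifelse(swap, l2, l1)
    lb <- ifelse(swap, l1, l2)
    rb2 <- (la / pmin(lb, -.Machine$double.eps))^2
    s2 <- hxx^2 + hyy^2 + 2 * hxy^2
    cpar <- max(sqrt(max(s2)), .Machine$double.eps) / 2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cpar^2)))
    v[lb >= 0] <- 0 # bright ridges only
    best <- pmax(best, v)
  }
  best
}

shift2 <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
  xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
  m[yi, xi, drop = FALSE]
}

#' Object area, perimeter and circularity of a labeled plane
#'
#' Per object: area is the pixel count scaled by `dx * dy`; the perimeter is
#' estimated either from a subpixel boundary polygon (marching squares at
#' the 0.5 level of the lightly smoothed mask; default) or by the
#' 4-direction Crofton line-intercept count; circularity is
#' `4 * pi * A / P^2`, clamped to `[0, 1]` with the pre-clamp value
#' retained. Medians over all objects summarize the field of view.
#'
#' @param labels Integer Y,X label matrix (or Y,X,1 array).
#' @param calibration A [pixel_calibration()].
#' @param method Perimeter estimator, `"contour"` or `"crofton"`.
#' @param time Acquisition time of the plane (min), carried into the record.
#' @param fov Field-of-view identifier.
#' @return An `er_morphology_record`: list with `fov`, `time`, `n_objects`,
#'   `median_area_um2`, `median_circularity`, `flagged` (TRUE when empty)
#'   and the per-object table `objects`.
#' @export
measure_er_morphology <- function(labels, calibration = pixel_calibration(),
                                  method = c("contour", "crofton"),
                                  time = 0, fov = 1L) {
  method <- match.arg(method)
  if (length(dim(labels)) == 3L) labels <- labels[, , 1]
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!length(ids)) {
    return(structure(list(fov = fov, time = time, n_objects = 0L,
                          median_area_um2 = NA_real_,
                          median_circularity = NA_real_,
                          flagged = TRUE, objects = NULL),
                     class = "er_morphology_record"))
  }
  px_area <- calibration$dx * calibration$dy
  objs <- lapply(ids, function(i) {
    m <- labels == i
    # crop to a padded bounding box for the perimeter estimate
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    sub <- m[max(1, rr[1] - 4):min(nrow(m), rr[2] + 4),
             max(1, cc[1] - 4):min(ncol(m), cc[2] + 4), drop = FALSE]
    a_px <- sum(sub)
    p_px <- switch(method,
                   contour = perimeter_contour(sub),
                   crofton = perimeter_crofton(sub))
    circ_raw <- circularity(a_px * px_area, p_px * calibration$dx)
    data.frame(id = i, area_px = a_px, area_um2 = a_px * px_area,
               perimeter_um = p_px * calibration$dx,
               circularity_raw = circ_raw,
               circularity = min(max(circ_raw, 0), 1))
  })
  objs <- do.call(rbind, objs)
  structure(list(fov = fov, time = time, n_objects = length(ids),
                 median_area_um2 = stats::median(objs$area_um2),
                 median_circularity = stats::median(objs$circularity),
                 flagged = FALSE, objects = objs),
            class = "er_morphology_record")
}

#' @export
print.er_morphology_record <- function(x, ...) {
  cat(sprintf("er_morphology_record: FOV %s t=%g min, %d objects", x$fov,
              x$time, x$n_objects))
  if (x$n_objects > 0) {
    cat(sprintf(", median area %.3g um^2, median circularity %.3f",
                x$median_area_um2, x$median_circularity))
  } else {
    cat(" (flagged: no objects)")
  }
  cat("\n")
  invisible(x)
}

#' Circularity of a shape
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a perfect circle, approaching 0 for
#' highly elongated objects.
#'
#' @param area Area (any consistent unit).
#' @param perimeter Perimeter (matching unit).
#' @return Circularity (unclamped).
#' @export
circularity <- function(area, perimeter) 4 * pi * area / perimeter^2

#' Subpixel boundary-polygon perimeter of a binary mask
#'
#' Marching-squares contour at the 0.5 level of the mask smoothed with a
#' 1 px Gaussian; the perimeter is the polygon length. Accurate to well
#' under 5% for discs with radius >= 10 px and nearly scale-invariant.
#'
#' @param mask Logical or 0/1 matrix.
#' @param sigma Smoothing sigma in pixels.
#' @return Perimeter in pixel units.
#' @export
perimeter_contour <- function(mask, sigma = 1) {
  p <- 6L
  mp <- matrix(0, nrow(mask) + 2L * p, ncol(mask) + 2L * p)
  mp[(p + 1):(p + nrow(mask)), (p + 1):(p + ncol(mask))] <- as.numeric(mask)
  s <- as.matrix(EBImage::gblur(EBImage::Image(mp), sigma = sigma))
  cl <- grDevices::contourLines(seq_len(nrow(s)), seq_len(ncol(s)), s, levels = 0.5)
  sum(vapply(cl, function(l) {
    sum(sqrt(diff(l$x)^2 + diff(l$y)^2))
  }, numeric(1)))
}

#' Crofton (4-direction line-intercept) perimeter of a binary mask
#'
#' Counts binary transitions along horizontal, vertical and both diagonal
#' line families and averages the Cauchy-Crofton estimates
#' `pi/2 * N_theta * spacing_theta`. Matches the standard 4-direction
#' Crofton estimator of common image-analysis libraries.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Perimeter in pixel units.
#' @export
perimeter_crofton <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  n0 <- sum(m[, -1] != m[, -ncol(m)]) + sum(m[, 1]) + sum(m[, ncol(m)])
  n90 <- sum(m[-1, ] != m[-nrow(m), ]) + sum(m[1, ]) + sum(m[nrow(m), ])
  nd1 <- sum(m[-1, -1] != m[-nrow(m), -ncol(m)])
  nd2 <- sum(m[-1, -ncol(m)] != m[-nrow(m), -1])
  mean(c(pi / 2 * n0, pi / 2 * n90, pi / 2 * nd1 / sqrt(2), pi / 2 * nd2 / sqrt(2)))
}

#' Build a per-FOV ER morphology time series
#'
#' @param labels_list List of per-frame label planes.
#' @param times Acquisition times (min), defaults to 0, dt, 2 dt, ...
#' @param calibration A [pixel_calibration()].
#' @param fov FOV identifier.
#' @param method Perimeter estimator.
#' @return data.frame, one row per frame: `fov`, `time`, `n_objects`,
#'   `median_area_um2`, `median_circularity`.
#' @export
er_timeseries <- function(labels_list, times = NULL,
                          calibration = pixel_calibration(), fov = 1L,
                          method = "contour") {
  if (is.null(times)) times <- (seq_along(labels_list) - 1) * calibration$dt
  recs <- mapply(function(lab, tm) {
    r <- measure_er_morphology(lab, calibration, method = method, time = tm,
                               fov = fov)
    data.frame(fov = r$fov, time = r$time, n_objects = r$n_objects,
               median_area_um2 = r$median_area_um2,
               median_circularity = r$median_circularity)
  }, labels_list, times, SIMPLIFY = FALSE)
  do.call(rbind, recs)
}

#' Fold change of ER morphology relative to the first time point
#'
#' Adds `fold_area` and `fold_circularity` columns, each record divided by
#' the value at the start of the series (so fold = 1 at t = 0).
#'
#' @param records An [er_timeseries()] data.frame for a single FOV, sorted
#'   by time.
#' @return The records with fold columns appended.
#' @export
er_fold_change <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  records <- records[order(records$time), , drop = FALSE]
  if (records$n_objects[1] == 0) {
    stop("cannot normalize: no objects at the first time point")
  }
  records$fold_area <- records$median_area_um2 / records$median_area_um2[1]
  records$fold_circularity <-
    records$median_circularity / records$median_circularity[1]
  records
}
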