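#' Calibrated multi-dimensional image stack
#'
#' The canonical in-memory container for fluorescence data: a 5-dimensional
#' intensity array in fixed T, C, Z, Y, X axis order (time, channel, z-plane,
#' row, column), together with its physical calibration and a channel-role
#' map. Arrays with fewer axes are padded with singleton dimensions on
#' construction, so a plain 2D image becomes a 1 x 1 x 1 x Y x X stack.
#'
#' Channel roles name what each channel images, one of `"probe"` (the
#' membrane-binding sensor), `"er_luminal"`, `"er_membrane"`, `"lamin"`
#' (nuclear-envelope reference) or `"other"`.
#'
#' @param data Numeric array with 2 to 5 dimensions; interpreted as the
#'   trailing axes of T,C,Z,Y,X (a 3D array is Z,Y,X; 4D is C,Z,Y,X).
#'   Intensities must be non-negative and finite.
#' @param calibration A [pixel_calibration()].
#' @param channel_roles Character vector of roles, one per channel, or a named
#'   vector whose names are channel indices.
#' @return An object of class `image_stack` with elements `data` (5D array),
#'   `calibration` and `channel_roles`.
#' @examples
#' s <- image_stack(matrix(0, 32, 32), pixel_calibration())
#' dim(s)
#' @export
image_stack <- function(data, calibration = pixel_calibration(),
                        channel_roles = NULL) {
  if (!is.array(data) && is.matrix(data)) data <- as.array(data)
  if (is.vector(data)) stop("data must be an array with 2 to 5 dimensions")
  nd <- length(dim(data))
  if (nd < 2 || nd > 5) stop("data must have 2 to 5 dimensions (up to T,C,Z,Y,X)")
  if (nd < 5) {
    dim(data) <- c(rep(1L, 5 - nd), dim(data))
  }
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (min(data) < 0) stop("intensities must be non-negative")
  if (!is_calibration(calibration)) stop("calibration must be a pixel_calibration object")
  nc <- dim(data)[2]
  channel_roles <- normalize_channel_roles(channel_roles, nc)
  structure(
    list(data = data, calibration = calibration, channel_roles = channel_roles),
    class = "image_stack"
  )
}

stack_roles <- c("probe", "er_luminal", "er_membrane", "lamin", "other")

normalize_channel_roles <- function(channel_roles, nc) {
  if (is.null(channel_roles)) {
    channel_roles <- rep("other", nc)
  }
  if (!is.character(channel_roles)) stop("channel_roles must be a character vector")
  if (is.null(names(channel_roles))) {
    if (length(channel_roles) != nc) {
      stop("channel_roles must have one role per channel (", nc, " channels)")
    }
    names(channel_roles) <- as.character(seq_len(nc))
  } else {
    idx <- suppressWarnings(as.integer(names(channel_roles)))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nc)) {
      stop("channel_roles names must be valid channel indices in 1..", nc)
    }
    full <- rep("other", nc)
    full[idx] <- unname(channel_roles)
    channel_roles <- full
    names(channel_roles) <- as.character(seq_len(nc))
  }
  bad <- setdiff(unique(channel_roles), stack_roles)
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  }
  channel_roles
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack [T=%d C=%d Z=%d Y=%d X=%d]\n", d[1], d[2], d[3], d[4], d[5]))
  cat("  roles:", paste(sprintf("%s=%s", names(x$channel_roles), x$channel_roles),
                        collapse = " "), "\n")
  print(x$calibration)
  invisible(x)
}

#' Extract one frame volume from a stack
#'
#' Returns a single (time, channel) volume re-ordered to Y, X, Z so that
#' per-slice image operations apply along the third dimension.
#'
#' @param stack An [image_stack()].
#' @param t Frame index (1-based).
#' @param channel Channel index, or a role name to be looked up in
#'   `channel_roles`.
#' @return Numeric array with dimensions Y, X, Z.
#' @export
frame_volume <- function(stack, t = 1, channel = 1) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- resolve_channel(stack, channel)
  d <- dim(stack$data)
  if (t < 1 || t > d[1]) stop("frame index out of range")
  v <- stack$data[t, ch, , , , drop = FALSE]
  dim(v) <- d[3:5]                      # Z,Y,X
  aperm(v, c(2, 3, 1))                  # Y,X,Z
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    hit <- which(stack$channel_roles == channel)
    if (!length(hit)) stop("no channel with role '", channel, "'")
    return(hit[1])
  }
  ch <- as.integer(channel)
  if (ch < 1 || ch > dim(stack$data)[2]) stop("channel index out of range")
  ch
}

#' Maximum-intensity projection of a frame volume
#'
#' @param stack An [image_stack()].
#' @param t Frame index.
#' @param channel Channel index or role.
#' @return Y x X matrix of per-pixel maxima over z.
#' @export
project_max <- function(stack, t = 1, channel = 1) {
  v <- frame_volume(stack, t, channel)
  apply(v, c(1, 2), max)
}
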