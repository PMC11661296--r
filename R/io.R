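#' Read a TIFF / OME-TIFF file into an image stack
#'
#' Loads a (multi-page) TIFF and normalizes its axes to the canonical
#' T,C,Z,Y,X order. Axis layout is resolved from, in order of precedence:
#' a JSON sidecar written by [write_stack()] (`<path>.meta.json`), OME-XML
#' metadata embedded in the ImageDescription tag, or `axes_hint`. OME or
#' sidecar calibration, when present, overrides the `calibration` argument.
#' A hint can only resolve a single non-spatial page axis (e.g. `"ZYX"`,
#' `"TYX"`, `"CYX"`, or `"YX"` for one page); a multi-page file whose pages
#' span more than one of T, C, Z needs embedded metadata and is otherwise
#' rejected as underdetermined rather than silently guessed.
#'
#' @param path Path to a TIFF or OME-TIFF file.
#' @param axes_hint Optional axis-order string (e.g. `"ZYX"`).
#' @param calibration Fallback [pixel_calibration()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, axes_hint = NULL, calibration = pixel_calibration()) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("only single-sample (grayscale) TIFF pages are supported")
  }
  np <- length(pages)
  meta <- read_sidecar(path)
  if (is.null(meta)) meta <- parse_ome_description(attr(pages[[1]], "description"))

  if (!is.null(meta)) {
    sizes <- meta$sizes # c(T,C,Z)
    if (prod(sizes) != np) {
      stop("metadata page count (", prod(sizes), ") disagrees with file (", np, ")")
    }
    if (!is.null(meta$calibration)) calibration <- meta$calibration
    roles <- meta$channel_roles
  } else {
    sizes <- sizes_from_hint(axes_hint, np)
    roles <- NULL
  }

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(sizes[1], sizes[2], sizes[3], ny, nx))
  # page order: T slowest, then C, then Z fastest (matches write_stack)
  p <- 1L
  for (t in seq_len(sizes[1])) for (ch in seq_len(sizes[2])) for (z in seq_len(sizes[3])) {
    arr[t, ch, z, , ] <- pages[[p]]
    p <- p + 1L
  }
  if (!is.null(meta) && !is.null(meta$scale)) arr <- arr * meta$scale
  image_stack(arr, calibration, channel_roles = roles)
}

sizes_from_hint <- function(axes_hint, np) {
  if (np == 1L) {
    if (!is.null(axes_hint) && !grepl("^[TCZ]*YX$", axes_hint)) {
      stop("unrecognized axes hint: ", axes_hint)
    }
    return(c(1L, 1L, 1L))
  }
  if (is.null(axes_hint)) {
    stop("axes underdetermined: multi-page TIFF without metadata or axes_hint")
  }
  ax <- gsub("YX$", "", axes_hint)
  if (!grepl("^[TCZ]*$", ax) || !grepl("YX$", axes_hint)) {
    stop("unrecognized axes hint: ", axes_hint)
  }
  page_axes <- strsplit(ax, "")[[1]]
  if (length(page_axes) != 1L) {
    stop("axes underdetermined: hint '", axes_hint,
         "' cannot partition ", np, " pages over more than one axis")
  }
  sizes <- c(T = 1L, C = 1L, Z = 1L)
  sizes[page_axes] <- np
  unname(sizes)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  m <- jsonlite::read_json(sp, simplifyVector = TRUE)
  cal <- do.call(pixel_calibration, as.list(m$calibration[c("dx", "dy", "dz", "dt")]))
  roles <- m$channel_roles
  if (!is.null(roles)) names(roles) <- as.character(seq_along(roles))
  list(
    sizes = as.integer(m$sizes),
    calibration = cal,
    channel_roles = roles,
    scale = if (length(m$scale)) as.numeric(m$scale) else NULL
  )
}

# Minimal OME-XML reader: sizes, dimension order, physical pixel sizes,
# channel names (used as roles when they match known role labels).
parse_ome_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  att <- function(a, default = NA) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) default else v
  }
  sizes <- c(
    as.integer(att("SizeT", "1")),
    as.integer(att("SizeC", "1")),
    as.integer(att("SizeZ", "1"))
  )
  cal <- NULL
  if (!is.na(att("PhysicalSizeX"))) {
    cal <- pixel_calibration(
      dx = as.numeric(att("PhysicalSizeX")),
      dy = as.numeric(att("PhysicalSizeY", att("PhysicalSizeX"))),
      dz = as.numeric(att("PhysicalSizeZ", "1.5")),
      dt = if (!is.na(att("TimeIncrement"))) as.numeric(att("TimeIncrement")) else 1
    )
  }
  chn <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  roles <- NULL
  if (length(chn) == sizes[2]) {
    nm <- xml2::xml_attr(chn, "Name")
    if (all(!is.na(nm)) && all(nm %in% stack_roles)) {
      roles <- nm
      names(roles) <- as.character(seq_along(roles))
    }
  }
  list(sizes = sizes, calibration = cal, channel_roles = roles, scale = NULL)
}

#' Write an image stack to TIFF with a JSON metadata sidecar
#'
#' Pages are emitted in T (slowest), C, Z (fastest) order. Integer-valued
#' stacks within the 16-bit range are stored losslessly as 16-bit TIFF;
#' other stacks are stored as 32-bit float scaled to `[0, 1]` with the scale
#' recorded in the sidecar. The sidecar (`<path>.meta.json`) carries axis
#' sizes, calibration and channel roles so that [read_stack()] restores the
#' stack without guessing.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  integerish <- mx <= 65535 && all(stack$data == round(stack$data))
  scale <- NULL
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    m <- stack$data[t, ch, z, , ]
    dim(m) <- d[4:5]
    pages[[p]] <- if (integerish) m / 65535 else m / max(mx, .Machine$double.eps)
    p <- p + 1L
  }
  if (!integerish) scale <- max(mx, .Machine$double.eps)
  tiff::writeTIFF(pages, path, bits.per.sample = if (integerish) 16L else 32L,
                  compression = "none")
  meta <- list(
    sizes = d[1:3],
    calibration = stack$calibration[c("dx", "dy", "dz", "dt")],
    channel_roles = unname(stack$channel_roles),
    scale = scale
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a result table as CSV
#'
#' Plain-CSV output with a header row; numeric columns keep full double
#' precision so a re-read reproduces the values.
#'
#' @param table A data.frame with unique column names.
#' @param path Output path; the directory is created if needed.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop("column names must be unique")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
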