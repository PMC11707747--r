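#' Multichannel image bundle
#'
#' The package's in-memory image container: a numeric array (rows = y,
#' cols = x, slices = channels) together with channel names, the physical
#' pixel size in micrometres, and provenance. The magnification tag follows
#' the convention 40x = 0.25 um/px, 10x = 1.0 um/px.
#'
#' Coordinates are pixel-centred, origin top-left, x = column, y = row.
#'
#' @param data numeric matrix or 3-d array
#' @param channels character vector of channel names, one per slice
#' @param pixel_size_um physical pixel size in micrometres (> 0)
#' @param provenance named list (seed, config hash, ...) carried through I/O
#' @return an `image_bundle` object
#' @export
image_bundle <- function(data, channels = NULL, pixel_size_um = 0.25,
                         provenance = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) vs_abort("`data` must be a matrix or h x w x c array")
  nc <- dim(data)[3]
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nc) - 1L)
  if (length(channels) != nc) {
    vs_abort(sprintf("channel-name count (%d) != channel count (%d)",
                     length(channels), nc))
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    vs_abort("`pixel_size_um` must be a positive number")
  }
  structure(
    list(data = data, channels = as.character(channels),
         pixel_size_um = as.numeric(pixel_size_um),
         magnification = mag_from_pixel_size(pixel_size_um),
         provenance = provenance),
    class = "image_bundle"
  )
}

#' @export
print.image_bundle <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_bundle> %d x %d px, %d channel(s) [%s]\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  cat(sprintf("  pixel size %.4g um/px (%.3gx)\n", x$pixel_size_um, x$magnification))
  invisible(x)
}

#' @export
dim.image_bundle <- function(x) dim(x$data)

#' Extract one channel of a bundle as a matrix
#' @param bundle an [image_bundle()]
#' @param channel channel name or index
#' @return numeric matrix
#' @export
get_channel <- function(bundle, channel) {
  stopifnot(inherits(bundle, "image_bundle"))
  if (is.character(channel)) {
    i <- match(channel, bundle$channels)
    if (is.na(i)) vs_abort(sprintf("no channel named '%s'", channel))
  } else i <- as.integer(channel)
  bundle$data[, , i]
}

#' Write a multichannel image to TIFF
#'
#' One 32-bit float page per channel. Channel names, pixel size and
#' provenance are written as a JSON sidecar (`<path>.json`) next to the
#' image, so the round trip through [read_multichannel_image()] is
#' lossless; the TIFF itself stays a plain multipage float TIFF any viewer
#' can open.
#'
#' @param bundle an [image_bundle()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_multichannel_image <- function(bundle, path) {
  stopifnot(inherits(bundle, "image_bundle"))
  # TIFF float pages are stored in [0, 1]; each channel is affinely mapped
  # there and its (offset, scale) recorded in the sidecar for exact restore
  ranges <- t(vapply(seq_along(bundle$channels),
                     function(i) range(bundle$data[, , i]), numeric(2)))
  pages <- lapply(seq_along(bundle$channels), function(i) {
    m <- bundle$data[, , i]
    span <- ranges[i, 2] - ranges[i, 1]
    if (span > 0) (m - ranges[i, 1]) / span else m * 0
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    vs_abort(sprintf("failed to write TIFF '%s': %s", path, as.character(ok)))
  }
  jsonlite::write_json(list(channels = bundle$channels,
                            pixel_size_um = bundle$pixel_size_um,
                            magnification = bundle$magnification,
                            channel_min = ranges[, 1], channel_max = ranges[, 2],
                            provenance = bundle$provenance),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multichannel TIFF written by this package (or any plain TIFF)
#'
#' Channel names and pixel size are recovered from the JSON sidecar when
#' present; otherwise channels are auto-named `ch00`, `ch01`, ... and a
#' default pixel size of 0.25 um (40x) is assumed, with a warning.
#'
#' @param path TIFF file path
#' @return an [image_bundle()]
#' @export
read_multichannel_image <- function(path) {
  if (!file.exists(path)) vs_abort(sprintf("no such file: '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (is.matrix(p)) p else as_gray(p, "luminance"))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  a <- array(0, c(h, w, length(pages)))
  for (i in seq_along(pages)) a[, , i] <- pages[[i]]
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- try(jsonlite::fromJSON(sidecar_path(path)), silent = TRUE)
    if (inherits(meta, "try-error")) meta <- NULL
  }
  if (is.null(meta)) {
    rlang::warn(sprintf(
      "'%s' has no channel/pixel-size metadata; auto-naming channels and assuming 0.25 um/px",
      path))
    return(image_bundle(a, pixel_size_um = 0.25))
  }
  if (length(meta$channels) != dim(a)[3]) {
    vs_abort(sprintf("metadata lists %d channels but file has %d pages",
                     length(meta$channels), dim(a)[3]))
  }
  if (!is.null(meta$channel_min)) {
    for (i in seq_len(dim(a)[3])) {
      span <- meta$channel_max[i] - meta$channel_min[i]
      a[, , i] <- if (span > 0) a[, , i] * span + meta$channel_min[i] else
        a[, , i] + meta$channel_min[i]
    }
  }
  prov <- meta$provenance
  if (is.null(prov) || length(prov) == 0) prov <- list()
  image_bundle(a, channels = meta$channels,
               pixel_size_um = meta$pixel_size_um, provenance = as.list(prov))
}

mif_channel_names <- function() c("DAPI", "PanCK", "PD-L1", "CD3", "CD8", "residualAF")
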