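#' Warp specification
#'
#' Describes a controlled misalignment for registration fixtures: a global
#' sub-pixel translation and/or a local Gaussian-profile displacement with
#' compact support, emulating the small folds and tears that mIF antigen
#' retrieval introduces.
#'
#' @param dx,dy global translation in pixels (content moves right/down for
#'   positive values); sub-pixel values are honoured via bilinear
#'   interpolation
#' @param local optional local warp: a list with `cx`, `cy` (centre, px),
#'   `radius` (hard support radius, px), `amp_x`, `amp_y` (peak
#'   displacement, px). Displacement decays as a Gaussian of sd `radius/2.5`
#'   and is exactly zero outside `radius`.
#' @return a `warp_spec` list
#' @export
warp_spec <- function(dx = 0, dy = 0, local = NULL) {
  if (!is.null(local)) {
    need <- c("cx", "cy", "radius", "amp_x", "amp_y")
    if (!all(need %in% names(local))) {
      vs_abort(sprintf("`local` must have fields %s", paste(need, collapse = ", ")))
    }
  }
  structure(list(dx = dx, dy = dy, local = local), class = "warp_spec")
}

warp_one_plane <- function(m, spec) {
  h <- nrow(m); w <- ncol(m)
  gx <- rep(seq_len(w), each = h)
  gy <- rep(seq_len(h), w)
  ddx <- rep(spec$dx, h * w)
  ddy <- rep(spec$dy, h * w)
  if (!is.null(spec$local)) {
    l <- spec$local
    d2 <- (gx - l$cx)^2 + (gy - l$cy)^2
    prof <- exp(-d2 / (2 * (l$radius / 2.5)^2))
    prof[d2 > l$radius^2] <- 0
    ddx <- ddx + l$amp_x * prof
    ddy <- ddy + l$amp_y * prof
  }
  # inverse mapping: sample the source at target minus displacement
  matrix(bilinear_sample(m, gy - ddy, gx - ddx), h, w)
}

#' Apply a warp to an image
#'
#' Pure-translation specs shift the content by exactly the stated vector;
#' local warps displace pixels only inside their support radius (pixels
#' farther than `radius` from the centre are bitwise unchanged).
#'
#' @param image an [image_bundle()], matrix, or h x w x c array
#' @param spec a [warp_spec()]
#' @return warped image of the same type
#' @export
apply_warp <- function(image, spec) {
  stopifnot(inherits(spec, "warp_spec"))
  dims <- if (inherits(image, "image_bundle")) dim(image$data) else
    if (is.matrix(image)) c(dim(image), 1L) else dim(image)
  if (abs(spec$dx) >= dims[2] || abs(spec$dy) >= dims[1]) {
    vs_abort("warp displacement exceeds the image extent")
  }
  if (identical(spec$dx, 0) && identical(spec$dy, 0) && is.null(spec$local)) {
    return(image)
  }
  wp <- function(a) {
    if (is.matrix(a)) return(warp_one_plane(a, spec))
    for (k in seq_len(dim(a)[3])) a[, , k] <- warp_one_plane(a[, , k], spec)
    a
  }
  if (inherits(image, "image_bundle")) {
    image$data <- wp(image$data)
    image
  } else {
    wp(image)
  }
}
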