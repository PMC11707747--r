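#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats optimize optim rnorm runif setNames quantile sd median cor qnorm
#' @importFrom utils head tail
NULL

vs_abort <- function(msg, class = "virtustain_error") {
  rlang::abort(msg, class = class)
}

# pixel-size <-> magnification convention used throughout:
# 40x = 0.25 um/px, 10x = 1.0 um/px  =>  magnification = 10 / pixel_size_um
mag_from_pixel_size <- function(pixel_size_um) 10 / pixel_size_um

pixel_size_from_mag <- function(magnification) 10 / magnification

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert a multichannel array to grayscale
#'
#' Channel-mean for fluorescence stacks (AF, mIF), luminance for 3-channel
#' RGB brightfield images. A plain matrix is returned unchanged.
#'
#' @param x matrix or 3-d array (rows = y, cols = x, slices = channels)
#' @param mode `"auto"`, `"mean"`, or `"luminance"`
#' @return numeric matrix
#' @export
as_gray <- function(x, mode = c("auto", "mean", "luminance")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) return(x)
  if (length(dim(x)) != 3L) vs_abort("expected a matrix or h x w x c array")
  nc <- dim(x)[3]
  if (mode == "auto") mode <- if (nc == 3L) "luminance" else "mean"
  if (mode == "luminance" && nc == 3L) {
    0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
  } else {
    apply(x, c(1, 2), mean)
  }
}

normalize01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

# Gaussian blur with replicate boundary (EBImage filter2 backend).
blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

blur_stack <- function(a, sigma) {
  if (sigma <= 0) return(a)
  for (k in seq_len(dim(a)[3])) a[, , k] <- blur2d(a[, , k], sigma)
  a
}

# 2x decimation with pre-smoothing; one Gaussian-pyramid level.
downsample2 <- function(m) {
  s <- blur2d(m, 1)
  s[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

gaussian_pyramid <- function(m, levels) {
  out <- vector("list", levels)
  out[[1]] <- m
  if (levels > 1) for (l in 2:levels) out[[l]] <- downsample2(out[[l - 1]])
  out
}

# Sample matrix m at real-valued coordinates (y, x), 1-based pixel centres,
# bilinear interpolation, replicate border.
bilinear_sample <- function(m, ys, xs) {
  h <- nrow(m); w <- ncol(m)
  ys <- clamp(ys, 1, h); xs <- clamp(xs, 1, w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- ys - y0; fx <- xs - x0
  idx <- function(yy, xx) m[cbind(yy, xx)]
  (1 - fy) * (1 - fx) * idx(y0, x0) +
    (1 - fy) * fx * idx(y0, x1) +
    fy * (1 - fx) * idx(y1, x0) +
    fy * fx * idx(y1, x1)
}

# Shift image content by (dx, dy) pixels (content moves right/down for
# positive values); sub-pixel via bilinear interpolation, replicate border.
shift_image <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  v <- bilinear_sample(m, g$y - dy, g$x - dx)
  matrix(v, h, w)
}

# Otsu threshold on a numeric vector (maximal between-class variance,
# 256-bin histogram over the data range).
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Remove connected components smaller than min_px from a logical mask.
remove_small_objects <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# disk-shaped structuring element
disk_kernel <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

rot90a <- function(a, k = 1L) {
  # counter-clockwise 90-degree rotations of a matrix or h x w x c array
  k <- ((k %% 4L) + 4L) %% 4L
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  rotm <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (k == 0L) return(a)
  if (is.matrix(a)) return(rotm(a))
  slices <- lapply(seq_len(dim(a)[3]), function(i) rotm(a[, , i]))
  out <- array(0, c(dim(slices[[1]]), dim(a)[3]))
  for (i in seq_along(slices)) out[, , i] <- slices[[i]]
  out
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    vs_abort("a single integer `seed` is required")
  }
  as.integer(seed)
}
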