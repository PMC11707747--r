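#' Pseudo-IHC rendering configuration
#'
#' Beer-Lambert absorption model mapping three mIF intensity maps (DAPI,
#' target stain, residual AF) to an IHC-like brightfield RGB image:
#' `rgb = color_offset + page_white * exp(-M %*% a)` per pixel, where `a`
#' are the normalized absorbance inputs and the columns of `M` hold the
#' optical-density coefficients of the hematoxylin-like, DAB-like, and
#' tissue-background components. Zero intensity everywhere renders exactly
#' the page color, matching empty regions of real brightfield scans. The
#' mapping is strictly pixel-wise and algebraically invertible on its
#' un-clipped range.
#'
#' @param od_matrix 3 x 3 nonnegative matrix; rows = RGB, columns =
#'   (hematoxylin, DAB, background-AF). Must be well conditioned.
#' @param intensity_norms positive 3-vector; raw intensities are divided by
#'   these (then clipped at 1) to give normalized absorbance inputs
#' @param color_offset RGB offset added to the transmitted light
#' @param page_white base transmittance color of the empty page
#' @param max_condition maximum allowed condition number of `od_matrix`
#' @return a `pihc_config` list
#' @export
pihc_config <- function(od_matrix = default_od_matrix(),
                        intensity_norms = c(dapi = 150, target = 150, af = 5),
                        color_offset = c(0.02, 0.02, 0.04),
                        page_white = c(0.93, 0.92, 0.90),
                        max_condition = 1e4) {
  od_matrix <- as.matrix(od_matrix)
  if (!all(dim(od_matrix) == c(3L, 3L))) vs_abort("`od_matrix` must be 3 x 3")
  if (any(od_matrix < 0)) vs_abort("optical-density coefficients must be >= 0")
  kap <- kappa(od_matrix, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    vs_abort(sprintf("`od_matrix` is ill-conditioned (condition number %.3g > %.3g); the inverse rendering requires an invertible matrix",
                     kap, max_condition))
  }
  if (any(intensity_norms <= 0)) vs_abort("`intensity_norms` must be positive")
  if (any(page_white + color_offset > 1) || any(color_offset < 0)) {
    vs_abort("`page_white + color_offset` must stay within the displayable [0, 1] range")
  }
  structure(list(od_matrix = od_matrix,
                 intensity_norms = as.numeric(intensity_norms),
                 color_offset = as.numeric(color_offset),
                 page_white = as.numeric(page_white)),
            class = "pihc_config")
}

#' Default optical-density matrix (hematoxylin, DAB, weak gray background)
#' @return 3 x 3 matrix, rows RGB, columns stains
#' @export
default_od_matrix <- function() {
  hema <- c(0.65, 0.70, 0.29)          # blue-purple nuclear stain direction
  dab <- c(0.27, 0.57, 0.78)           # brown chromogen direction
  bg <- c(0.30, 0.30, 0.30)            # weak gray tissue background
  m <- cbind(hematoxylin = hema / sqrt(sum(hema^2)) * 1.8,
             dab = dab / sqrt(sum(dab^2)) * 1.6,
             background = bg / sqrt(sum(bg^2)) * 0.35)
  rownames(m) <- c("R", "G", "B")
  m
}

as_plane <- function(x, name) {
  if (inherits(x, "image_bundle")) x <- x$data[, , 1]
  if (!is.matrix(x)) vs_abort(sprintf("`%s` must be a matrix intensity map", name))
  x
}

#' Render a pseudo-IHC RGB image from three mIF intensity maps
#'
#' The DAPI map renders the hematoxylin component (nuclei blue-purple), the
#' target-stain map renders the DAB component (target brown), and the
#' residual-AF map renders the gray tissue background. Strictly pixel-wise;
#' each RGB channel is monotone non-increasing in every input.
#'
#' @param dapi,target,residual_af equal-shape nonnegative matrices
#' @param config a [pihc_config()]
#' @return h x w x 3 RGB array in \[0, 1\] with attribute `"clipped"` giving
#'   the count of normalized intensities clipped at 1
#' @export
mif_to_pihc <- function(dapi, target, residual_af, config = pihc_config()) {
  stopifnot(inherits(config, "pihc_config"))
  dapi <- as_plane(dapi, "dapi"); target <- as_plane(target, "target")
  residual_af <- as_plane(residual_af, "residual_af")
  if (!all(dim(dapi) == dim(target)) || !all(dim(dapi) == dim(residual_af))) {
    vs_abort("the three intensity maps must have identical shapes")
  }
  tol <- -1e-9 * max(config$intensity_norms)
  if (min(dapi) < tol || min(target) < tol || min(residual_af) < tol) {
    vs_abort("intensity maps must be nonnegative")
  }
  dapi <- pmax(dapi, 0); target <- pmax(target, 0); residual_af <- pmax(residual_af, 0)
  nrm <- config$intensity_norms
  A <- cbind(as.vector(dapi) / nrm[1], as.vector(target) / nrm[2],
             as.vector(residual_af) / nrm[3])
  clipped <- sum(A > 1)
  A <- pmin(A, 1)
  OD <- A %*% t(config$od_matrix)          # n x 3, per-pixel RGB optical density
  rgb <- sweep(exp(-OD), 2, config$page_white, `*`)
  rgb <- sweep(rgb, 2, config$color_offset, `+`)
  out <- array(rgb, c(dim(dapi), 3L))
  attr(out, "clipped") <- clipped
  out
}

#' Invert a pseudo-IHC image back to its three mIF intensity maps
#'
#' Exact algebraic inverse of [mif_to_pihc()] on its un-clipped range:
#' `a = -M^{-1} log((rgb - offset) / white)`, then de-normalization. Pixels
#' whose transmittance leaves the log domain (<= 0 after offset removal) are
#' clamped to the domain boundary and counted; recovered intensities are
#' floored at 0.
#'
#' @param rgb h x w x 3 array
#' @param config a [pihc_config()]
#' @return list with matrices `dapi`, `target`, `residual_af` and the count
#'   `n_clamped` of out-of-domain pixels
#' @export
pihc_to_mif <- function(rgb, config = pihc_config()) {
  stopifnot(inherits(config, "pihc_config"))
  if (inherits(rgb, "image_bundle")) rgb <- rgb$data
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) vs_abort("`rgb` must be h x w x 3")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  Tm <- sweep(matrix(rgb, h * w, 3L), 2, config$color_offset, `-`)
  Tm <- sweep(Tm, 2, config$page_white, `/`)
  bad <- Tm <= 0 | Tm > 1
  n_clamped <- sum(rowSums(bad) > 0)
  if (n_clamped > 0) {
    rlang::warn(sprintf("%d pixel(s) outside the invertible transmittance domain were clamped", n_clamped))
  }
  Tm <- clamp(Tm, 1e-12, 1)
  A <- -log(Tm) %*% solve(t(config$od_matrix))   # forward is OD = A M^T
  A <- sweep(A, 2, config$intensity_norms, `*`)
  A <- pmax(A, 0)
  # exact zeros for numerically tiny recovered intensities
  A[abs(A) < 1e-9 * max(config$intensity_norms)] <- 0
  list(dapi = matrix(A[, 1], h, w), target = matrix(A[, 2], h, w),
       residual_af = matrix(A[, 3], h, w), n_clamped = n_clamped)
}

#' Overlay several pseudo-IHC renders of one section in absorbance space
#'
#' Each member image is converted to per-pixel optical density
#' `-log((rgb - offset)/white)`; optionally re-colored by projecting its
#' total stain density onto a pseudo-color direction; the densities are
#' summed and re-exposed through the Beer-Lambert model. A `NULL`
#' pseudo-color keeps the member's own hue, so a single image with identity
#' pseudo-color reproduces itself.
#'
#' @param pihc_set nonempty list of h x w x 3 arrays
#' @param pseudo_colors list (same length) of `NULL` or nonnegative
#'   3-vectors (the per-channel OD direction for that member)
#' @param config a [pihc_config()] (page color and offset)
#' @return h x w x 3 RGB array
#' @export
multiplex_overlay <- function(pihc_set, pseudo_colors = NULL,
                              config = pihc_config()) {
  if (!is.list(pihc_set) || length(pihc_set) == 0) {
    vs_abort("`pihc_set` must be a nonempty list of RGB images")
  }
  if (is.null(pseudo_colors)) pseudo_colors <- vector("list", length(pihc_set))
  if (length(pseudo_colors) != length(pihc_set)) {
    vs_abort("one pseudo-color (or NULL) per image is required")
  }
  d <- dim(pihc_set[[1]])
  od_of <- function(img) {
    if (!all(dim(img) == d)) vs_abort("all images must share one shape")
    Tm <- sweep(matrix(img, prod(d[1:2]), 3L), 2, config$color_offset, `-`)
    Tm <- sweep(Tm, 2, config$page_white, `/`)
    -log(clamp(Tm, 1e-12, 1))
  }
  total <- matrix(0, prod(d[1:2]), 3L)
  for (i in seq_along(pihc_set)) {
    od <- od_of(pihc_set[[i]])
    pc <- pseudo_colors[[i]]
    if (!is.null(pc)) {
      if (length(pc) != 3 || any(pc < 0)) vs_abort("pseudo-colors must be nonnegative 3-vectors")
      od <- rowMeans(od) %o% as.numeric(pc)
    }
    total <- total + od
  }
  rgb <- sweep(exp(-total), 2, config$page_white, `*`)
  rgb <- sweep(rgb, 2, config$color_offset, `+`)
  array(rgb, d)
}
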