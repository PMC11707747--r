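#' Detect tissue foreground
#'
#' Foreground where the smoothed total intensity exceeds an automatically
#' chosen (Otsu) threshold, morphologically cleaned. The threshold is
#' data-relative, so the mask is invariant to global intensity scaling.
#'
#' @param image an [image_bundle()], matrix, or array
#' @param sigma smoothing sd in pixels
#' @param min_object_px connected components smaller than this are dropped
#' @param invert detect dark-on-light tissue (brightfield H&E) when TRUE;
#'   `"auto"` inverts 3-channel RGB inputs
#' @return logical matrix (TRUE = tissue)
#' @export
tissue_mask <- function(image, sigma = 3, min_object_px = 64L, invert = "auto") {
  is_rgb <- (inherits(image, "image_bundle") && dim(image$data)[3] == 3L) ||
    (is.array(image) && !is.matrix(image) && dim(image)[3] == 3L)
  g <- if (inherits(image, "image_bundle")) as_gray(image$data) else as_gray(image)
  if (identical(invert, "auto")) invert <- is_rgb
  if (isTRUE(invert)) g <- max(g) - g
  if (length(g) == 0) vs_abort("empty image")
  s <- blur2d(g, sigma)
  if (diff(range(s)) < 1e-9) {
    rlang::warn("blank image: returning an empty tissue mask")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  thr <- otsu_threshold(as.vector(s))
  mask <- s > thr
  mask <- EBImage::closing(mask * 1, disk_kernel(3)) > 0
  mask <- remove_small_objects(matrix(as.logical(mask), nrow(g), ncol(g)), min_object_px)
  mask
}

#' Sampling policy for paired training patches
#'
#' @param tumor_weight_factor multiplicative weight inside PanCK-positive
#'   (tumor) regions, >= 1
#' @param pdl1_weight_factor multiplicative weight inside PD-L1-positive
#'   regions, >= 1
#' @param exclusion_mask optional logical raster; sampling probability is 0
#'   where TRUE (warped regions from registration QC)
#' @param seed integer seed for the patch draw
#' @return a `sampling_policy` list
#' @export
sampling_policy <- function(tumor_weight_factor = 3, pdl1_weight_factor = 3,
                            exclusion_mask = NULL, seed = 1L) {
  if (tumor_weight_factor < 1 || pdl1_weight_factor < 1) {
    vs_abort("weight factors must be >= 1")
  }
  structure(list(tumor_weight_factor = tumor_weight_factor,
                 pdl1_weight_factor = pdl1_weight_factor,
                 exclusion_mask = exclusion_mask, seed = check_seed(seed)),
            class = "sampling_policy")
}

positive_region <- function(channel, sigma = 2) {
  s <- blur2d(channel, sigma)
  if (diff(range(s)) < 1e-9) return(matrix(FALSE, nrow(s), ncol(s)))
  s > otsu_threshold(as.vector(s))
}

#' Build the normalized patch-centre sampling weights
#'
#' Weights are proportional to 1 on tissue, multiplied by the tumor factor
#' inside PanCK-positive regions and by the PD-L1 factor inside
#' PD-L1-positive regions (Otsu-thresholded smoothed channels), and exactly
#' 0 outside tissue or inside the exclusion mask. Normalized to sum to 1.
#'
#' @param tissue logical tissue raster
#' @param policy a [sampling_policy()]
#' @param panck,pdl1 optional intensity maps used for up-weighting
#' @return numeric probability matrix summing to 1
#' @export
build_sampling_weights <- function(tissue, policy = sampling_policy(),
                                   panck = NULL, pdl1 = NULL) {
  w <- tissue * 1
  if (!is.null(panck)) {
    w <- w * ifelse(positive_region(panck), policy$tumor_weight_factor, 1)
  }
  if (!is.null(pdl1)) {
    w <- w * ifelse(positive_region(pdl1), policy$pdl1_weight_factor, 1)
  }
  if (!is.null(policy$exclusion_mask)) w[policy$exclusion_mask] <- 0
  s <- sum(w)
  if (s <= 0) vs_abort("all-zero sampling weight field: nothing to sample from")
  w / s
}

#' Sample co-located AF/stain patch pairs
#'
#' Centres are drawn from the weight raster (deterministic per policy seed).
#' Each pair crops `af_size x af_size` from the AF image and the concentric
#' `(af_size + 2 pad) x (af_size + 2 pad)` window from the stain image; the
#' default geometry is 128 px AF vs 160 px stain (16-px pad per side) at 40x.
#'
#' @param af_wsi,stain_wsi aligned [image_bundle()]s (or arrays) at 40x
#' @param n number of pairs (>= 1)
#' @param weights probability raster from [build_sampling_weights()]
#' @param policy a [sampling_policy()] (supplies the seed)
#' @param af_size AF patch side in px (default 128)
#' @param pad stain padding per side in px (default 16)
#' @return list of `patch_pair`s, each `list(af, stain, center_xy)`, with a
#'   tibble manifest in attribute `"manifest"`
#' @export
sample_paired_patches <- function(af_wsi, stain_wsi, n, weights,
                                  policy = sampling_policy(),
                                  af_size = 128L, pad = 16L) {
  stopifnot(n >= 1)
  af <- if (inherits(af_wsi, "image_bundle")) af_wsi$data else af_wsi
  st <- if (inherits(stain_wsi, "image_bundle")) stain_wsi$data else stain_wsi
  if (is.matrix(af)) af <- array(af, c(dim(af), 1L))
  if (is.matrix(st)) st <- array(st, c(dim(st), 1L))
  h <- dim(af)[1]; w <- dim(af)[2]
  if (!all(dim(st)[1:2] == c(h, w))) vs_abort("AF and stain WSIs must be co-registered (equal shape)")
  stain_size <- af_size + 2L * pad
  if (h < stain_size || w < stain_size) vs_abort("WSI smaller than the stain patch footprint")
  half_af <- af_size / 2; half_st <- stain_size / 2
  # valid centres keep the full stain footprint inside the frame
  wts <- weights
  # centre c crops rows (c - half_st):(c + half_st - 1); keep them in frame
  lo_y <- as.integer(half_st) + 1L; hi_y <- h - as.integer(half_st) + 1L
  lo_x <- as.integer(half_st) + 1L; hi_x <- w - as.integer(half_st) + 1L
  valid <- matrix(FALSE, h, w)
  valid[lo_y:hi_y, lo_x:hi_x] <- TRUE
  wts[!valid] <- 0
  s <- sum(wts)
  if (s <= 0) vs_abort("no valid patch centres under the weight field")
  wts <- wts / s
  set.seed(policy$seed)
  idx <- sample.int(h * w, n, replace = TRUE, prob = as.vector(wts))
  cy <- (idx - 1L) %% h + 1L
  cx <- (idx - 1L) %/% h + 1L
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ya <- (cy[i] - half_af):(cy[i] + half_af - 1L)
    xa <- (cx[i] - half_af):(cx[i] + half_af - 1L)
    ys <- (cy[i] - half_st):(cy[i] + half_st - 1L)
    xs <- (cx[i] - half_st):(cx[i] + half_st - 1L)
    p <- list(af = af[ya, xa, , drop = FALSE],
              stain = st[ys, xs, , drop = FALSE],
              center_xy = c(cx[i], cy[i]))
    stopifnot(dim(p$stain)[1] == dim(p$af)[1] + 2L * pad,
              dim(p$stain)[2] == dim(p$af)[2] + 2L * pad)
    class(p) <- "patch_pair"
    pairs[[i]] <- p
  }
  attr(pairs, "manifest") <- tibble::tibble(
    i = seq_len(n), cx = cx, cy = cy, af_size = af_size, pad = pad,
    seed = policy$seed)
  pairs
}
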