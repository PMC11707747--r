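#' Normalized gradient-field / total-gradient distance between two patches
#'
#' Multimodal image distance based on edge orientation, insensitive to
#' contrast direction. For `metric = "ngf"` the distance is
#' `mean(1 - cos^2)` of the angle between regularized gradients,
#' `d = mean_px [ 1 - (<grad a, grad b> / (|grad a|_eps |grad b|_eps))^2 ]`,
#' with `|g|_eps = sqrt(|g|^2 + eps^2)`. For `metric = "ntg"` it is the
#' total-variation ratio `sum|grad(a - b)| / (sum|grad a| + sum|grad b|)`.
#'
#' @param a,b equal-shape grayscale matrices, expected normalized to \[0, 1\]
#' @param metric `"ngf"` or `"ntg"`
#' @param eps gradient regularizer as a fraction of the intensity range
#'   (guards constant regions); must be > 0 for constant patches
#' @param trim border pixels excluded from the sum (shift-evaluation guard)
#' @return nonnegative scalar distance
#' @export
gradient_field_distance <- function(a, b, metric = c("ngf", "ntg"),
                                    eps = 0.01, trim = 0L) {
  metric <- match.arg(metric)
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    vs_abort("`a` and `b` must be equal-shape matrices")
  }
  grad <- function(m) {
    h <- nrow(m); w <- ncol(m)
    gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
    gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
    list(gx = gx, gy = gy)
  }
  ga <- grad(a); gb <- grad(b)
  keep <- matrix(TRUE, nrow(a), ncol(a))
  if (trim > 0) {
    keep[] <- FALSE
    keep[(trim + 1):(nrow(a) - trim), (trim + 1):(ncol(a) - trim)] <- TRUE
  }
  if (metric == "ngf") {
    na2 <- ga$gx^2 + ga$gy^2
    nb2 <- gb$gx^2 + gb$gy^2
    if (eps <= 0 && (all(na2 == 0) || all(nb2 == 0))) {
      vs_abort("constant patch with eps = 0: gradient normalization undefined")
    }
    dot <- ga$gx * gb$gx + ga$gy * gb$gy
    denom <- sqrt((na2 + eps^2) * (nb2 + eps^2))
    mean((1 - (dot / denom)^2)[keep])
  } else {
    gd <- grad(a - b)
    num <- sum(sqrt(gd$gx^2 + gd$gy^2)[keep])
    den <- sum(sqrt(ga$gx^2 + ga$gy^2)[keep]) + sum(sqrt(gb$gx^2 + gb$gy^2)[keep])
    if (den == 0) {
      if (eps <= 0) vs_abort("constant patches with eps = 0: NTG undefined")
      return(0)
    }
    num / den
  }
}

# Powell's direction-set minimizer for smooth low-dimensional objectives.
# Line searches use Brent's method (stats::optimize) on a bounded interval.
powell_minimize <- function(f, x0, bounds, tol = 1e-3, maxit = 20L) {
  n <- length(x0)
  dirs <- diag(n)
  x <- x0
  fx <- f(x)
  for (it in seq_len(maxit)) {
    x_start <- x; f_start <- fx
    biggest_drop <- 0; biggest_i <- 1L
    for (i in seq_len(n)) {
      d <- dirs[, i]
      ls <- stats::optimize(function(s) f(x + s * d), interval = bounds, tol = tol / 4)
      if (ls$objective < fx) {
        drop <- fx - ls$objective
        if (drop > biggest_drop) { biggest_drop <- drop; biggest_i <- i }
        x <- x + ls$minimum * d
        fx <- ls$objective
      }
    }
    # Powell direction replacement: discard the direction of largest decrease
    dnew <- x - x_start
    if (sqrt(sum(dnew^2)) > 1e-12) {
      ls <- stats::optimize(function(s) f(x + s * dnew / sqrt(sum(dnew^2))),
                            interval = bounds, tol = tol / 4)
      if (ls$objective < fx) {
        x <- x + ls$minimum * dnew / sqrt(sum(dnew^2))
        fx <- ls$objective
      }
      dirs[, biggest_i] <- dnew / sqrt(sum(dnew^2))
    }
    if (f_start - fx < tol * (abs(f_start) + 1e-12) && sqrt(sum((x - x_start)^2)) < tol) break
  }
  list(par = x, value = fx, converged = TRUE, iterations = it)
}

#' Local translational alignment score of a patch pair
#'
#' Minimizes the gradient-field distance over a 2-d translation using
#' Powell's method, coarse-to-fine over a Gaussian pyramid (default three
#' levels, warm-starting each finer level from the coarser solution). The
#' magnitude of the recovered translation, scaled to micrometres, is the
#' alignment score (lower = better aligned); the 6-um rule is evaluated at
#' the 10x reference where 1 px = 1 um.
#'
#' @param a,b equal-shape grayscale patches (matrices); they are normalized
#'   to \[0, 1\] internally
#' @param metric `"ngf"` or `"ntg"`
#' @param pyramid_levels number of Gaussian pyramid levels (default 3)
#' @param pixel_size_um physical pixel size of the patches
#' @param eps gradient regularizer passed to [gradient_field_distance()]
#' @param max_shift_px Powell search bound at the finest level
#' @param tie_break_zero_tol treat |t| below this (px) as exactly zero
#' @return an `alignment_score` list: `translation_px` (x, y),
#'   `score_um_at_10x`, `metric`, `converged`
#' @export
local_translation_score <- function(a, b, metric = c("ngf", "ntg"),
                                    pyramid_levels = 3L, pixel_size_um = 1.0,
                                    eps = 0.01, max_shift_px = 32,
                                    tie_break_zero_tol = 1e-3) {
  metric <- match.arg(metric)
  if (!is.matrix(a)) a <- as_gray(a)
  if (!is.matrix(b)) b <- as_gray(b)
  if (min(dim(a)) < 32) vs_abort("patches must be at least 32 px")
  a <- normalize01(a); b <- normalize01(b)
  pa <- gaussian_pyramid(a, pyramid_levels)
  pb <- gaussian_pyramid(b, pyramid_levels)
  t_cur <- c(0, 0)
  converged <- TRUE
  for (l in rev(seq_len(pyramid_levels))) {
    lev_scale <- 2^(l - 1)
    al <- pa[[l]]; bl <- pb[[l]]
    trim <- max(2L, ceiling(max_shift_px / lev_scale / 4))
    obj <- function(t) {
      gradient_field_distance(al, shift_image(bl, t[1], t[2]),
                              metric = metric, eps = eps, trim = trim)
    }
    bound <- max_shift_px / lev_scale
    res <- try(powell_minimize(obj, t_cur, bounds = c(-bound, bound),
                               tol = if (l == 1) 1e-3 else 5e-3),
               silent = TRUE)
    if (inherits(res, "try-error")) { converged <- FALSE; break }
    t_lvl <- res$par
    val <- res$value
    # tie-breaks under an essentially flat objective: fractional shifts of b
    # add interpolation smoothing, which can shave a spurious ~0.02% off the
    # metric; prefer the integer (and then the zero) translation when it is
    # within 0.1% of the optimum
    t_int <- round(t_lvl)
    if (l == 1 && any(t_int != t_lvl) &&
        obj(t_int) <= val * (1 + 1e-3) + 1e-12) { t_lvl <- t_int; val <- obj(t_int) }
    if (sqrt(sum(t_lvl^2)) > tie_break_zero_tol &&
        obj(c(0, 0)) <= val * (1 + 1e-3) + 1e-12) t_lvl <- c(0, 0)
    t_cur <- if (l > 1) 2 * t_lvl else t_lvl
  }
  if (!converged) {
    return(structure(list(translation_px = c(NA_real_, NA_real_),
                          score_um_at_10x = Inf, metric = metric,
                          converged = FALSE),
                     class = "alignment_score"))
  }
  mag_px <- sqrt(sum(t_cur^2))
  if (mag_px < tie_break_zero_tol) { t_cur <- c(0, 0); mag_px <- 0 }
  structure(list(translation_px = t_cur,
                 score_um_at_10x = mag_px * pixel_size_um,
                 metric = metric, converged = TRUE),
            class = "alignment_score")
}

#' @export
print.alignment_score <- function(x, ...) {
  cat(sprintf("<alignment_score> t = (%.3f, %.3f) px, score %.3f um (%s)%s\n",
              x$translation_px[1], x$translation_px[2], x$score_um_at_10x,
              toupper(x$metric), if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Misalignment decision for an alignment score
#'
#' A region is flagged as misaligned when its alignment score is strictly
#' greater than the threshold (default 6 um at the 10x reference); a score
#' of exactly the threshold is retained.
#'
#' @param score an `alignment_score` or a numeric score in um
#' @param threshold_um exclusion threshold, default 6
#' @return a `qc_decision` list with `misaligned`, `score_um_at_10x`,
#'   `threshold_um`
#' @export
qc_decision <- function(score, threshold_um = 6.0) {
  s <- if (inherits(score, "alignment_score")) score$score_um_at_10x else as.numeric(score)
  stopifnot(threshold_um > 0)
  structure(list(misaligned = s > threshold_um, score_um_at_10x = s,
                 threshold_um = threshold_um),
            class = "qc_decision")
}

#' Tile-wise warping exclusion mask for a globally aligned image pair
#'
#' Tiles the pair on an overlapping grid, scores each tile with
#' [local_translation_score()], and flags every pixel covered by a tile
#' whose score exceeds the threshold. The mask feeds patch sampling:
#' flagged regions are excluded.
#'
#' @param af_img,stain_img aligned images ([image_bundle()] or matrix)
#' @param tile_px tile size in pixels at the images' own resolution
#' @param overlap fractional tile overlap (0.5 = 50%)
#' @param threshold_um exclusion threshold in um at the 10x reference
#' @param metric,pyramid_levels,eps passed to the scorer
#' @param max_shift_px Powell bound per tile
#' @return logical matrix mask (TRUE = excluded), with per-tile scores in
#'   attribute `"tiles"` (a tibble)
#' @export
qc_exclusion_mask <- function(af_img, stain_img, tile_px = 128L, overlap = 0.5,
                              threshold_um = 6.0, metric = "ngf",
                              pyramid_levels = 3L, eps = 0.01,
                              max_shift_px = 16) {
  px_um <- 1.0
  if (inherits(af_img, "image_bundle")) px_um <- af_img$pixel_size_um
  a <- if (inherits(af_img, "image_bundle")) as_gray(af_img$data, "mean") else as_gray(af_img)
  b <- if (inherits(stain_img, "image_bundle")) as_gray(stain_img$data) else as_gray(stain_img)
  if (!all(dim(a) == dim(b))) vs_abort("image pair must share one shape (empty overlap?)")
  h <- nrow(a); w <- ncol(a)
  if (h < tile_px || w < tile_px) vs_abort("images smaller than one tile")
  step <- max(1L, round(tile_px * (1 - overlap)))
  ys <- unique(c(seq(1L, h - tile_px + 1L, by = step), h - tile_px + 1L))
  xs <- unique(c(seq(1L, w - tile_px + 1L, by = step), w - tile_px + 1L))
  mask <- matrix(FALSE, h, w)
  rows <- vector("list", length(ys) * length(xs))
  k <- 0L
  for (y0 in ys) for (x0 in xs) {
    k <- k + 1L
    ta <- a[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L)]
    tb <- b[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L)]
    # featureless tiles carry no alignment information; retain them
    if (sd(ta) < 1e-8 || sd(tb) < 1e-8) {
      rows[[k]] <- tibble::tibble(x0 = x0, y0 = y0, score_um = 0, misaligned = FALSE)
      next
    }
    sc <- local_translation_score(ta, tb, metric = metric,
                                  pyramid_levels = pyramid_levels,
                                  pixel_size_um = px_um, eps = eps,
                                  max_shift_px = max_shift_px)
    dec <- qc_decision(sc, threshold_um)
    if (dec$misaligned) {
      mask[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L)] <- TRUE
    }
    rows[[k]] <- tibble::tibble(x0 = x0, y0 = y0, score_um = dec$score_um_at_10x,
                                misaligned = dec$misaligned)
  }
  attr(mask, "tiles") <- dplyr::bind_rows(rows)
  mask
}

# ---- global affine alignment -------------------------------------------

#' Affine transform container
#' @param matrix 2 x 3 matrix `[A | t]` mapping centre-origin target pixel
#'   coordinates (x, y) to source coordinates
#' @param pixel_size_um pixel size of the frames
#' @return an `affine_transform`
#' @export
affine_transform <- function(matrix = cbind(diag(2), c(0, 0)), pixel_size_um = 1.0) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(2L, 3L)))
  if (abs(det(matrix[, 1:2])) < 1e-8) vs_abort("affine linear part is singular")
  structure(list(matrix = matrix, pixel_size_um = pixel_size_um),
            class = "affine_transform")
}

# warp `moving` into the fixed frame: for each target pixel p (centre-origin),
# sample moving at A p + t
apply_affine <- function(img, tf) {
  m <- if (inherits(img, "image_bundle")) img$data else img
  wp <- function(plane) {
    h <- nrow(plane); w <- ncol(plane)
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    gx <- rep(seq_len(w), each = h) - cx
    gy <- rep(seq_len(h), w) - cy
    sx <- tf$matrix[1, 1] * gx + tf$matrix[1, 2] * gy + tf$matrix[1, 3] + cx
    sy <- tf$matrix[2, 1] * gx + tf$matrix[2, 2] * gy + tf$matrix[2, 3] + cy
    matrix(bilinear_sample(plane, sy, sx), h, w)
  }
  if (is.matrix(m)) out <- wp(m)
  else { out <- m; for (k in seq_len(dim(m)[3])) out[, , k] <- wp(m[, , k]) }
  if (inherits(img, "image_bundle")) { img$data <- out; img } else out
}

#' Global affine alignment of an image pair
#'
#' Iterative multi-resolution estimation of the 6-parameter affine transform
#' mapping the fixed frame onto the moving image, minimizing the
#' gradient-field distance (Nelder-Mead refinement per pyramid level, with
#' a translation pre-search at the coarsest level). Pairs whose residual
#' distance fails to improve on the unaligned baseline are flagged as
#' failed, mirroring the exclusion of slides that cannot be aligned.
#'
#' @param moving,fixed images ([image_bundle()] or matrix)
#' @param metric `"ngf"` or `"ntg"`
#' @param pyramid_levels multi-resolution levels
#' @param eps gradient regularizer
#' @param maxit Nelder-Mead iterations per level
#' @return list: `transform` (an [affine_transform()]), `residual`,
#'   `baseline`, `converged`
#' @export
global_affine_align <- function(moving, fixed, metric = "ngf",
                                pyramid_levels = 3L, eps = 0.01, maxit = 400L) {
  px_um <- if (inherits(fixed, "image_bundle")) fixed$pixel_size_um else 1.0
  a <- if (inherits(fixed, "image_bundle")) as_gray(fixed$data) else as_gray(fixed)
  b <- if (inherits(moving, "image_bundle")) as_gray(moving$data) else as_gray(moving)
  if (!all(dim(a) == dim(b))) vs_abort("moving and fixed must share one shape")
  a <- normalize01(a); b <- normalize01(b)
  if (sd(a) < 1e-8 || sd(b) < 1e-8) vs_abort("blank image: nothing to align")
  pa <- gaussian_pyramid(a, pyramid_levels)
  pb <- gaussian_pyramid(b, pyramid_levels)
  # parameters: (a11-1, a12, a21, a22-1, tx, ty)
  par <- c(0, 0, 0, 0, 0, 0)
  obj_for <- function(al, bl, trim) {
    function(p) {
      tf <- affine_transform(cbind(matrix(c(1 + p[1], p[3], p[2], 1 + p[4]), 2, 2),
                                   c(p[5], p[6])))
      gradient_field_distance(al, apply_affine(bl, tf), metric = metric,
                              eps = eps, trim = trim)
    }
  }
  for (l in rev(seq_len(pyramid_levels))) {
    al <- pa[[l]]; bl <- pb[[l]]
    trim <- max(2L, round(min(dim(al)) * 0.08))
    f <- obj_for(al, bl, trim)
    if (l == pyramid_levels) {
      # coarse translation pre-search on an integer grid
      rng <- round(min(dim(al)) / 4)
      best <- c(0, 0); bestv <- f(par)
      for (ty in seq(-rng, rng, by = 2)) for (tx in seq(-rng, rng, by = 2)) {
        v <- f(c(par[1:4], tx, ty))
        if (v < bestv) { bestv <- v; best <- c(tx, ty) }
      }
      par[5:6] <- best
    }
    scale_t <- max(2, min(dim(al)) / 8)
    res <- stats::optim(par, f, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8,
                                       parscale = c(rep(0.05, 4), rep(scale_t, 2))))
    par <- res$par
    if (l > 1) par[5:6] <- par[5:6] * 2
  }
  # tie-break toward the identity when the objective is essentially flat
  # there: resampling under a near-identity warp smooths the moving image,
  # shaving a spurious few-1e-4 relative off the gradient metric (a genuine
  # sub-pixel misalignment costs ~1e-2), so prefer the exact identity
  f_fin <- obj_for(pa[[1]], pb[[1]], max(2L, round(min(dim(a)) * 0.08)))
  if (f_fin(rep(0, 6)) <= f_fin(par) * (1 + 1e-3) + 1e-12) par <- rep(0, 6)
  A <- matrix(c(1 + par[1], par[3], par[2], 1 + par[4]), 2, 2)
  tf <- affine_transform(cbind(A, par[5:6]), pixel_size_um = px_um)
  trim <- max(2L, round(min(dim(a)) * 0.08))
  resid <- gradient_field_distance(a, apply_affine(b, tf), metric = metric,
                                   eps = eps, trim = trim)
  base <- gradient_field_distance(a, b, metric = metric, eps = eps, trim = trim)
  # floor: the metric's self-distance on the fixed image (not 0 for NGF)
  floor0 <- gradient_field_distance(a, a, metric = metric, eps = eps, trim = trim)
  converged <- resid <= floor0 + 0.5 * max(base - floor0, 0) + 1e-9
  list(transform = tf, residual = resid, baseline = base,
       self_floor = floor0, converged = converged)
}
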