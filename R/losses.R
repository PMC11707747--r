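#' Intensity-dependent pixel weighting scheme
#'
#' Weight for the shift-invariant regression loss as a function of the
#' target-stain IF intensity: `w = max(1, log(min(i, imax)))`, so pixels
#' with higher target intensity count more, capped at the clip ceiling.
#' For noisy targets (CD8) a low-intensity clamp forces `w = 1` for all
#' intensities below `clamp_below` (15 for CD8), suppressing label noise
#' from background and nonspecific fluorescence.
#'
#' @param imax clip ceiling for the intensity (> 1, else the log weighting
#'   degenerates)
#' @param clamp_below intensities strictly below this get weight exactly 1
#'   (0 disables; 15 is the CD8 setting)
#' @param log_base `"e"` (default) or `"10"`
#' @return a `weighting_scheme` list
#' @export
weighting_scheme <- function(imax, clamp_below = 0, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  if (!is.numeric(imax) || imax <= 1) {
    vs_abort("`imax` must be > 1 (the log weighting degenerates otherwise)")
  }
  stopifnot(clamp_below >= 0)
  structure(list(imax = imax, clamp_below = clamp_below, log_base = log_base),
            class = "weighting_scheme")
}

#' CD8 weighting scheme (low-intensity clamp at 15)
#' @param imax clip ceiling
#' @return a [weighting_scheme()] with `clamp_below = 15`
#' @export
cd8_weighting_scheme <- function(imax = 255) weighting_scheme(imax, clamp_below = 15)

#' Evaluate the pixel weight
#'
#' Vectorizes element-wise over intensity maps. Always >= 1; equal to 1
#' whenever the intensity is below the clamp; non-decreasing in the
#' intensity; constant for intensities at or above `imax`.
#'
#' @param i nonnegative intensity (scalar, vector, or matrix)
#' @param scheme a [weighting_scheme()]
#' @return weights, same shape as `i`
#' @export
pixel_weight <- function(i, scheme) {
  stopifnot(inherits(scheme, "weighting_scheme"))
  if (any(i < 0)) vs_abort("intensities must be nonnegative")
  lg <- if (scheme$log_base == "e") log else log10
  w <- i  # preserve the input's shape (matrix/array dims)
  w[] <- pmax(1, lg(pmin(i, scheme$imax)))
  w[i < scheme$clamp_below] <- 1
  w
}

# crop the 128^2-equivalent window of a padded target at integer offset
crop_at <- function(target, dx, dy, size_h, size_w) {
  target[(dy + 1):(dy + size_h), (dx + 1):(dx + size_w), , drop = FALSE]
}

#' Shift-invariant weighted L1 + L2 regression loss
#'
#' The target comes padded by `pad` pixels per side (160 vs 128 in the
#' production geometry); the loss is the minimum over all integer crop
#' offsets `(dx, dy) in [0, 2 pad]^2` of the weighted mean L1 plus weighted
#' mean L2 error between the prediction and the crop, absorbing residual
#' global-alignment errors of up to `pad` px per axis. Weights (a padded
#' map, cropped identically) are normalized to mean 1, so uniform weights
#' reproduce the unweighted loss.
#'
#' @param pred h x w x c array (or matrix)
#' @param target_padded (h + 2 pad) x (w + 2 pad) x c array
#' @param weights optional (h + 2 pad) x (w + 2 pad) map
#' @return scalar loss with attributes `"offset"` (the minimizing `(dx, dy)`,
#'   `(pad, pad)` = centred) and `"l1"`, `"l2"` components at the minimum
#' @export
shift_invariant_loss <- function(pred, target_padded, weights = NULL) {
  if (is.matrix(pred)) pred <- array(pred, c(dim(pred), 1L))
  if (is.matrix(target_padded)) target_padded <- array(target_padded, c(dim(target_padded), 1L))
  dp <- dim(pred); dt <- dim(target_padded)
  if (dp[3] != dt[3]) vs_abort("prediction and target channel counts differ")
  pad2_h <- dt[1] - dp[1]; pad2_w <- dt[2] - dp[2]
  if (pad2_h < 0 || pad2_w < 0 || pad2_h %% 2 != 0 || pad2_w %% 2 != 0 ||
      pad2_h != pad2_w) {
    vs_abort("target must be the prediction padded by an equal whole number of pixels per side")
  }
  if (!is.null(weights) && !all(dim(weights)[1:2] == dt[1:2])) {
    vs_abort("weights must match the padded target shape")
  }
  best <- Inf; best_off <- c(0L, 0L); best_l1 <- NA_real_; best_l2 <- NA_real_
  pv <- as.vector(pred)
  for (dy in 0:pad2_h) for (dx in 0:pad2_w) {
    tc <- crop_at(target_padded, dx, dy, dp[1], dp[2])
    diff <- pv - as.vector(tc)
    if (is.null(weights)) {
      l1 <- mean(abs(diff)); l2 <- mean(diff^2)
    } else {
      wc <- weights[(dy + 1):(dy + dp[1]), (dx + 1):(dx + dp[2])]
      wc <- wc / mean(wc)
      wv <- rep(as.vector(wc), dp[3])
      l1 <- mean(wv * abs(diff)); l2 <- mean(wv * diff^2)
    }
    v <- l1 + l2
    if (v < best) { best <- v; best_off <- c(dx, dy); best_l1 <- l1; best_l2 <- l2 }
  }
  structure(best, offset = best_off, l1 = best_l1, l2 = best_l2)
}

# gradient of the shift-invariant loss w.r.t. the prediction, at the
# minimizing offset (the min over offsets is locally that branch)
shift_invariant_grad <- function(pred, target_padded, weights = NULL) {
  if (is.matrix(pred)) pred <- array(pred, c(dim(pred), 1L))
  if (is.matrix(target_padded)) target_padded <- array(target_padded, c(dim(target_padded), 1L))
  loss <- shift_invariant_loss(pred, target_padded, weights)
  off <- attr(loss, "offset")
  dp <- dim(pred)
  tc <- crop_at(target_padded, off[1], off[2], dp[1], dp[2])
  diff <- pred - tc
  n <- length(diff)
  if (is.null(weights)) {
    g <- (sign(diff) + 2 * diff) / n
  } else {
    wc <- weights[(off[2] + 1):(off[2] + dp[1]), (off[1] + 1):(off[1] + dp[2])]
    wc <- wc / mean(wc)
    wv <- array(rep(as.vector(wc), dp[3]), dp)
    g <- wv * (sign(diff) + 2 * diff) / n
  }
  list(value = as.numeric(loss), grad = g, offset = off)
}

#' Rotational consistency loss
#'
#' Mean L1 discrepancy between `rot_k^{-1}(G(rot_k(x)))` and `G(x)` for
#' 90-degree rotations `k`, penalizing orientation bias in the generator.
#' Exactly 0 for any spatially pointwise (rotation-equivariant) model.
#'
#' @param generator function mapping an h x w x c array to an output array
#' @param af_patch square input patch
#' @param k `NULL` to average over the three rotations, or one of 1:3
#'   (quarter-turns)
#' @return nonnegative scalar
#' @export
rotational_consistency_loss <- function(generator, af_patch, k = NULL) {
  if (is.matrix(af_patch)) af_patch <- array(af_patch, c(dim(af_patch), 1L))
  if (dim(af_patch)[1] != dim(af_patch)[2]) vs_abort("rotational consistency needs a square patch")
  base <- generator(af_patch)
  ks <- if (is.null(k)) 1:3 else as.integer(k)
  vals <- vapply(ks, function(kk) {
    back <- rot90a(generator(rot90a(af_patch, kk)), -kk)
    mean(abs(back - base))
  }, numeric(1))
  mean(vals)
}

#' Conditional and unconditional adversarial losses
#'
#' Non-saturating GAN objectives for the three-discriminator arrangement:
#' one conditional branch scoring (AF, stain) jointly and two unconditional
#' branches scoring the stain at full and half resolution. Returns the
#' generator-side and discriminator-side scalars, each a weighted sum over
#' branches:
#' `d = -log D(real) - log(1 - D(fake))`, `g = -log D(fake)`.
#'
#' @param discriminators list of three scoring functions (cond, uncond_full,
#'   uncond_half), each mapping its input array to a probability in (0, 1);
#'   trained discriminator networks are wrapped automatically by [train()]
#' @param af AF input patch (conditional branch context)
#' @param real_stain,fake_stain stain patches
#' @param branch_weights length-3 nonnegative weights (cond, uncond_full,
#'   uncond_half)
#' @return list `g_adv`, `d_adv`, and per-branch tibble `branches`
#' @export
adversarial_losses <- function(discriminators, af, real_stain, fake_stain,
                               branch_weights = c(1, 1, 1)) {
  if (length(discriminators) != 3L) vs_abort("three discriminator branches are required")
  stopifnot(length(branch_weights) == 3L, all(branch_weights >= 0))
  if (is.matrix(real_stain)) real_stain <- array(real_stain, c(dim(real_stain), 1L))
  if (is.matrix(fake_stain)) fake_stain <- array(fake_stain, c(dim(fake_stain), 1L))
  half <- function(x) {
    out <- array(0, c(floor(dim(x)[1] / 2), floor(dim(x)[2] / 2), dim(x)[3]))
    for (c_ in seq_len(dim(x)[3])) out[, , c_] <- downsample2(x[, , c_])[seq_len(dim(out)[1]), seq_len(dim(out)[2])]
    out
  }
  cat_ch <- function(a, b) {
    out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
    out[, , seq_len(dim(a)[3])] <- a
    out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
    out
  }
  inputs_real <- list(cat_ch(af, real_stain), real_stain, half(real_stain))
  inputs_fake <- list(cat_ch(af, fake_stain), fake_stain, half(fake_stain))
  eps <- 1e-12
  g <- 0; d <- 0
  rows <- vector("list", 3L)
  for (i in 1:3) {
    pr <- clamp(discriminators[[i]](inputs_real[[i]]), eps, 1 - eps)
    pf <- clamp(discriminators[[i]](inputs_fake[[i]]), eps, 1 - eps)
    d_i <- -log(pr) - log(1 - pf)
    g_i <- -log(pf)
    d <- d + branch_weights[i] * d_i
    g <- g + branch_weights[i] * g_i
    rows[[i]] <- tibble::tibble(branch = c("conditional", "unconditional_full",
                                           "unconditional_half")[i],
                                p_real = pr, p_fake = pf, d_loss = d_i, g_loss = g_i)
  }
  list(g_adv = g, d_adv = d, branches = dplyr::bind_rows(rows))
}

#' Fréchet distance between two feature distributions
#'
#' Gaussian-approximation Fréchet distance on sample moments:
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`. The matrix square
#' root trace is computed from the eigenvalues of `S1 S2` (clamped at 0);
#' near-singular covariances are diagonally regularized (logged).
#'
#' @param feats_real,feats_fake numeric matrices, rows = samples, columns =
#'   feature dimensions (vectors are treated as 1-d features)
#' @return nonnegative scalar
#' @export
frechet_feature_distance <- function(feats_real, feats_fake) {
  X <- if (is.null(dim(feats_real))) matrix(feats_real, ncol = 1) else as.matrix(feats_real)
  Y <- if (is.null(dim(feats_fake))) matrix(feats_fake, ncol = 1) else as.matrix(feats_fake)
  if (nrow(X) < 2 || nrow(Y) < 2) vs_abort("at least 2 feature vectors per set are required")
  if (ncol(X) != ncol(Y)) vs_abort("feature dimensions differ")
  mu1 <- colMeans(X); mu2 <- colMeans(Y)
  S1 <- stats::cov(X); S2 <- stats::cov(Y)
  reg <- 1e-10 * max(diag(S1), diag(S2), 1)
  if (rcond(S1 + diag(reg, ncol(X))) < 1e-12 || rcond(S2 + diag(reg, ncol(X))) < 1e-12) {
    rlang::inform("near-singular covariance: applying diagonal regularization")
    S1 <- S1 + diag(1e-8, ncol(X)); S2 <- S2 + diag(1e-8, ncol(X))
  }
  ev <- eigen(S1 %*% S2, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(Re(ev), 0)))
  max(0, sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * tr_sqrt)
}

#' Fixed-seed random-projection patch embedding
#'
#' Desk-scale feature extractor for the Fréchet distance: flattens each
#' patch and projects it onto `dim` fixed Gaussian directions (one shared
#' projection per patch shape and seed). A cheap, deterministic stand-in
#' feature space; any extractor returning a sample x feature matrix can be
#' plugged into [frechet_feature_distance()] instead.
#'
#' @param patches list of equal-shape arrays
#' @param dim embedding dimension
#' @param seed projection seed
#' @return matrix, one row per patch
#' @export
random_projection_features <- function(patches, dim = 16L, seed = 7L) {
  stopifnot(length(patches) >= 1)
  p <- length(patches[[1]])
  set.seed(check_seed(seed))
  P <- matrix(rnorm(p * dim), p, dim) / sqrt(p)
  t(vapply(patches, function(x) as.vector(as.vector(x) %*% P), numeric(dim)))
}
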