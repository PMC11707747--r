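#' Stainer training configuration
#'
#' Loss weights, optimizer schedule, and geometry of the pix2pix-style
#' virtual stainer. Any of `lambda_*` or `lr` may be a function of the step
#' (a schedule); scalars mean "constant". Adversarial branches are off by
#' default (desk-scale regression training); enabling them activates the
#' alternating generator/discriminator updates.
#'
#' @param in_channels,out_channels generator input/output channels
#' @param base_filters U-Net width at the top level
#' @param steps training steps
#' @param batch_size patches per step
#' @param lr Adam learning rate (scalar or `function(step)`)
#' @param lambda_reg weight of the shift-invariant regression loss
#' @param lambda_cond_adv,lambda_uncond_adv adversarial branch weights
#' @param lambda_rot rotational-consistency weight
#' @param lambda_l2 L2 weight-decay coefficient
#' @param weight_scheme optional [weighting_scheme()] for pixel weights
#'   derived from the target IF intensity
#' @param val_every validate (and checkpoint) every this many steps
#' @param fd_dim random-projection feature dimension for the Fréchet metric
#' @param seed master seed (init + batch draws)
#' @return a `stainer_config` list
#' @export
stainer_config <- function(in_channels = 20L, out_channels = 3L,
                           base_filters = 8L, steps = 200L, batch_size = 4L,
                           lr = 2e-3, lambda_reg = 1, lambda_cond_adv = 0,
                           lambda_uncond_adv = 0, lambda_rot = 0,
                           lambda_l2 = 0, weight_scheme = NULL,
                           val_every = 25L, fd_dim = 16L, seed = 1L) {
  lam <- c(lambda_reg = if (is.function(lambda_reg)) 0 else lambda_reg,
           lambda_cond_adv = if (is.function(lambda_cond_adv)) 0 else lambda_cond_adv,
           lambda_uncond_adv = if (is.function(lambda_uncond_adv)) 0 else lambda_uncond_adv,
           lambda_rot = if (is.function(lambda_rot)) 0 else lambda_rot,
           lambda_l2 = if (is.function(lambda_l2)) 0 else lambda_l2)
  if (any(lam < 0)) vs_abort("loss weights must be >= 0")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_filters = as.integer(base_filters),
                 steps = as.integer(steps), batch_size = as.integer(batch_size),
                 lr = lr, lambda_reg = lambda_reg,
                 lambda_cond_adv = lambda_cond_adv,
                 lambda_uncond_adv = lambda_uncond_adv,
                 lambda_rot = lambda_rot, lambda_l2 = lambda_l2,
                 weight_scheme = weight_scheme,
                 val_every = as.integer(val_every), fd_dim = as.integer(fd_dim),
                 seed = check_seed(seed)),
            class = "stainer_config")
}

sched_val <- function(x, step) if (is.function(x)) x(step) else x

pair_fields <- function(p) {
  af <- if (!is.null(p$af)) p$af else p[[1]]
  st <- if (!is.null(p$stain)) p$stain else p[[2]]
  if (is.matrix(af)) af <- array(af, c(dim(af), 1L))
  if (is.matrix(st)) st <- array(st, c(dim(st), 1L))
  list(af = af, stain = st, weight_map = p$weight_map)
}

validate_generator <- function(params, val_pairs, config) {
  gen <- make_generator(params)
  pad_of <- function(p) (dim(p$stain)[1] - dim(p$af)[1]) %/% 2L
  l1s <- numeric(length(val_pairs))
  preds <- vector("list", length(val_pairs))
  reals <- vector("list", length(val_pairs))
  for (i in seq_along(val_pairs)) {
    p <- pair_fields(val_pairs[[i]])
    y <- gen(p$af)
    ls <- shift_invariant_loss(y, p$stain)
    l1s[i] <- attr(ls, "l1")
    pd <- pad_of(p)
    preds[[i]] <- y
    reals[[i]] <- if (pd > 0) {
      p$stain[(pd + 1):(pd + dim(y)[1]), (pd + 1):(pd + dim(y)[2]), , drop = FALSE]
    } else p$stain
  }
  fd <- if (length(val_pairs) >= 2) {
    fr <- random_projection_features(reals, dim = config$fd_dim, seed = 7L)
    ff <- random_projection_features(preds, dim = config$fd_dim, seed = 7L)
    frechet_feature_distance(fr, ff)
  } else NA_real_
  list(val_l1 = mean(l1s), val_fd = fd)
}

#' Train the virtual stainer
#'
#' Alternating Adam updates of the U-Net generator (shift-invariant weighted
#' L1+L2 regression, optional rotational-consistency and adversarial terms,
#' L2 weight decay) and, when adversarial weights are nonzero, of the three
#' discriminators. Fully seeded: two runs with the same data, config and
#' seed produce identical loss curves. Validation L1 and the Fréchet
#' feature distance are logged every `val_every` steps and a generator
#' checkpoint is kept at each validation point.
#'
#' @param pairs training patch pairs (`list(af, stain)` each, stain padded)
#' @param val_pairs held-out pairs for validation
#' @param config a [stainer_config()]
#' @return a `virtustain_train` state: `history` tibble, `checkpoints`,
#'   `generator` (final params), `config`
#' @export
train <- function(pairs, val_pairs, config = stainer_config()) {
  stopifnot(inherits(config, "stainer_config"))
  if (length(pairs) < 1) vs_abort("at least one training pair is required")
  set.seed(config$seed)
  gp <- unet_init(config$in_channels, config$out_channels, config$base_filters,
                  seed = config$seed)
  gstate <- adam_init(gp)
  adv_on <- (!is.function(config$lambda_cond_adv) && config$lambda_cond_adv > 0) ||
    (!is.function(config$lambda_uncond_adv) && config$lambda_uncond_adv > 0) ||
    is.function(config$lambda_cond_adv) || is.function(config$lambda_uncond_adv)
  if (adv_on) {
    dcond <- disc_init(config$in_channels + config$out_channels,
                       config$base_filters, seed = config$seed + 101L)
    dfull <- disc_init(config$out_channels, config$base_filters,
                       seed = config$seed + 102L)
    dhalf <- disc_init(config$out_channels, config$base_filters,
                       seed = config$seed + 103L)
    dstates <- list(adam_init(dcond), adam_init(dfull), adam_init(dhalf))
  }
  history <- list()
  checkpoints <- list()
  v0 <- validate_generator(gp, val_pairs, config)
  history[[1]] <- tibble::tibble(step = 0L, loss = NA_real_, reg = NA_real_,
                                 rot = NA_real_, g_adv = NA_real_,
                                 d_adv = NA_real_, val_l1 = v0$val_l1,
                                 val_fd = v0$val_fd)
  checkpoints[[1]] <- list(step = 0L, params = gp,
                           val_l1 = v0$val_l1, val_fd = v0$val_fd)

  half_down <- function(x) {
    out <- array(0, c(dim(x)[1] %/% 2L, dim(x)[2] %/% 2L, dim(x)[3]))
    for (c_ in seq_len(dim(x)[3]))
      out[, , c_] <- pool2_fwd(x[, , c_, drop = FALSE])$y[, , 1]
    out
  }

  for (step in seq_len(config$steps)) {
    lr <- sched_val(config$lr, step)
    l_reg <- sched_val(config$lambda_reg, step)
    l_rot <- sched_val(config$lambda_rot, step)
    l_ca <- sched_val(config$lambda_cond_adv, step)
    l_ua <- sched_val(config$lambda_uncond_adv, step)
    l_l2 <- sched_val(config$lambda_l2, step)
    idx <- sample.int(length(pairs), min(config$batch_size, length(pairs)),
                      replace = length(pairs) < config$batch_size)
    gacc <- NULL
    tot_reg <- 0; tot_rot <- 0; tot_gadv <- 0; tot_dadv <- 0
    for (ii in idx) {
      p <- pair_fields(pairs[[ii]])
      fw <- unet_fwd(gp, p$af)
      dy <- array(0, dim(fw$y))
      # regression branch
      if (l_reg > 0) {
        wmap <- NULL
        if (!is.null(p$weight_map)) {
          wmap <- p$weight_map
        } else if (!is.null(config$weight_scheme) && !is.null(p$target_if)) {
          wmap <- pixel_weight(p$target_if, config$weight_scheme)
        }
        sg <- shift_invariant_grad(fw$y, p$stain, wmap)
        tot_reg <- tot_reg + sg$value
        dy <- dy + l_reg * sg$grad
      }
      # rotational-consistency branch (one quarter-turn, drawn per step)
      rot_extra <- NULL
      if (l_rot > 0) {
        kk <- sample(1:3, 1L)
        fw_r <- unet_fwd(gp, rot90a(p$af, kk))
        back <- rot90a(fw_r$y, -kk)
        n <- length(back)
        rl <- mean(abs(back - fw$y))
        tot_rot <- tot_rot + rl
        d_back <- sign(back - fw$y) / n
        dy <- dy - l_rot * d_back
        rot_extra <- list(cache = fw_r$cache, dout = rot90a(l_rot * d_back, kk))
      }
      # adversarial branch (generator side, discriminators frozen)
      disc_fb <- NULL
      if (adv_on && (l_ca > 0 || l_ua > 0)) {
        fake <- fw$y
        af_fake <- array(0, c(dim(p$af)[1], dim(p$af)[2],
                              dim(p$af)[3] + dim(fake)[3]))
        af_fake[, , seq_len(dim(p$af)[3])] <- p$af
        af_fake[, , dim(p$af)[3] + seq_len(dim(fake)[3])] <- fake
        fc <- disc_fwd(dcond, af_fake)
        ff <- disc_fwd(dfull, fake)
        fh <- disc_fwd(dhalf, half_down(fake))
        # non-saturating generator loss: -log D(fake); d/dz = -(1 - D)
        tot_gadv <- tot_gadv + l_ca * (-log(max(fc$prob, 1e-12))) +
          l_ua * (-log(max(ff$prob, 1e-12)) - log(max(fh$prob, 1e-12)))
        bc <- disc_bwd(dcond, fc$cache, -l_ca * (1 - fc$prob))
        bf <- disc_bwd(dfull, ff$cache, -l_ua * (1 - ff$prob))
        bh <- disc_bwd(dhalf, fh$cache, -l_ua * (1 - fh$prob))
        dfake <- bc$dx[, , dim(p$af)[3] + seq_len(dim(fake)[3]), drop = FALSE] + bf$dx
        # route the half-resolution gradient back through the downsampling
        dhalf_up <- array(0, dim(fake))
        for (c_ in seq_len(dim(fake)[3]))
          dhalf_up[, , c_] <- pool2_bwd(c(dim(fake)[1], dim(fake)[2], 1L),
                                        bh$dx[, , c_, drop = FALSE])[, , 1]
        dy <- dy + dfake + dhalf_up
        disc_fb <- list(af_fake = af_fake, fake = fake)
      }
      bw <- unet_bwd(gp, fw$cache, dy)
      g <- bw$grads
      if (!is.null(rot_extra)) {
        bw2 <- unet_bwd(gp, rot_extra$cache, rot_extra$dout)
        for (nm in names(g)) {
          g[[nm]]$dK <- g[[nm]]$dK + bw2$grads[[nm]]$dK
          g[[nm]]$db <- g[[nm]]$db + bw2$grads[[nm]]$db
        }
      }
      if (is.null(gacc)) gacc <- g
      else for (nm in names(g)) {
        gacc[[nm]]$dK <- gacc[[nm]]$dK + g[[nm]]$dK
        gacc[[nm]]$db <- gacc[[nm]]$db + g[[nm]]$db
      }
      # discriminator update (alternating, on this sample's real/fake)
      if (adv_on && (l_ca > 0 || l_ua > 0)) {
        pd <- (dim(p$stain)[1] - dim(p$af)[1]) %/% 2L
        real <- if (pd > 0) {
          p$stain[(pd + 1):(pd + dim(p$af)[1]),
                  (pd + 1):(pd + dim(p$af)[2]), , drop = FALSE]
        } else p$stain
        af_real <- disc_fb$af_fake
        af_real[, , dim(p$af)[3] + seq_len(dim(real)[3])] <- real
        dsets <- list(list(net = dcond, w = l_ca,
                           real = af_real, fake = disc_fb$af_fake),
                      list(net = dfull, w = l_ua, real = real, fake = disc_fb$fake),
                      list(net = dhalf, w = l_ua, real = half_down(real),
                           fake = half_down(disc_fb$fake)))
        nets <- list(dcond, dfull, dhalf)
        for (di in 1:3) {
          ds <- dsets[[di]]
          if (ds$w <= 0) next
          fr <- disc_fwd(ds$net, ds$real)
          fk <- disc_fwd(ds$net, ds$fake)
          tot_dadv <- tot_dadv + ds$w * (-log(max(fr$prob, 1e-12)) -
                                           log(max(1 - fk$prob, 1e-12)))
          br <- disc_bwd(ds$net, fr$cache, -ds$w * (1 - fr$prob))
          bk <- disc_bwd(ds$net, fk$cache, ds$w * fk$prob)
          dg <- br$grads
          for (nm in names(dg)) {
            dg[[nm]]$dK <- dg[[nm]]$dK + bk$grads[[nm]]$dK
            dg[[nm]]$db <- dg[[nm]]$db + bk$grads[[nm]]$db
          }
          upd <- adam_step(nets[[di]], dg, dstates[[di]], lr, step)
          nets[[di]] <- upd$params; dstates[[di]] <- upd$state
        }
        dcond <- nets[[1]]; dfull <- nets[[2]]; dhalf <- nets[[3]]
      }
    }
    nb <- length(idx)
    for (nm in names(gacc)) {
      gacc[[nm]]$dK <- gacc[[nm]]$dK / nb
      gacc[[nm]]$db <- gacc[[nm]]$db / nb
    }
    upd <- adam_step(gp, gacc, gstate, lr, step, weight_decay = l_l2)
    gp <- upd$params; gstate <- upd$state
    total <- l_reg * tot_reg / nb + l_rot * tot_rot / nb + tot_gadv / nb +
      l_l2 * param_sq_norm(gp)
    if (!is.finite(total)) {
      vs_abort(sprintf(
        "NaN/Inf loss at step %d (reg %.4g, rot %.4g, g_adv %.4g); aborting with diagnostics",
        step, tot_reg / nb, tot_rot / nb, tot_gadv / nb))
    }
    if (step %% config$val_every == 0L || step == config$steps) {
      v <- validate_generator(gp, val_pairs, config)
      history[[length(history) + 1L]] <- tibble::tibble(
        step = step, loss = total, reg = tot_reg / nb, rot = tot_rot / nb,
        g_adv = tot_gadv / nb, d_adv = tot_dadv / nb,
        val_l1 = v$val_l1, val_fd = v$val_fd)
      checkpoints[[length(checkpoints) + 1L]] <- list(
        step = step, params = gp, val_l1 = v$val_l1, val_fd = v$val_fd)
    } else {
      history[[length(history) + 1L]] <- tibble::tibble(
        step = step, loss = total, reg = tot_reg / nb, rot = tot_rot / nb,
        g_adv = tot_gadv / nb, d_adv = tot_dadv / nb,
        val_l1 = NA_real_, val_fd = NA_real_)
    }
  }
  structure(list(history = dplyr::bind_rows(history),
                 checkpoints = checkpoints, generator = gp, config = config),
            class = "virtustain_train")
}

#' @export
print.virtustain_train <- function(x, ...) {
  h <- x$history
  cat(sprintf("<virtustain_train> %d steps, %d checkpoints\n",
              max(h$step), length(x$checkpoints)))
  last <- dplyr::filter(h, !is.na(.data$val_l1))
  if (nrow(last)) {
    cat(sprintf("  val L1: %.5f (step 0) -> %.5f (final)\n",
                last$val_l1[1], last$val_l1[nrow(last)]))
  }
  invisible(x)
}

#' Tidy the training history
#' @param x a `virtustain_train`
#' @param ... unused
#' @return the per-step history tibble
#' @export
tidy.virtustain_train <- function(x, ...) x$history

#' One-row training summary
#' @param x a `virtustain_train`
#' @param ... unused
#' @return tibble with steps, final/initial validation L1 and FD, selected
#'   checkpoint
#' @export
glance.virtustain_train <- function(x, ...) {
  v <- dplyr::filter(x$history, !is.na(.data$val_l1))
  tibble::tibble(steps = max(x$history$step),
                 initial_val_l1 = v$val_l1[1],
                 final_val_l1 = v$val_l1[nrow(v)],
                 final_val_fd = v$val_fd[nrow(v)],
                 selected_step = select_checkpoint(x))
}

#' Select the best checkpoint by combined validation L1 and Fréchet distance
#'
#' Minimizes the rank-sum of the validation L1 rank and the Fréchet-distance
#' rank over all validated checkpoints; ties go to the earlier step.
#'
#' @param state a `virtustain_train`
#' @return the selected checkpoint's step (the parameters are in
#'   `state$checkpoints`)
#' @export
select_checkpoint <- function(state) {
  cks <- if (inherits(state, "virtustain_train")) state$checkpoints else state
  if (length(cks) == 0) vs_abort("no validated checkpoints to select from")
  l1 <- vapply(cks, function(c_) c_$val_l1, numeric(1))
  fd <- vapply(cks, function(c_) c_$val_fd, numeric(1))
  steps <- vapply(cks, function(c_) c_$step, numeric(1))
  if (all(is.na(fd))) fd <- l1 * 0
  rs <- rank(l1, ties.method = "min") + rank(fd, ties.method = "min")
  steps[order(rs, steps)][1]
}

checkpoint_params <- function(state, step) {
  for (c_ in state$checkpoints) if (c_$step == step) return(c_$params)
  vs_abort(sprintf("no checkpoint at step %d", step))
}

#' Tile-wise whole-slide inference with feathered blending
#'
#' Runs the generator over overlapping tiles and blends the seams with a
#' cosine-ramp feather, so the output matches single-pass inference in the
#' interior and has no tile artifacts. Output dimensions equal input
#' dimensions.
#'
#' @param af_wsi [image_bundle()] or array with the generator's input
#'   channel count
#' @param generator function from [make_generator()], or a
#'   `virtustain_train` (its selected checkpoint is used)
#' @param tile_px tile size (even; clipped to the image size)
#' @param overlap_px overlap between tiles (even)
#' @return stain [image_bundle()] (array input gives array output)
#' @export
predict_wsi <- function(af_wsi, generator, tile_px = 128L, overlap_px = 32L) {
  if (inherits(generator, "virtustain_train")) {
    generator <- make_generator(checkpoint_params(generator, select_checkpoint(generator)))
  }
  a <- if (inherits(af_wsi, "image_bundle")) af_wsi$data else af_wsi
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  h <- dim(a)[1]; w <- dim(a)[2]
  tile_px <- min(tile_px, h, w)
  tile_px <- tile_px - tile_px %% 2L
  overlap_px <- min(overlap_px, tile_px - 2L)
  step <- tile_px - overlap_px
  ys <- unique(c(seq(1L, max(1L, h - tile_px + 1L), by = step), h - tile_px + 1L))
  xs <- unique(c(seq(1L, max(1L, w - tile_px + 1L), by = step), w - tile_px + 1L))
  ramp <- function(n, ov) {
    r <- rep(1, n)
    if (ov > 0) {
      t <- (seq_len(ov) - 0.5) / ov
      r[seq_len(ov)] <- (1 - cos(pi * t)) / 2
      r[(n - ov + 1):n] <- rev((1 - cos(pi * t)) / 2)
    }
    r
  }
  wt2 <- outer(ramp(tile_px, overlap_px), ramp(tile_px, overlap_px))
  out <- NULL; acc_w <- matrix(0, h, w)
  for (y0 in ys) for (x0 in xs) {
    tl <- a[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L), , drop = FALSE]
    yhat <- generator(tl)
    if (is.null(out)) out <- array(0, c(h, w, dim(yhat)[3]))
    for (c_ in seq_len(dim(yhat)[3])) {
      out[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L), c_] <-
        out[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L), c_] + yhat[, , c_] * wt2
    }
    acc_w[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L)] <-
      acc_w[y0:(y0 + tile_px - 1L), x0:(x0 + tile_px - 1L)] + wt2
  }
  for (c_ in seq_len(dim(out)[3])) out[, , c_] <- out[, , c_] / acc_w
  if (inherits(af_wsi, "image_bundle")) {
    image_bundle(out, channels = sprintf("pred%02d", seq_len(dim(out)[3])),
                 pixel_size_um = af_wsi$pixel_size_um,
                 provenance = c(af_wsi$provenance, list(stage = "predict")))
  } else out
}
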