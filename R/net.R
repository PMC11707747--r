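# Minimal convolutional-network engine (forward + exact backprop) used by
# the virtual stainer. Arrays are h x w x c; convolutions are 3 x 3, stride
# 1, zero-padded "same", implemented with im2col so the heavy lifting is a
# single matrix multiply. All parameters live in plain nested lists, which
# keeps Adam and the determinism contract trivial.

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

conv_param <- function(cin, cout, k = 3L) {
  list(K = matrix(glorot_uniform(k * k * cin, k * k * cout, k * k * cin * cout),
                  k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

im2col3 <- function(x) {
  # 3x3 neighbourhoods, zero padding; returns (h*w) x (9*cin)
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  j <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1L
    sl <- xp[(1 + dy):(h + dy), (1 + dx):(w + dx), , drop = FALSE]
    cols[, ((j - 1L) * cin + 1L):(j * cin)] <- matrix(sl, h * w, cin)
  }
  cols
}

col2im3 <- function(dcols, h, w, cin) {
  dxp <- array(0, c(h + 2L, w + 2L, cin))
  j <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1L
    sl <- array(dcols[, ((j - 1L) * cin + 1L):(j * cin)], c(h, w, cin))
    dxp[(1 + dy):(h + dy), (1 + dx):(w + dx), ] <-
      dxp[(1 + dy):(h + dy), (1 + dx):(w + dx), , drop = FALSE] + sl
  }
  dxp[2:(h + 1), 2:(w + 1), , drop = FALSE]
}

conv_fwd <- function(p, x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  if (p$k == 1L) {
    xm <- matrix(x, h * w, p$cin)
    out <- xm %*% p$K + matrix(p$b, h * w, p$cout, byrow = TRUE)
    return(list(y = array(out, c(h, w, p$cout)), cache = list(xm = xm, h = h, w = w)))
  }
  cols <- im2col3(x)
  out <- cols %*% p$K + matrix(p$b, h * w, p$cout, byrow = TRUE)
  list(y = array(out, c(h, w, p$cout)), cache = list(cols = cols, h = h, w = w))
}

conv_bwd <- function(p, cache, dy) {
  h <- cache$h; w <- cache$w
  dym <- matrix(dy, h * w, p$cout)
  if (p$k == 1L) {
    dK <- crossprod(cache$xm, dym)
    db <- colSums(dym)
    dx <- array(dym %*% t(p$K), c(h, w, p$cin))
    return(list(dx = dx, dK = dK, db = db))
  }
  dK <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- dym %*% t(p$K)
  list(dx = col2im3(dcols, h, w, p$cin), dK = dK, db = db)
}

lrelu_fwd <- function(x, alpha = 0.2) {
  y <- ifelse(x > 0, x, alpha * x)
  list(y = y, cache = x > 0)
}
lrelu_bwd <- function(cache, dy, alpha = 0.2) ifelse(cache, dy, alpha * dy)

pool2_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  h2 <- h %/% 2L; w2 <- w %/% 2L
  y <- (x[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
          x[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
          x[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE] +
          x[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]) / 4
  list(y = y, cache = c(h, w, cc))
}
pool2_bwd <- function(cache, dy) {
  h <- cache[1]; w <- cache[2]; cc <- cache[3]
  dx <- array(0, c(h, w, cc))
  g <- dy / 4
  h2 <- dim(dy)[1]; w2 <- dim(dy)[2]
  dx[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), ] <- g
  dx[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), ] <- g
  dx[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), ] <- g
  dx[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), ] <- g
  dx
}

up2_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  idx_h <- rep(seq_len(h), each = 2); idx_w <- rep(seq_len(w), each = 2)
  list(y = x[idx_h, idx_w, , drop = FALSE], cache = c(h, w, dim(x)[3]))
}
up2_bwd <- function(cache, dy) {
  h <- cache[1]; w <- cache[2]; cc <- cache[3]
  (dy[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
     dy[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
     dy[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
     dy[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize U-Net generator parameters
#'
#' Compact two-level U-Net: two 3x3 conv + leaky-ReLU blocks per level, 2x2
#' average-pool down, nearest-neighbour up, skip concatenation, and a 1x1
#' sigmoid output head. Glorot-uniform initialization. Fully convolutional,
#' so any input size divisible by 2 works.
#'
#' @param in_channels,out_channels input/output channel counts
#' @param base_filters filters at the top level (doubled at the bottom)
#' @param seed init seed
#' @return a `unet_params` list
#' @export
unet_init <- function(in_channels = 20L, out_channels = 3L, base_filters = 8L,
                      seed = 1L) {
  set.seed(check_seed(seed))
  f <- base_filters
  p <- list(
    enc1a = conv_param(in_channels, f), enc1b = conv_param(f, f),
    enc2a = conv_param(f, 2L * f), enc2b = conv_param(2L * f, 2L * f),
    up1 = conv_param(2L * f, f),
    dec1a = conv_param(2L * f, f), dec1b = conv_param(f, f),
    head = conv_param(f, out_channels, k = 1L)
  )
  structure(p, class = "unet_params",
            in_channels = in_channels, out_channels = out_channels,
            base_filters = f)
}

unet_fwd <- function(p, x) {
  c1 <- conv_fwd(p$enc1a, x);  a1 <- lrelu_fwd(c1$y)
  c2 <- conv_fwd(p$enc1b, a1$y); a2 <- lrelu_fwd(c2$y)
  pl <- pool2_fwd(a2$y)
  c3 <- conv_fwd(p$enc2a, pl$y); a3 <- lrelu_fwd(c3$y)
  c4 <- conv_fwd(p$enc2b, a3$y); a4 <- lrelu_fwd(c4$y)
  up <- up2_fwd(a4$y)
  c5 <- conv_fwd(p$up1, up$y); a5 <- lrelu_fwd(c5$y)
  skip <- array(0, c(dim(a2$y)[1], dim(a2$y)[2], dim(a2$y)[3] + dim(a5$y)[3]))
  skip[, , seq_len(dim(a2$y)[3])] <- a2$y
  skip[, , dim(a2$y)[3] + seq_len(dim(a5$y)[3])] <- a5$y
  c6 <- conv_fwd(p$dec1a, skip); a6 <- lrelu_fwd(c6$y)
  c7 <- conv_fwd(p$dec1b, a6$y); a7 <- lrelu_fwd(c7$y)
  c8 <- conv_fwd(p$head, a7$y)
  y <- sigmoid(c8$y)
  list(y = y, cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, pl = pl,
                           c3 = c3, a3 = a3, c4 = c4, a4 = a4, up = up,
                           c5 = c5, a5 = a5, nskip = dim(a2$y)[3],
                           c6 = c6, a6 = a6, c7 = c7, a7 = a7, c8 = c8, y = y))
}

unet_bwd <- function(p, cache, dy) {
  g <- list()
  dz <- dy * cache$y * (1 - cache$y)
  b8 <- conv_bwd(p$head, cache$c8$cache, dz); g$head <- b8
  d7 <- lrelu_bwd(cache$a7$cache, b8$dx)
  b7 <- conv_bwd(p$dec1b, cache$c7$cache, d7); g$dec1b <- b7
  d6 <- lrelu_bwd(cache$a6$cache, b7$dx)
  b6 <- conv_bwd(p$dec1a, cache$c6$cache, d6); g$dec1a <- b6
  ns <- cache$nskip
  dskip_a2 <- b6$dx[, , seq_len(ns), drop = FALSE]
  dskip_a5 <- b6$dx[, , ns + seq_len(dim(b6$dx)[3] - ns), drop = FALSE]
  d5 <- lrelu_bwd(cache$a5$cache, dskip_a5)
  b5 <- conv_bwd(p$up1, cache$c5$cache, d5); g$up1 <- b5
  dup <- up2_bwd(cache$up$cache, b5$dx)
  d4 <- lrelu_bwd(cache$a4$cache, dup)
  b4 <- conv_bwd(p$enc2b, cache$c4$cache, d4); g$enc2b <- b4
  d3 <- lrelu_bwd(cache$a3$cache, b4$dx)
  b3 <- conv_bwd(p$enc2a, cache$c3$cache, d3); g$enc2a <- b3
  dpl <- pool2_bwd(cache$pl$cache, b3$dx)
  d2 <- lrelu_bwd(cache$a2$cache, dpl + dskip_a2)
  b2 <- conv_bwd(p$enc1b, cache$c2$cache, d2); g$enc1b <- b2
  d1 <- lrelu_bwd(cache$a1$cache, b2$dx)
  b1 <- conv_bwd(p$enc1a, cache$c1$cache, d1); g$enc1a <- b1
  list(grads = lapply(g, function(z) list(dK = z$dK, db = z$db)), dx = b1$dx)
}

#' Wrap generator parameters as a prediction function
#' @param params a [unet_init()] parameter set
#' @return function mapping an h x w x c array to the generated stain array
#' @export
make_generator <- function(params) {
  force(params)
  function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    unet_fwd(params, x)$y
  }
}

# ---- discriminators -----------------------------------------------------

disc_init <- function(in_channels, base_filters = 8L, seed = 1L) {
  set.seed(check_seed(seed))
  f <- base_filters
  structure(list(c1 = conv_param(in_channels, f),
                 c2 = conv_param(f, 2L * f),
                 head = conv_param(2L * f, 1L, k = 1L)),
            class = "disc_params", in_channels = in_channels)
}

disc_fwd <- function(p, x) {
  c1 <- conv_fwd(p$c1, x); a1 <- lrelu_fwd(c1$y)
  p1 <- pool2_fwd(a1$y)
  c2 <- conv_fwd(p$c2, p1$y); a2 <- lrelu_fwd(c2$y)
  p2 <- pool2_fwd(a2$y)
  hd <- conv_fwd(p$head, p2$y)
  z <- mean(hd$y)
  list(prob = sigmoid(z), z = z,
       cache = list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
                    hd = hd, nout = length(hd$y)))
}

disc_bwd <- function(p, cache, dprob_z) {
  # dprob_z = dLoss/dz at the scalar logit (caller applies sigmoid algebra)
  dy <- array(dprob_z / cache$nout, dim(cache$hd$y))
  bh <- conv_bwd(p$head, cache$hd$cache, dy)
  dp2 <- pool2_bwd(cache$p2$cache, bh$dx)
  d2 <- lrelu_bwd(cache$a2$cache, dp2)
  b2 <- conv_bwd(p$c2, cache$c2$cache, d2)
  dp1 <- pool2_bwd(cache$p1$cache, b2$dx)
  d1 <- lrelu_bwd(cache$a1$cache, dp1)
  b1 <- conv_bwd(p$c1, cache$c1$cache, d1)
  list(grads = list(c1 = list(dK = b1$dK, db = b1$db),
                    c2 = list(dK = b2$dK, db = b2$db),
                    head = list(dK = bh$dK, db = bh$db)),
       dx = b1$dx)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(mK = p$K * 0, vK = p$K * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (nm in names(grads)) {
    gK <- grads[[nm]]$dK + 2 * weight_decay * params[[nm]]$K
    gb <- grads[[nm]]$db
    st <- state[[nm]]
    st$mK <- beta1 * st$mK + (1 - beta1) * gK
    st$vK <- beta2 * st$vK + (1 - beta2) * gK^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    mKh <- st$mK / (1 - beta1^t); vKh <- st$vK / (1 - beta2^t)
    mbh <- st$mb / (1 - beta1^t); vbh <- st$vb / (1 - beta2^t)
    params[[nm]]$K <- params[[nm]]$K - lr * mKh / (sqrt(vKh) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mbh / (sqrt(vbh) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

param_sq_norm <- function(params) {
  sum(vapply(params, function(p) sum(p$K^2) + sum(p$b^2), numeric(1)))
}
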