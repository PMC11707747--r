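test_that("backprop through the U-Net matches finite differences", {
  set.seed(3)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  tgt <- array(runif(20 * 20 * 1), c(20, 20, 1))
  p <- virtustain:::unet_init(2L, 1L, 4L, seed = 5)
  lossfun <- function(pp) {
    y <- virtustain:::unet_fwd(pp, x)$y
    as.numeric(shift_invariant_loss(y, tgt))
  }
  fw <- virtustain:::unet_fwd(p, x)
  sg <- virtustain:::shift_invariant_grad(fw$y, tgt)
  bw <- virtustain:::unet_bwd(p, fw$cache, sg$grad)
  eps <- 1e-6
  set.seed(9)
  for (nm in c("enc1a", "enc2b", "up1", "dec1b", "head")) {
    i <- sample(length(p[[nm]]$K), 1)
    p_plus <- p; p_plus[[nm]]$K[i] <- p_plus[[nm]]$K[i] + eps
    p_minus <- p; p_minus[[nm]]$K[i] <- p_minus[[nm]]$K[i] - eps
    num <- (lossfun(p_plus) - lossfun(p_minus)) / (2 * eps)
    expect_equal(bw$grads[[nm]]$dK[i], num, tolerance = 1e-4)
  }
})

test_that("pure weight decay strictly shrinks the parameter norm", {
  pairs <- list(list(af = array(0.5, c(16, 16, 2)),
                     stain = array(0.5, c(16, 16, 1))))
  cfg <- stainer_config(in_channels = 2L, out_channels = 1L, base_filters = 4L,
                        steps = 10L, batch_size = 1L, lambda_reg = 0,
                        lambda_rot = 0, lambda_l2 = 1e-3, lr = 1e-3,
                        val_every = 10L, seed = 2)
  st <- train(pairs, pairs, cfg)
  n0 <- virtustain:::param_sq_norm(virtustain:::unet_init(2L, 1L, 4L, seed = 2))
  n1 <- virtustain:::param_sq_norm(st$generator)
  expect_lt(n1, n0)
})

test_that("checkpoint selection minimizes the rank-sum with earlier-step ties", {
  cks <- list(list(step = 100L, params = NULL, val_l1 = 0.10, val_fd = 0.90),
              list(step = 200L, params = NULL, val_l1 = 0.90, val_fd = 0.10),
              list(step = 300L, params = NULL, val_l1 = 0.20, val_fd = 0.20),
              list(step = 400L, params = NULL, val_l1 = 0.50, val_fd = 0.50))
  # A best L1 (rank 1 + 4), B best FD (4 + 1), C second in both (2 + 2):
  # C has the strictly best rank-sum
  expect_equal(select_checkpoint(cks), 300L)
  one <- list(list(step = 50L, params = NULL, val_l1 = 1, val_fd = 1))
  expect_equal(select_checkpoint(one), 50L)
  dom <- list(list(step = 10L, params = NULL, val_l1 = 0.1, val_fd = 0.1),
              list(step = 20L, params = NULL, val_l1 = 0.2, val_fd = 0.2))
  expect_equal(select_checkpoint(dom), 10L)
  tie <- list(list(step = 10L, params = NULL, val_l1 = 0.1, val_fd = 0.1),
              list(step = 20L, params = NULL, val_l1 = 0.1, val_fd = 0.1))
  expect_equal(select_checkpoint(tie), 10L)
  expect_error(select_checkpoint(list()), "checkpoint")
})

test_that("tiled inference has no seams and matches single-pass in degenerate tiling", {
  # pointwise generator on a constant image: output must be constant
  pointwise <- function(x) {
    out <- array(0, c(dim(x)[1], dim(x)[2], 1L))
    out[, , 1] <- 0.3 * x[, , 1] + 0.1
    out
  }
  wsi <- array(0.5, c(96, 96, 1))
  pred <- predict_wsi(wsi, pointwise, tile_px = 32L, overlap_px = 8L)
  expect_equal(max(pred) - min(pred), 0)
  expect_equal(dim(pred)[1:2], c(96L, 96L))
  # tile >= image: identical to a single pass
  set.seed(6)
  wsi2 <- array(runif(64 * 64 * 2), c(64, 64, 2))
  p <- virtustain:::unet_init(2L, 1L, 4L, seed = 3)
  gen <- make_generator(p)
  single <- gen(wsi2)
  tiled <- predict_wsi(wsi2, gen, tile_px = 64L, overlap_px = 0L)
  expect_equal(tiled, single, tolerance = 1e-12)
  # two tilings agree in the interior within blend tolerance
  t1 <- predict_wsi(wsi2, gen, tile_px = 32L, overlap_px = 8L)
  t2 <- predict_wsi(wsi2, gen, tile_px = 48L, overlap_px = 16L)
  interior <- 17:48
  expect_lt(max(abs(t1[interior, interior, 1] - t2[interior, interior, 1])), 0.05)
})

test_that("a short training run is bitwise deterministic and NaNs abort", {
  pairs <- tiny_pairs(n = 6, af_size = 32L, pad = 4L, seed = 19)
  cfg <- stainer_config(in_channels = 20L, out_channels = 3L, base_filters = 4L,
                        steps = 8L, batch_size = 2L, val_every = 4L, seed = 19)
  s1 <- train(pairs[1:4], pairs[5:6], cfg)
  s2 <- train(pairs[1:4], pairs[5:6], cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$generator, s2$generator)
  # an absurd learning rate overflows the weight-decay term to Inf
  bad <- stainer_config(in_channels = 20L, out_channels = 3L, base_filters = 4L,
                        steps = 5L, batch_size = 2L, lr = 1e200,
                        lambda_l2 = 1e-3, val_every = 5L, seed = 19)
  expect_error(train(pairs[1:4], pairs[5:6], bad), "NaN|Inf")
})

test_that("schedules change the effective rates over steps", {
  pairs <- tiny_pairs(n = 4, af_size = 32L, pad = 4L, seed = 23)
  lr_sched <- function(step) if (step <= 2) 1e-3 else 1e-4
  cfg <- stainer_config(in_channels = 20L, out_channels = 3L, base_filters = 4L,
                        steps = 4L, batch_size = 2L, lr = lr_sched,
                        val_every = 4L, seed = 23)
  st <- train(pairs[1:3], pairs[4], cfg)
  expect_equal(nrow(st$history), 5L)  # step 0 + 4 steps
  expect_true(all(is.finite(st$history$loss[-1])))
})

test_that("adversarial training steps run and log both sides of the minimax game", {
  pairs <- tiny_pairs(n = 4, af_size = 32L, pad = 4L, seed = 29)
  cfg <- stainer_config(in_channels = 20L, out_channels = 3L, base_filters = 4L,
                        steps = 3L, batch_size = 1L, lambda_cond_adv = 0.1,
                        lambda_uncond_adv = 0.1, val_every = 3L, seed = 29)
  st <- train(pairs[1:3], pairs[4], cfg)
  h <- st$history[-1, ]
  expect_true(all(is.finite(h$g_adv)))
  expect_true(all(is.finite(h$d_adv)))
  expect_true(all(h$g_adv > 0))
})
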