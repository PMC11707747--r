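test_that("pixel weighting obeys the floor, the CD8 clamp, and the ceiling", {
  sch <- weighting_scheme(imax = 255)
  expect_equal(pixel_weight(1, sch), 1)                   # log 1 = 0, floored
  expect_equal(pixel_weight(0, sch), 1)
  cd8 <- cd8_weighting_scheme(imax = 255)
  expect_equal(pixel_weight(10, cd8), 1)                  # below the clamp at 15
  expect_equal(pixel_weight(14.999, cd8), 1)
  expect_equal(pixel_weight(15, cd8), max(1, log(15)))    # clamp is strict (< 15)
  # constant at and beyond imax
  expect_equal(pixel_weight(255, sch), log(255))
  expect_equal(pixel_weight(2550, sch), log(255))
  # monotone non-decreasing, always >= 1
  i <- seq(0, 400, by = 0.5)
  w <- pixel_weight(i, sch)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w >= 1))
  # vectorized evaluation equals the scalar loop
  set.seed(1)
  grid <- matrix(runif(400, 0, 300), 20, 20)
  wv <- pixel_weight(grid, cd8)
  ws <- apply(grid, c(1, 2), function(x) pixel_weight(x, cd8))
  expect_equal(wv, ws)
  # log10 switch
  sch10 <- weighting_scheme(imax = 1000, log_base = "10")
  expect_equal(pixel_weight(1000, sch10), 3)
  expect_error(weighting_scheme(imax = 1), "imax")
})

test_that("shift-invariant loss is zero at the true offset and recovers it", {
  set.seed(2)
  target <- array(runif(160 * 160 * 2), c(160, 160, 2))
  pred <- target[17:144, 17:144, , drop = FALSE]  # centre crop
  l0 <- shift_invariant_loss(pred, target)
  expect_equal(as.numeric(l0), 0)
  expect_equal(attr(l0, "offset"), c(16L, 16L))
  # off-centre crop: loss 0, offset recovered
  pred2 <- target[17:144, 5:132, , drop = FALSE]  # dx = 4, dy = 16
  l2 <- shift_invariant_loss(pred2, target)
  expect_equal(as.numeric(l2), 0)
  expect_equal(attr(l2, "offset"), c(4L, 16L))
  # uniform weights equal no weights (normalization)
  wts <- matrix(5, 160, 160)
  expect_equal(as.numeric(shift_invariant_loss(pred2, target, wts)),
               as.numeric(shift_invariant_loss(pred2, target)))
  expect_error(shift_invariant_loss(array(0, c(64, 64, 1)),
                                    array(0, c(80, 80, 2))), "channel")
})

test_that("shift-invariant loss never exceeds the fixed-centre loss", {
  set.seed(3)
  for (rep in 1:5) {
    target <- array(runif(48 * 48), c(48, 48, 1))
    pred <- array(runif(32 * 32), c(32, 32, 1))
    si <- as.numeric(shift_invariant_loss(pred, target))
    centre <- target[9:40, 9:40, , drop = FALSE]
    fixed <- mean(abs(pred - centre)) + mean((pred - centre)^2)
    expect_lte(si, fixed + 1e-12)
  }
})

test_that("nonuniform pixel weights change the loss in the expected direction", {
  # zero padding: a single fixed offset, so the weight at the wrong pixel acts
  target <- array(0, c(12, 12, 1))
  pred <- array(0, c(12, 12, 1))
  pred[5, 5, 1] <- 1    # a single wrong pixel
  wts <- matrix(1, 12, 12)
  base <- as.numeric(shift_invariant_loss(pred, target, wts))
  wts2 <- wts; wts2[5, 5] <- 10   # up-weight the wrong pixel's location
  up <- as.numeric(shift_invariant_loss(pred, target, wts2))
  expect_gt(up, base)
  wts3 <- wts; wts3[5, 5] <- 0.1  # down-weight it
  down <- as.numeric(shift_invariant_loss(pred, target, wts3))
  expect_lt(down, base)
})

test_that("rotational consistency is zero for pointwise models and positive for oriented ones", {
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  pointwise <- function(z) z * 0.5 + 0.1
  expect_equal(rotational_consistency_loss(pointwise, x), 0)
  for (k in 1:3) expect_equal(rotational_consistency_loss(pointwise, x, k = k), 0)
  oriented <- function(z) {
    out <- z
    out[, , 1] <- matrix(rep(seq(0, 1, length.out = 16), 16), 16, 16)
    out
  }
  expect_gt(rotational_consistency_loss(oriented, x), 0.1)
  expect_error(rotational_consistency_loss(pointwise, array(0, c(8, 10, 1))),
               "square")
})

test_that("adversarial losses match the closed form for chance and confident discriminators", {
  af <- array(0, c(16, 16, 2))
  real <- array(runif(16 * 16), c(16, 16, 1))
  fake <- array(runif(16 * 16), c(16, 16, 1))
  chance <- list(function(x) 0.5, function(x) 0.5, function(x) 0.5)
  l <- adversarial_losses(chance, af, real, fake)
  expect_equal(l$d_adv, 3 * 2 * log(2), tolerance = 1e-12)
  expect_equal(l$g_adv, 3 * log(2), tolerance = 1e-12)
  # perfect discriminator on disjoint supports: d -> 0, g large
  real2 <- array(0, c(16, 16, 1)); real2[1:8, , 1] <- 1    # support: top half
  fake2 <- array(0, c(16, 16, 1)); fake2[9:16, , 1] <- 1   # support: bottom half
  tell <- function(x) {
    st <- x[, , dim(x)[3], drop = FALSE]                   # stain channel
    if (mean(st[seq_len(dim(st)[1] / 2), , 1]) > mean(st[-seq_len(dim(st)[1] / 2), , 1]))
      1 - 1e-9 else 1e-9
  }
  lp <- adversarial_losses(list(tell, tell, tell), af, real2, fake2)
  expect_lt(lp$d_adv, 1e-7)
  expect_gt(lp$g_adv, 3 * log(1e8))
  # zero branch weight removes that branch exactly
  l2 <- adversarial_losses(chance, af, real, fake, branch_weights = c(1, 0, 0))
  expect_equal(l2$d_adv, 2 * log(2), tolerance = 1e-12)
  expect_equal(l2$g_adv, log(2), tolerance = 1e-12)
  expect_error(adversarial_losses(chance[1:2], af, real, fake), "three")
})

test_that("Frechet distance matches the Gaussian closed form and is symmetric", {
  set.seed(4)
  x <- matrix(rnorm(500), ncol = 1)
  expect_equal(frechet_feature_distance(x, x), 0, tolerance = 1e-10)
  y <- matrix(rnorm(500, mean = 2), ncol = 1)
  d <- frechet_feature_distance(x, y)
  expect_equal(d, frechet_feature_distance(y, x), tolerance = 1e-10)
  # equal unit variances: distance ~ (mu1 - mu2)^2 = 4
  expect_equal(d, 4, tolerance = 0.5)
  # multivariate sanity against the closed form with known moments
  set.seed(5)
  X <- matrix(rnorm(4000), ncol = 2)
  Y <- matrix(rnorm(4000), ncol = 2) %*% chol(matrix(c(2, 0, 0, 2), 2)) +
    matrix(rep(c(1, -1), each = 2000), ncol = 2)
  d2 <- frechet_feature_distance(X, Y)
  closed <- 2 + (1 + 2 - 2 * sqrt(2)) * 2   # |mu|^2 + tr(I + 2I - 2 sqrt(2) I)
  expect_equal(d2, closed, tolerance = 0.25)
  expect_error(frechet_feature_distance(x[1, , drop = FALSE], y), "at least 2")
})
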