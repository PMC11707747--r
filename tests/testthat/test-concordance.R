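test_that("Dice matches hand counts and handles empty masks by convention", {
  a <- matrix(FALSE, 5, 5); a[1, 1:6 %% 5 + 1] <- TRUE
  m1 <- matrix(FALSE, 4, 4); m1[1:6] <- TRUE            # |a| = 6
  m2 <- matrix(FALSE, 4, 4); m2[c(1:3, 8)] <- TRUE      # |b| = 4, overlap 3
  expect_equal(dice_score(m1, m2), 0.6)
  expect_equal(dice_score(m1, m1), 1.0)
  disj <- matrix(FALSE, 4, 4); disj[10:12] <- TRUE
  expect_equal(dice_score(m1, disj), 0)
  expect_message(d <- dice_score(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)),
                 "empty")
  expect_equal(d, 1.0)
  expect_error(dice_score(m1, matrix(FALSE, 5, 5)), "shape")
  # symmetry and monotonicity under growing overlap at fixed sizes
  expect_equal(dice_score(m2, m1), dice_score(m1, m2))
  m3 <- matrix(FALSE, 4, 4); m3[c(1:4)] <- TRUE         # overlap 4 of |b| = 4
  expect_gt(dice_score(m1, m3), dice_score(m1, m2))
})

test_that("combined-tumor merging conserves pixel mass and commutes with Dice", {
  set.seed(61)
  cats <- histology_categories()
  r1 <- label_map(matrix(sample(1:9, 400, replace = TRUE), 20, 20))
  r2 <- label_map(matrix(sample(1:9, 400, replace = TRUE), 20, 20))
  m1 <- merge_combined_tumor(r1)
  expect_equal(sum(unclass(m1) == 1), sum(unclass(r1) %in% 1:6))
  expect_equal(sum(unclass(m1) == 3), sum(unclass(r1) == 8))
  expect_equal(length(m1), length(r1))
  # Dice on combined tumor equals Dice of the unions of subtype masks
  m2 <- merge_combined_tumor(r2)
  d_merged <- dice_score(unclass(m1) == 1, unclass(m2) == 1)
  d_union <- dice_score(matrix(unclass(r1) %in% 1:6, 20, 20),
                        matrix(unclass(r2) %in% 1:6, 20, 20))
  expect_equal(d_merged, d_union)
  # non-tumor pixels keep their categories
  expect_true(all((unclass(r1) == 7) == (unclass(m1) == 2)))
  expect_error(label_map(matrix(10, 2, 2)), "outside")
})

test_that("the 5% subtype-prevalence rule is strict and excludes zero-tumor cases", {
  cases <- tibble::tibble(
    case = rep(1:4, each = 2),
    subtype = rep(c("acinar", "solid"), 4),
    area = c(4, 96,      # case 1: 4% acinar -> excluded
             5.1, 94.9,  # case 2: 5.1% -> included
             5, 95,      # case 3: exactly 5% -> excluded (strict)
             0, 0))      # case 4: zero tumor -> warned, excluded
  expect_warning(keep <- luad5_subset(cases, "acinar"), "zero tumor")
  expect_equal(keep, 2L)
  # toy cohort: 4 cases at 1%, 6 at 10% -> subset of 6
  cohort <- tibble::tibble(case = 1:10, subtype = "solid",
                           area = c(rep(1, 4), rep(10, 6)))
  cohort2 <- dplyr::bind_rows(cohort,
                              tibble::tibble(case = 1:10, subtype = "acinar",
                                             area = 100 - cohort$area))
  expect_equal(sort(luad5_subset(cohort2, "solid")), 5:10)
  expect_error(luad5_subset(cases, "necrosis"), "not a tumor subtype")
})

test_that("Pearson CI matches the direct formula and the Fisher-z oracle", {
  # fixed 6-point toy table: r from the covariance formula to 1e-12
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0, 0.7)
  y <- c(2.0, 3.9, 2.1, 6.2, 3.8, 1.1)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ci <- pearson_ci(x, y)
  expect_equal(ci$r, r_direct, tolerance = 1e-12)
  # independent oracle: stats::cor.test uses the same Fisher-z interval
  ct <- cor.test(x, y)
  expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(ct$conf.int), tolerance = 1e-9)
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_ci(x, -x)$r, -1.0)
  expect_error(pearson_ci(x, rep(1, 6)), "zero variance")
  expect_error(pearson_ci(1:3, 1:3), "length")
})

test_that("paired summaries separate bias from correlation and ignore case order", {
  set.seed(67)
  base <- tidyr::expand_grid(case = 1:8, roi = "tissue",
                             measure = c("cell_density", "tps_percent"),
                             marker = "PD-L1")
  base$value <- runif(nrow(base), 10, 90)
  # identical inputs: r = 1, |diff| = 0
  s_id <- paired_summary(base, base)
  expect_true(all(s_id$r == 1))
  expect_true(all(s_id$mean_abs_diff == 0))
  # constant bias: r = 1, |diff| = bias
  biased <- dplyr::mutate(base, value = value + 5)
  s_b <- paired_summary(base, biased)
  expect_true(all(abs(s_b$r - 1) < 1e-12))
  expect_true(all(abs(s_b$mean_abs_diff - 5) < 1e-12))
  # shuffling case order changes nothing
  shuf <- biased[sample(nrow(biased)), ]
  expect_equal(paired_summary(base, shuf), s_b)
  # undefined entries are dropped pairwise with counts
  holey <- biased; holey$value[1] <- NA
  s_h <- paired_summary(base, holey)
  expect_equal(sum(s_h$n_dropped), 1L)
  expect_error(paired_summary(base[0, ], biased[0, ]), "pairs")
})

test_that("correlation degrades monotonically with injected measurement noise", {
  set.seed(71)
  truth <- tibble::tibble(case = 1:12, roi = "tissue", measure = "cell_density",
                          marker = "CD3", value = runif(12, 100, 1000))
  rs <- vapply(c(0, 50, 400), function(s) {
    noisy <- dplyr::mutate(truth, value = value + rnorm(12, 0, s))
    paired_summary(truth, noisy)$r
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("per-case Dice summaries report mean, SD and median", {
  d <- tibble::tibble(case = rep(1:3, each = 2),
                      category = rep(c("combined_tumor", "other"), 3),
                      dice = c(0.9, 0.8, 0.7, 0.6, 0.8, 0.7))
  s <- dice_summary(d)
  expect_equal(s$dice_mean[s$category == "combined_tumor"], 0.8)
  expect_equal(s$dice_median[s$category == "other"], 0.7)
  expect_equal(s$n_cases, c(3L, 3L))
})
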