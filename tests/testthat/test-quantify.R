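test_that("blank DAPI yields an empty cell table, not an error", {
  tab <- segment_cells(matrix(0, 64, 64), pixel_size_um = 0.25)
  expect_equal(nrow(tab), 0)
  expect_true(all(attr(tab, "labels") == 0))
})

test_that("well-separated nuclei are each segmented once, with correct areas", {
  ph <- make_phantom(phantom_config(width_px = 384, height_px = 384,
                                    n_tumor = 0, n_t_cell = 0, n_cytotoxic = 0,
                                    n_other = 40, seed = 41))
  mif <- render_mif(ph, noiseless_render_config(41))
  cells <- segment_cells(mif)
  expect_equal(nrow(cells), 40)
  expect_true(all(cells$area_um2 > 0))
  expect_equal(cells$area_um2, cells$area_px * 0.25^2)
})

test_that("two touching nuclei are split into two cells", {
  dapi <- matrix(0, 64, 64)
  for (c0 in list(c(28, 32), c(40, 32))) {   # centres 12 px apart, radius 8
    r2 <- outer((1:64 - c0[2])^2, rep(1, 64)) + outer(rep(1, 64), (1:64 - c0[1])^2)
    dapi <- dapi + 100 * exp(-r2 / (2 * 25)) * (r2 <= 64)
  }
  merged <- segment_cells(dapi, split = FALSE)
  expect_equal(nrow(merged), 1)   # without marker-controlled splitting they merge
  split <- segment_cells(dapi, split = TRUE)
  expect_equal(nrow(split), 2)
})

test_that("tumor segmentation recovers the phantom mask and is scale-invariant", {
  expect_false(any(segment_tumor(matrix(0, 64, 64))))
  ph <- small_phantom(43, width_px = 256, height_px = 256, n_tumor = 25,
                      n_t_cell = 10, n_cytotoxic = 5, n_other = 5)
  mif <- render_mif(ph, noiseless_render_config(43))
  panck <- get_channel(mif, "PanCK")
  m <- segment_tumor(panck)
  iou <- sum(m & ph$tumor_mask) / sum(m | ph$tumor_mask)
  expect_gt(iou, 0.9)
  expect_identical(segment_tumor(panck * 2), m)
})

test_that("positivity classification follows the mean-intensity threshold exactly", {
  ph <- make_phantom(phantom_config(width_px = 384, height_px = 384,
                                    n_tumor = 0, n_t_cell = 30, n_cytotoxic = 10,
                                    n_other = 0, pdl1_immune_frac = 0,
                                    seed = 47))
  mif <- render_mif(ph, noiseless_render_config(47))
  cells <- segment_cells(mif)
  cd3 <- classify_positive(cells, get_channel(mif, "CD3"), threshold = 20, "CD3")
  cd8 <- classify_positive(cd3, get_channel(mif, "CD8"), threshold = 20, "CD8")
  expect_equal(sum(cd8$pos_CD3), 30)
  expect_equal(sum(cd8$pos_CD8), 10)
  # trivial thresholds
  all_pos <- classify_positive(cells, get_channel(mif, "CD3"), threshold = 0, "CD3")
  expect_true(all(all_pos$pos_CD3))
  none <- classify_positive(cells, get_channel(mif, "CD3"),
                            threshold = max(get_channel(mif, "CD3")) + 1, "CD3")
  expect_false(any(none$pos_CD3))
  expect_error(classify_positive(cells, matrix(0, 4, 4), 1, "CD3"), "mismatch")
})

test_that("TPS and CPS match hand counts, with CPS adding immune cells", {
  # 10 tumor cells, 3 PD-L1+ tumor, 0 PD-L1+ immune: TPS = CPS = 30
  t1 <- toy_cell_table(n_tumor = 10, n_tumor_pdl1 = 3, n_immune_pdl1 = 0)
  m1 <- measure_roi(t1, full_mask(), full_mask(), roi = "tissue",
                    pixel_size_um = 1)
  expect_equal(m1$value[m1$measure == "tps_percent"], 30)
  expect_equal(m1$value[m1$measure == "cps_percent"], 30)
  # adding 2 PD-L1+ immune cells: TPS unchanged, CPS = 50
  t2 <- toy_cell_table(n_tumor = 10, n_tumor_pdl1 = 3, n_immune_pdl1 = 2)
  m2 <- measure_roi(t2, full_mask(), full_mask(), roi = "tissue",
                    pixel_size_um = 1)
  expect_equal(m2$value[m2$measure == "tps_percent"], 30)
  expect_equal(m2$value[m2$measure == "cps_percent"], 50)
  # CPS caps at 100
  t3 <- toy_cell_table(n_tumor = 2, n_tumor_pdl1 = 2, n_immune_pdl1 = 8)
  m3 <- measure_roi(t3, full_mask(), full_mask(), roi = "tissue",
                    pixel_size_um = 1)
  expect_equal(m3$value[m3$measure == "cps_percent"], 100)
})

test_that("zero tumor cells gives explicit NA TPS/CPS and empty ROIs give NA percentages", {
  t0 <- toy_cell_table(n_tumor = 0, n_tumor_pdl1 = 0, n_immune_pdl1 = 3)
  m0 <- measure_roi(t0, matrix(FALSE, 100, 100), full_mask(), roi = "tissue",
                    pixel_size_um = 1)
  expect_true(is.na(m0$value[m0$measure == "tps_percent"]))
  expect_match(m0$note[m0$measure == "tps_percent"], "no tumor cells")
  empty_roi <- matrix(FALSE, 100, 100)
  me <- measure_roi(t0, matrix(FALSE, 100, 100), full_mask(), roi = "tissue",
                    roi_mask = empty_roi, pixel_size_um = 1)
  expect_true(all(is.na(me$value[me$measure == "positive_percentage"])))
  expect_true(all(me$value[me$measure == "cell_density"] == 0))
})

test_that("colocalization equals ground truth and respects set inclusion", {
  ph <- make_phantom(phantom_config(width_px = 384, height_px = 384,
                                    n_tumor = 0, n_t_cell = 20, n_cytotoxic = 10,
                                    n_other = 5, seed = 53))
  mif <- render_mif(ph, noiseless_render_config(53))
  cells <- segment_cells(mif)
  cells <- classify_positive(cells, get_channel(mif, "PD-L1"), 20, "PD-L1")
  cells <- classify_positive(cells, get_channel(mif, "CD3"), 20, "CD3")
  cells <- classify_positive(cells, get_channel(mif, "CD8"), 20, "CD8")
  cc <- colocalization_counts(cells)
  expect_equal(cc$count[cc$pair == "CD3&CD8"], 10)
  expect_lte(cc$count[cc$pair == "CD3&CD8"], min(sum(cells$pos_CD3), sum(cells$pos_CD8)))
  expect_lte(cc$count[cc$pair == "CD3&PD-L1"], min(sum(cells$pos_CD3), sum(cells$pos_PDL1)))
  expect_error(colocalization_counts(cells, pairs = list(c("CD3", "FOXP3"))),
               "unknown")
})

test_that("raising the CD8 nonspecific background inflates CD8 calls more than colocalized calls", {
  ph <- small_phantom(59, width_px = 320, height_px = 320, n_tumor = 15,
                      n_t_cell = 20, n_cytotoxic = 8, n_other = 10)
  count_cd8 <- function(amp) {
    rc <- render_config(seed = 59, noise_sd = 0, cd8_nonspecific_amplitude = amp)
    mif <- render_mif(ph, rc)
    cells <- segment_cells(mif)
    cells <- classify_positive(cells, get_channel(mif, "CD3"), 20, "CD3")
    cells <- classify_positive(cells, get_channel(mif, "CD8"), 20, "CD8")
    c(cd8 = sum(cells$pos_CD8), coloc = sum(cells$pos_CD3 & cells$pos_CD8))
  }
  clean <- count_cd8(0)
  noisy <- count_cd8(80)   # background peaks well above the 20-unit threshold
  expect_gt(noisy["cd8"], clean["cd8"])          # false positives appear
  infl_cd8 <- noisy["cd8"] - clean["cd8"]
  infl_coloc <- abs(noisy["coloc"] - clean["coloc"])
  expect_lte(infl_coloc, infl_cd8)               # colocalization is more robust
})

test_that("densities scale as 1 / pixel_size^2", {
  t1 <- toy_cell_table(n_tumor = 10, n_tumor_pdl1 = 3, n_immune_pdl1 = 2)
  m1 <- measure_roi(t1, full_mask(), full_mask(), roi = "tissue", pixel_size_um = 1)
  attr(t1, "pixel_size_um") <- 2
  m2 <- measure_roi(t1, full_mask(), full_mask(), roi = "tissue", pixel_size_um = 2)
  d1 <- m1$value[m1$measure == "cell_density" & m1$marker == "DAPI"]
  d2 <- m2$value[m2$measure == "cell_density" & m2$marker == "DAPI"]
  expect_equal(d1 / d2, 4)
})
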