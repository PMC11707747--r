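#' Segment cells from the DAPI channel
#'
#' Threshold-based nuclear segmentation: Gaussian smoothing, automatic
#' (Otsu) or fixed thresholding, distance-transform peak markers and
#' watershed splitting of touching nuclei, small-object removal.
#' Deterministic. An empty foreground yields an empty table, not an error.
#'
#' @param dapi DAPI intensity matrix (or [image_bundle()]; its DAPI channel
#'   is used)
#' @param pixel_size_um physical pixel size (taken from the bundle if given)
#' @param sigma smoothing sd in px
#' @param threshold `"otsu"` or a numeric intensity threshold
#' @param min_area_px minimum cell area
#' @param split split touching nuclei by watershed when TRUE
#' @return a `cell_table` tibble (id, x, y, area_um2, area_px) with the
#'   label image in attribute `"labels"` and the pixel size in
#'   `"pixel_size_um"`
#' @export
segment_cells <- function(dapi, pixel_size_um = NULL, sigma = 1.5,
                          threshold = "otsu", min_area_px = 9L, split = TRUE) {
  if (inherits(dapi, "image_bundle")) {
    if (is.null(pixel_size_um)) pixel_size_um <- dapi$pixel_size_um
    dapi <- get_channel(dapi, "DAPI")
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1.0
  if (any(dapi < 0)) vs_abort("DAPI map must be nonnegative")
  s <- blur2d(dapi, sigma)
  thr <- if (identical(threshold, "otsu")) {
    if (diff(range(s)) < 1e-9) Inf else otsu_threshold(as.vector(s))
  } else as.numeric(threshold)
  fg <- s > thr
  fg <- remove_small_objects(fg, min_area_px)
  empty_tab <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                              area_px = numeric(), area_um2 = numeric())
  if (!any(fg)) {
    lab <- matrix(0L, nrow(dapi), ncol(dapi))
    out <- empty_tab
    attr(out, "labels") <- lab
    attr(out, "pixel_size_um") <- pixel_size_um
    class(out) <- c("cell_table", class(out))
    return(out)
  }
  if (split) {
    dm <- EBImage::distmap(fg * 1)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    lab <- EBImage::bwlabel(fg * 1)
  }
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  # drop labels below the minimum area, then relabel contiguously
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  remap <- integer(length(sizes)); remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  n <- length(keep)
  if (n == 0) {
    out <- empty_tab
  } else {
    idx <- which(lab > 0)
    ids <- lab[idx]
    ys <- (idx - 1L) %% nrow(lab) + 1L
    xs <- (idx - 1L) %/% nrow(lab) + 1L
    area_px <- tabulate(ids, n)
    out <- tibble::tibble(id = seq_len(n),
                          x = as.numeric(tapply(xs, ids, mean)),
                          y = as.numeric(tapply(ys, ids, mean)),
                          area_px = as.numeric(area_px),
                          area_um2 = area_px * pixel_size_um^2)
  }
  attr(out, "labels") <- lab
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("cell_table", class(out))
  out
}

#' Segment the tumor region from the PanCK channel
#'
#' Smoothed data-relative (Otsu) threshold, hole filling and small-object
#' removal. Invariant to global intensity scaling.
#'
#' @param panck PanCK intensity matrix or [image_bundle()]
#' @param sigma smoothing sd in px
#' @param min_object_px minimum region size
#' @return logical tumor mask
#' @export
segment_tumor <- function(panck, sigma = 3, min_object_px = 64L) {
  if (inherits(panck, "image_bundle")) panck <- get_channel(panck, "PanCK")
  s <- blur2d(panck, sigma)
  if (diff(range(s)) < 1e-9) return(matrix(FALSE, nrow(panck), ncol(panck)))
  m <- s > otsu_threshold(as.vector(s))
  m <- EBImage::fillHull(m * 1) > 0
  remove_small_objects(matrix(as.logical(m), nrow(panck), ncol(panck)),
                       min_object_px)
}

#' Flag marker-positive cells by mean intensity
#'
#' A cell is positive for a marker when the mean marker intensity over its
#' segmented pixels is at or above the threshold. Adds `mean_<marker>` and
#' `pos_<marker>` columns.
#'
#' @param cells a `cell_table` from [segment_cells()]
#' @param marker_map marker intensity matrix, same shape as the DAPI map
#' @param threshold positivity threshold (explicit config value, no
#'   auto-tuning)
#' @param marker marker name, e.g. `"CD3"`
#' @return the augmented `cell_table`
#' @export
classify_positive <- function(cells, marker_map, threshold, marker) {
  stopifnot(inherits(cells, "cell_table"))
  lab <- attr(cells, "labels")
  if (!all(dim(marker_map) == dim(lab))) vs_abort("marker map shape mismatch")
  mcol <- paste0("mean_", gsub("-", "", marker))
  pcol <- paste0("pos_", gsub("-", "", marker))
  if (nrow(cells) == 0) {
    cells[[mcol]] <- numeric(); cells[[pcol]] <- logical()
    return(cells)
  }
  idx <- which(lab > 0)
  mm <- as.numeric(tapply(marker_map[idx], lab[idx], mean))
  at <- attributes(cells)
  cells[[mcol]] <- mm
  cells[[pcol]] <- mm >= threshold
  attr(cells, "labels") <- at$labels
  attr(cells, "pixel_size_um") <- at$pixel_size_um
  cells
}

#' Mark cells inside the tumor region (by centroid membership)
#' @param cells a `cell_table`
#' @param tumor logical tumor mask
#' @return `cell_table` with an `in_tumor` column
#' @export
assign_in_tumor <- function(cells, tumor) {
  at <- attributes(cells)
  if (nrow(cells) == 0) { cells$in_tumor <- logical() }
  else {
    idx <- cbind(pmin(pmax(round(cells$y), 1), nrow(tumor)),
                 pmin(pmax(round(cells$x), 1), ncol(tumor)))
    cells$in_tumor <- tumor[idx]
  }
  attr(cells, "labels") <- at$labels
  attr(cells, "pixel_size_um") <- at$pixel_size_um
  cells
}

cells_in_mask <- function(cells, mask) {
  if (nrow(cells) == 0) return(cells[0, ])
  idx <- cbind(pmin(pmax(round(cells$y), 1), nrow(mask)),
               pmin(pmax(round(cells$x), 1), ncol(mask)))
  cells[mask[idx], , drop = FALSE]
}

#' Quantify a stained slide over a region of interest
#'
#' Computes the threshold-based measurement suite over one ROI definition:
#' PanCK-positive area (mm^2, tumor mask within the ROI); cell density
#' (cells/mm^2) for DAPI (all cells), PD-L1, CD3, CD8; positive-cell
#' percentage for PD-L1/CD3/CD8 (not DAPI, whose percentage is definitionally
#' 100); TPS = 100 x PD-L1+ tumor cells / tumor cells; CPS = 100 x (PD-L1+
#' tumor + PD-L1+ non-tumor cells) / tumor cells, capped at 100; and
#' CD3&CD8 / CD3&PD-L1 colocalization counts, densities and percentages.
#' TPS/CPS with zero tumor cells in the ROI are explicit `NA` with a note,
#' never silent zeros; percentages in an empty ROI are likewise `NA`.
#'
#' @param cells a `cell_table` with `pos_PDL1`, `pos_CD3`, `pos_CD8` and
#'   `in_tumor` columns
#' @param tumor_mask the slide's own tumor mask (PanCK)
#' @param tissue logical tissue mask
#' @param roi one of `"tissue"`, `"real_tumor"`, `"respective_tumor"`
#' @param roi_mask the resolved ROI mask; defaults to `tissue` for the
#'   tissue ROI and `tumor_mask` otherwise (pass the real-stain tumor mask
#'   here to evaluate a virtual slide inside the real tumor ROI)
#' @param pixel_size_um physical pixel size (taken from `cells` if absent)
#' @return a `measurement_set` tibble: `roi`, `measure`, `marker`, `value`,
#'   `note`
#' @export
measure_roi <- function(cells, tumor_mask, tissue,
                        roi = c("tissue", "real_tumor", "respective_tumor"),
                        roi_mask = NULL, pixel_size_um = NULL) {
  roi <- match.arg(roi)
  stopifnot(inherits(cells, "cell_table"))
  if (!("in_tumor" %in% names(cells))) vs_abort("run `assign_in_tumor()` first")
  for (cl in c("pos_PDL1", "pos_CD3", "pos_CD8")) {
    if (!(cl %in% names(cells))) vs_abort(sprintf("missing column `%s`: run `classify_positive()`", cl))
  }
  if (is.null(pixel_size_um)) pixel_size_um <- attr(cells, "pixel_size_um") %||% 1.0
  if (is.null(roi_mask)) roi_mask <- if (roi == "tissue") tissue else tumor_mask
  px_mm2 <- (pixel_size_um / 1000)^2
  roi_area_mm2 <- sum(roi_mask) * px_mm2
  rc <- cells_in_mask(cells, roi_mask)
  n_cells <- nrow(rc)
  dens <- function(k) if (roi_area_mm2 > 0) k / roi_area_mm2 else 0
  pct <- function(k) if (n_cells > 0) 100 * k / n_cells else NA_real_
  n_pdl1 <- sum(rc$pos_PDL1); n_cd3 <- sum(rc$pos_CD3); n_cd8 <- sum(rc$pos_CD8)
  n_c38 <- sum(rc$pos_CD3 & rc$pos_CD8)
  n_c3p <- sum(rc$pos_CD3 & rc$pos_PDL1)
  n_tum <- sum(rc$in_tumor)
  n_pdl1_tum <- sum(rc$pos_PDL1 & rc$in_tumor)
  n_pdl1_imm <- sum(rc$pos_PDL1 & !rc$in_tumor)
  tps <- if (n_tum > 0) 100 * n_pdl1_tum / n_tum else NA_real_
  cps <- if (n_tum > 0) min(100, 100 * (n_pdl1_tum + n_pdl1_imm) / n_tum) else NA_real_
  no_tumor_note <- if (n_tum == 0) "undefined: no tumor cells in ROI" else NA_character_
  empty_note <- if (n_cells == 0) "undefined: no cells in ROI" else NA_character_
  out <- tibble::tribble(
    ~measure, ~marker, ~value, ~note,
    "positive_area_mm2", "PanCK", sum(tumor_mask & roi_mask) * px_mm2, NA_character_,
    "cell_density", "DAPI", dens(n_cells), NA_character_,
    "cell_density", "PD-L1", dens(n_pdl1), NA_character_,
    "cell_density", "CD3", dens(n_cd3), NA_character_,
    "cell_density", "CD8", dens(n_cd8), NA_character_,
    "positive_percentage", "CD3", pct(n_cd3), empty_note,
    "positive_percentage", "CD8", pct(n_cd8), empty_note,
    "tps_percent", "PD-L1", tps, no_tumor_note,
    "cps_percent", "PD-L1", cps, no_tumor_note,
    "coloc_count", "CD3&CD8", as.numeric(n_c38), NA_character_,
    "coloc_count", "CD3&PD-L1", as.numeric(n_c3p), NA_character_,
    "coloc_density", "CD3&CD8", dens(n_c38), NA_character_,
    "coloc_density", "CD3&PD-L1", dens(n_c3p), NA_character_,
    "coloc_percentage", "CD3&CD8", pct(n_c38), empty_note,
    "coloc_percentage", "CD3&PD-L1", pct(n_c3p), empty_note)
  out <- dplyr::mutate(out, roi = roi, .before = 1)
  class(out) <- c("measurement_set", class(out))
  out
}

#' Colocalization counts for marker pairs
#'
#' A cell counts for a pair iff it is positive for both markers; densities
#' and percentages follow the same conventions as [measure_roi()].
#'
#' @param cells a `cell_table` with positivity flags
#' @param pairs list of 2-vectors from `{"CD3","CD8","PD-L1"}`
#' @param roi_mask optional ROI restriction
#' @param pixel_size_um physical pixel size
#' @return tibble with pair, count, density, percentage
#' @export
colocalization_counts <- function(cells, pairs = list(c("CD3", "CD8"),
                                                      c("CD3", "PD-L1")),
                                  roi_mask = NULL, pixel_size_um = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  if (is.null(pixel_size_um)) pixel_size_um <- attr(cells, "pixel_size_um") %||% 1.0
  rc <- if (is.null(roi_mask)) cells else cells_in_mask(cells, roi_mask)
  area_mm2 <- if (is.null(roi_mask)) NA_real_ else sum(roi_mask) * (pixel_size_um / 1000)^2
  colname <- function(m) paste0("pos_", gsub("-", "", m))
  purrr::map_dfr(pairs, function(pr) {
    cn <- colname(pr)
    if (!all(cn %in% names(rc))) {
      vs_abort(sprintf("unknown marker pair (%s, %s)", pr[1], pr[2]))
    }
    k <- sum(rc[[cn[1]]] & rc[[cn[2]]])
    tibble::tibble(pair = paste(pr, collapse = "&"), count = k,
                   density = if (is.na(area_mm2) || area_mm2 == 0) NA_real_ else k / area_mm2,
                   percentage = if (nrow(rc) > 0) 100 * k / nrow(rc) else NA_real_)
  })
}

#' Full mIF quantification of one slide
#'
#' Convenience pipeline: segment cells (DAPI) and tumor (PanCK), classify
#' positivity for PD-L1/CD3/CD8 at the configured thresholds, and measure
#' the requested ROIs. For the `real_tumor` ROI on a virtual slide pass the
#' real tumor mask via `real_tumor_mask`.
#'
#' @param mif an [image_bundle()] with the 6 mIF channels
#' @param thresholds named positivity thresholds (PD-L1, CD3, CD8)
#' @param rois character subset of the three ROI definitions
#' @param real_tumor_mask optional externally supplied tumor mask used for
#'   the `real_tumor` ROI
#' @param tissue optional tissue mask (computed from the bundle otherwise)
#' @return list: `cells`, `tumor_mask`, `tissue`, `measurements` (bound
#'   measurement tibble)
#' @export
quantify_mif <- function(mif, thresholds = c(`PD-L1` = 20, CD3 = 20, CD8 = 20),
                         rois = c("tissue", "respective_tumor"),
                         real_tumor_mask = NULL, tissue = NULL) {
  stopifnot(inherits(mif, "image_bundle"))
  cells <- segment_cells(mif)
  tum <- segment_tumor(mif)
  if (is.null(tissue)) tissue <- tissue_mask(mif)
  cells <- classify_positive(cells, get_channel(mif, "PD-L1"), thresholds[["PD-L1"]], "PD-L1")
  cells <- classify_positive(cells, get_channel(mif, "CD3"), thresholds[["CD3"]], "CD3")
  cells <- classify_positive(cells, get_channel(mif, "CD8"), thresholds[["CD8"]], "CD8")
  cells <- assign_in_tumor(cells, tum)
  meas <- purrr::map_dfr(rois, function(r) {
    rm <- switch(r, tissue = tissue,
                 real_tumor = real_tumor_mask %||% tum,
                 respective_tumor = tum)
    measure_roi(cells, tum, tissue, roi = r, roi_mask = rm,
                pixel_size_um = mif$pixel_size_um)
  })
  list(cells = cells, tumor_mask = tum, tissue = tissue, measurements = meas)
}
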