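#' Phantom configuration
#'
#' Parameters of the synthetic tissue phantom: field geometry, cell counts
#' per class, nucleus size, and marker-expression levels. The phantom is a
#' two-compartment (nucleus / cytoplasm) cartoon of NSCLC tissue: a blobby
#' tumor region populated by PanCK-expressing tumor cells (a configurable
#' fraction PD-L1 positive), CD3-expressing T cells in the surrounding
#' stroma (a subset of them CD3+CD8+ cytotoxic), and marker-negative
#' "other" cells.
#'
#' @param width_px,height_px field size in pixels (>= 64)
#' @param pixel_size_um physical pixel size, default 0.25 (40x)
#' @param n_tumor,n_t_cell,n_other cell counts; `n_cytotoxic` of the T cells
#'   additionally express CD8
#' @param n_cytotoxic number of CD3+CD8+ cells among the T cells
#' @param pdl1_tumor_frac fraction of tumor cells expressing PD-L1
#' @param pdl1_immune_frac fraction of T cells expressing PD-L1
#' @param nucleus_radius_px mean nucleus radius in pixels
#' @param nucleus_radius_sd sd of nucleus radius
#' @param min_separation_px minimum centre-to-centre distance between nuclei
#' @param tumor_fraction approximate fraction of the field area covered by
#'   the tumor region
#' @param expression_range uniform range for positive marker expression
#' @param max_packing_density maximum allowed total nucleus area / field area
#' @param seed integer seed (mandatory)
#' @return a `phantom_config` list
#' @export
phantom_config <- function(width_px = 512L, height_px = 512L,
                           pixel_size_um = 0.25,
                           n_tumor = 60L, n_t_cell = 30L, n_cytotoxic = 15L,
                           n_other = 20L,
                           pdl1_tumor_frac = 0.3, pdl1_immune_frac = 0.2,
                           nucleus_radius_px = 5, nucleus_radius_sd = 0.8,
                           min_separation_px = NULL,
                           tumor_fraction = 0.25,
                           expression_range = c(40, 120),
                           max_packing_density = 0.4,
                           seed = 1L) {
  if (width_px < 64 || height_px < 64) vs_abort("field must be at least 64 x 64 px")
  if (n_cytotoxic > n_t_cell) vs_abort("`n_cytotoxic` cannot exceed `n_t_cell`")
  if (is.null(min_separation_px)) min_separation_px <- 2.6 * nucleus_radius_px
  cfg <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
              pixel_size_um = pixel_size_um,
              n_tumor = as.integer(n_tumor), n_t_cell = as.integer(n_t_cell),
              n_cytotoxic = as.integer(n_cytotoxic), n_other = as.integer(n_other),
              pdl1_tumor_frac = pdl1_tumor_frac, pdl1_immune_frac = pdl1_immune_frac,
              nucleus_radius_px = nucleus_radius_px,
              nucleus_radius_sd = nucleus_radius_sd,
              min_separation_px = min_separation_px,
              tumor_fraction = tumor_fraction,
              expression_range = expression_range,
              max_packing_density = max_packing_density,
              seed = check_seed(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# blobby simply-connected region: a disk whose radius wobbles with angle
make_blob_mask <- function(h, w, cx, cy, r0, wobble = 0.25, nharm = 4L) {
  th <- atan2(rep(seq_len(h), w) - cy, rep(seq_len(w), each = h) - cx)
  rad <- sqrt((rep(seq_len(w), each = h) - cx)^2 + (rep(seq_len(h), w) - cy)^2)
  amp <- runif(nharm, -wobble, wobble)
  ph <- runif(nharm, 0, 2 * pi)
  rr <- r0 * (1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
    amp[k] * cos(k * th + ph[k]))))
  matrix(rad <= rr, h, w)
}

place_cells <- function(n, allowed_mask, existing, min_sep, max_tries = 200L) {
  # rejection sampling with a hard minimum-separation (Poisson-disk-like)
  h <- nrow(allowed_mask); w <- ncol(allowed_mask)
  ok_idx <- which(allowed_mask)
  if (n > 0 && length(ok_idx) == 0) vs_abort("packing failure: no room for requested cells")
  pts <- existing
  placed <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    done <- FALSE
    for (t in seq_len(max_tries)) {
      j <- ok_idx[sample.int(length(ok_idx), 1L)]
      y <- (j - 1L) %% h + 1L; x <- (j - 1L) %/% h + 1L
      if (nrow(pts) == 0 ||
          min((pts[, 1] - x)^2 + (pts[, 2] - y)^2) >= min_sep^2) {
        pts <- rbind(pts, c(x, y)); placed <- rbind(placed, c(x, y))
        done <- TRUE; break
      }
    }
    if (!done) vs_abort(sprintf(
      "packing failure: could not place cell %d of %d at min separation %.1f px",
      i, n, min_sep))
  }
  list(placed = placed, all = pts)
}

#' Generate a synthetic tissue phantom
#'
#' Deterministic for a fixed seed. Returns the phantom with its full ground
#' truth: a per-nucleus table (centre, radius, class, marker expression),
#' the tumor-region mask, and the tissue mask.
#'
#' @param config a [phantom_config()]
#' @return a `tissue_phantom` object with fields `nuclei` (tibble with
#'   columns id, x, y, radius_px, cell_class, expr_PanCK, expr_PDL1,
#'   expr_CD3, expr_CD8), `tumor_mask`, `tissue_mask`, `width_px`,
#'   `height_px`, `pixel_size_um`, `seed`
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  c0 <- config
  h <- c0$height_px; w <- c0$width_px
  # feasibility: total nucleus area vs field area
  ntot <- c0$n_tumor + c0$n_t_cell + c0$n_other
  dens <- ntot * pi * c0$nucleus_radius_px^2 / (h * w)
  if (dens > c0$max_packing_density) {
    vs_abort(sprintf("packing failure: requested density %.2f exceeds maximum %.2f",
                     dens, c0$max_packing_density))
  }
  set.seed(c0$seed)

  empty <- matrix(FALSE, h, w)
  if (ntot == 0L) {
    nuclei <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                             radius_px = numeric(), cell_class = character(),
                             expr_PanCK = numeric(), expr_PDL1 = numeric(),
                             expr_CD3 = numeric(), expr_CD8 = numeric())
    out <- list(width_px = w, height_px = h, pixel_size_um = c0$pixel_size_um,
                nuclei = nuclei, tumor_mask = empty, tissue_mask = empty,
                seed = c0$seed, config = c0)
    class(out) <- "tissue_phantom"
    return(out)
  }

  # tumor region: blobby disk covering about tumor_fraction of the field
  r0 <- sqrt(c0$tumor_fraction * h * w / pi)
  cx <- runif(1, 0.35 * w, 0.65 * w); cy <- runif(1, 0.35 * h, 0.65 * h)
  tumor_mask <- if (c0$n_tumor > 0) make_blob_mask(h, w, cx, cy, r0) else empty

  margin <- ceiling(c0$nucleus_radius_px + 2)
  inner <- empty
  inner[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
  tumor_allowed <- tumor_mask & inner
  # erode so tumor nuclei sit fully inside the region
  if (any(tumor_allowed)) {
    tumor_allowed <- EBImage::erode(tumor_allowed * 1,
                                    disk_kernel(ceiling(c0$nucleus_radius_px))) > 0
    tumor_allowed <- tumor_allowed & inner
  }
  stroma_allowed <- inner & !EBImage::dilate(tumor_mask * 1,
                                             disk_kernel(ceiling(c0$min_separation_px))) > 0
  stroma_allowed <- inner & !(EBImage::dilate(tumor_mask * 1,
                                              disk_kernel(ceiling(c0$min_separation_px))) > 0)

  pts <- matrix(numeric(0), 0, 2)
  tum <- place_cells(c0$n_tumor, tumor_allowed, pts, c0$min_separation_px)
  pts <- tum$all
  tc <- place_cells(c0$n_t_cell, stroma_allowed, pts, c0$min_separation_px)
  pts <- tc$all
  oth <- place_cells(c0$n_other, stroma_allowed, pts, c0$min_separation_px)

  xy <- rbind(tum$placed, tc$placed, oth$placed)
  cls <- c(rep("tumor", c0$n_tumor), rep("t_cell", c0$n_t_cell),
           rep("other", c0$n_other))
  # mark cytotoxic subset among the T cells (first n_cytotoxic after shuffle)
  if (c0$n_t_cell > 0) {
    t_idx <- which(cls == "t_cell")
    cyt <- sample(t_idx, c0$n_cytotoxic)
    cls[cyt] <- "cytotoxic_t_cell"
  }
  n <- length(cls)
  radius <- pmax(2, rnorm(n, c0$nucleus_radius_px, c0$nucleus_radius_sd))
  rexpr <- function(k) runif(k, c0$expression_range[1], c0$expression_range[2])

  expr_PanCK <- ifelse(cls == "tumor", rexpr(n), 0)
  expr_CD3 <- ifelse(cls %in% c("t_cell", "cytotoxic_t_cell"), rexpr(n), 0)
  expr_CD8 <- ifelse(cls == "cytotoxic_t_cell", rexpr(n), 0)
  pdl1 <- numeric(n)
  tum_i <- which(cls == "tumor")
  if (length(tum_i)) {
    k <- round(c0$pdl1_tumor_frac * length(tum_i))
    if (k > 0) pdl1[sample(tum_i, k)] <- rexpr(k)
  }
  imm_i <- which(cls %in% c("t_cell", "cytotoxic_t_cell"))
  if (length(imm_i)) {
    k <- round(c0$pdl1_immune_frac * length(imm_i))
    if (k > 0) pdl1[sample(imm_i, k)] <- rexpr(k)
  }

  nuclei <- tibble::tibble(id = seq_len(n), x = xy[, 1], y = xy[, 2],
                           radius_px = radius, cell_class = cls,
                           expr_PanCK = expr_PanCK, expr_PDL1 = pdl1,
                           expr_CD3 = expr_CD3, expr_CD8 = expr_CD8)

  # tissue = tumor region plus a dilated neighbourhood of all nuclei, closed
  cellmap <- empty
  cellmap[cbind(pmin(pmax(round(xy[, 2]), 1), h), pmin(pmax(round(xy[, 1]), 1), w))] <- TRUE
  tissue <- (EBImage::dilate(cellmap * 1, disk_kernel(ceiling(3 * c0$nucleus_radius_px))) > 0) |
    tumor_mask
  tissue <- EBImage::closing(tissue * 1, disk_kernel(ceiling(2 * c0$nucleus_radius_px))) > 0

  out <- list(width_px = w, height_px = h, pixel_size_um = c0$pixel_size_um,
              nuclei = nuclei, tumor_mask = tumor_mask,
              tissue_mask = matrix(as.logical(tissue), h, w),
              seed = c0$seed, config = c0)
  class(out) <- "tissue_phantom"
  out
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %d x %d px @ %.3g um/px, %d nuclei\n",
              x$height_px, x$width_px, x$pixel_size_um, nrow(x$nuclei)))
  if (nrow(x$nuclei)) print(table(x$nuclei$cell_class))
  invisible(x)
}

#' Tidy a phantom's ground truth into a tibble
#' @param x a `tissue_phantom`
#' @param ... unused
#' @return the per-nucleus tibble with an `in_tumor` column added
#' @export
tidy.tissue_phantom <- function(x, ...) {
  nuc <- x$nuclei
  if (nrow(nuc) == 0) return(dplyr::mutate(nuc, in_tumor = logical()))
  idx <- cbind(pmin(pmax(round(nuc$y), 1), x$height_px),
               pmin(pmax(round(nuc$x), 1), x$width_px))
  nuc$in_tumor <- x$tumor_mask[idx]
  nuc
}
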