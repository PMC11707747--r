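#' Rendering configuration for the phantom stains
#'
#' Controls the optics and noise of the synthetic renders. The 20-channel
#' autofluorescence spectra are free parameters of the phantom (no
#' quantitative per-tissue AF spectra are established for this cartoon);
#' defaults are smooth Gaussian bumps peaked at different channels per
#' tissue class. CD8 nonspecific background is a smooth low-frequency
#' additive field plus speckle, emulating the background and nonspecific
#' fluorescence seen in real CD8 stains.
#'
#' @param background_af_level flat AF background added to every channel
#' @param cd8_nonspecific_amplitude amplitude of the additive CD8 background
#' @param noise_sd Gaussian read-noise sd (intensity units)
#' @param psf_sigma_px point-spread blur applied to every render
#' @param af_channel_spectra 4 x 20 nonnegative matrix, rows = tissue class
#'   (nuclei, tumor_cytoplasm, stroma, background), columns = AF channels
#' @param mif_background_level constant background of the mIF stain channels
#' @param dapi_level nominal DAPI intensity at a nucleus centre
#' @param residual_af_attenuation residual-AF channel = this x total AF emission
#' @param seed integer seed for the noise draws
#' @return a `render_config` list
#' @export
render_config <- function(background_af_level = 0.05,
                          cd8_nonspecific_amplitude = 8,
                          noise_sd = 1.5,
                          psf_sigma_px = 1,
                          af_channel_spectra = default_af_spectra(),
                          mif_background_level = 2,
                          dapi_level = 100,
                          residual_af_attenuation = 0.2,
                          seed = 1L) {
  stopifnot(background_af_level >= 0, cd8_nonspecific_amplitude >= 0,
            noise_sd >= 0, psf_sigma_px >= 0, mif_background_level >= 0)
  if (!is.matrix(af_channel_spectra) || ncol(af_channel_spectra) != 20L) {
    vs_abort("`af_channel_spectra` must be a matrix with 20 columns")
  }
  if (any(af_channel_spectra < 0) || any(rowSums(af_channel_spectra) <= 0)) {
    vs_abort("AF spectra must be nonnegative with positive row sums")
  }
  structure(list(background_af_level = background_af_level,
                 cd8_nonspecific_amplitude = cd8_nonspecific_amplitude,
                 noise_sd = noise_sd, psf_sigma_px = psf_sigma_px,
                 af_channel_spectra = af_channel_spectra,
                 mif_background_level = mif_background_level,
                 dapi_level = dapi_level,
                 residual_af_attenuation = residual_af_attenuation,
                 seed = check_seed(seed)),
            class = "render_config")
}

#' Default per-class AF emission spectra (4 classes x 20 channels)
#' @return nonnegative matrix with rownames nuclei, tumor_cytoplasm, stroma,
#'   background
#' @export
default_af_spectra <- function() {
  ch <- seq_len(20)
  bump <- function(mu, s, amp) amp * exp(-(ch - mu)^2 / (2 * s^2))
  sp <- rbind(nuclei = bump(4, 2, 1.0),
              tumor_cytoplasm = bump(9, 2.5, 0.9),
              stroma = bump(14, 3, 0.8),
              background = rep(0.05, 20))
  sp
}

# additively paint radial bumps at nuclei; profile peaks at the centre so
# every nucleus centre is a strict local maximum of the painted field
paint_nuclei <- function(h, w, nuc, values, radius_scale = 1,
                         profile = c("gauss", "disk")) {
  profile <- match.arg(profile)
  img <- matrix(0, h, w)
  if (nrow(nuc) == 0) return(img)
  for (i in seq_len(nrow(nuc))) {
    if (values[i] <= 0) next
    r <- nuc$radius_px[i] * radius_scale
    x0 <- nuc$x[i]; y0 <- nuc$y[i]
    xr <- max(1, floor(x0 - 2 * r)):min(w, ceiling(x0 + 2 * r))
    yr <- max(1, floor(y0 - 2 * r)):min(h, ceiling(y0 + 2 * r))
    dx2 <- outer(rep(1, length(yr)), (xr - x0)^2)
    dy2 <- outer((yr - y0)^2, rep(1, length(xr)))
    d2 <- dx2 + dy2
    patch <- if (profile == "gauss") {
      values[i] * exp(-d2 / (2 * (r / 1.6)^2)) * (d2 <= (2 * r)^2)
    } else {
      values[i] * (d2 <= r^2)
    }
    img[yr, xr] <- img[yr, xr] + patch
  }
  img
}

# CD8 nonspecific background: smooth low-frequency field plus speckle
cd8_background_field <- function(h, w, amplitude) {
  if (amplitude <= 0) return(matrix(0, h, w))
  lowfreq <- normalize01(blur2d(matrix(rnorm(h * w), h, w), sigma = min(h, w) / 12))
  speck <- matrix(0, h, w)
  n_speck <- round(0.002 * h * w)
  if (n_speck > 0) {
    idx <- sample.int(h * w, n_speck)
    speck[idx] <- runif(n_speck, 0.5, 1)
    speck <- blur2d(speck, 1)
    if (max(speck) > 0) speck <- speck / max(speck)
  }
  amplitude * (0.7 * lowfreq + 0.3 * speck)
}

#' Render the 6-channel mIF image of a phantom
#'
#' Channels: DAPI, PanCK, PD-L1, CD3, CD8, residualAF. DAPI is painted as a
#' radial bump per nucleus (every nucleus centre is a local maximum); PanCK
#' covers the tumor region plus tumor-cell bodies; PD-L1/CD3/CD8 are painted
#' on the expressing cells' bodies; the CD8 channel additionally receives
#' the nonspecific background field; residualAF is an attenuated copy of the
#' total AF emission.
#'
#' @param phantom a [make_phantom()] result
#' @param config a [render_config()]
#' @return an [image_bundle()] with 6 named channels
#' @export
render_mif <- function(phantom, config = render_config()) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(config, "render_config"))
  h <- phantom$height_px; w <- phantom$width_px
  set.seed(config$seed)
  nuc <- phantom$nuclei

  dapi <- paint_nuclei(h, w, nuc, rep(config$dapi_level, nrow(nuc)))
  panck <- matrix(0, h, w)
  if (any(nuc$cell_class == "tumor")) {
    base <- 0.6 * mean(nuc$expr_PanCK[nuc$cell_class == "tumor"])
    panck <- phantom$tumor_mask * base +
      paint_nuclei(h, w, nuc, 0.4 * nuc$expr_PanCK, radius_scale = 1.6, profile = "disk")
  }
  pdl1 <- paint_nuclei(h, w, nuc, nuc$expr_PDL1, radius_scale = 1.6, profile = "disk")
  cd3 <- paint_nuclei(h, w, nuc, nuc$expr_CD3, radius_scale = 1.4, profile = "disk")
  cd8 <- paint_nuclei(h, w, nuc, nuc$expr_CD8, radius_scale = 1.4, profile = "disk")

  # residual AF derives from the (noiseless) AF emission
  emission <- af_emission_total(phantom, config)
  raf <- config$residual_af_attenuation * emission

  chans <- list(dapi, panck, pdl1, cd3, cd8)
  # FFT-backed blur can leave O(1e-16) negative ripple; intensities are >= 0
  chans <- lapply(chans, function(m) pmax(blur2d(m, config$psf_sigma_px), 0))
  chans <- lapply(chans, function(m) m + config$mif_background_level)
  chans[[5]] <- chans[[5]] + cd8_background_field(h, w, config$cd8_nonspecific_amplitude)
  chans[[6]] <- raf
  if (config$noise_sd > 0) {
    chans <- lapply(chans, function(m) pmax(0, m + matrix(rnorm(h * w, 0, config$noise_sd), h, w)))
  }
  a <- array(0, c(h, w, 6L))
  for (i in 1:6) a[, , i] <- chans[[i]]
  image_bundle(a, channels = mif_channel_names(),
               pixel_size_um = phantom$pixel_size_um,
               provenance = list(seed = config$seed, kind = "mif"))
}

# per-class abundance maps (nuclei density, tumor cytoplasm, stroma, background)
class_abundances <- function(phantom) {
  h <- phantom$height_px; w <- phantom$width_px
  nucmap <- paint_nuclei(h, w, phantom$nuclei,
                         rep(1, nrow(phantom$nuclei)), profile = "disk")
  nucmap <- pmin(nucmap, 1)
  tum_cyto <- phantom$tumor_mask & !(nucmap > 0)
  stroma <- phantom$tissue_mask & !phantom$tumor_mask & !(nucmap > 0)
  list(nuclei = nucmap, tumor_cytoplasm = tum_cyto * 1,
       stroma = stroma * 1, background = phantom$tissue_mask * 1)
}

af_emission_total <- function(phantom, config) {
  ab <- class_abundances(phantom)
  tot <- rowSums(config$af_channel_spectra)
  em <- ab$nuclei * tot["nuclei"] + ab$tumor_cytoplasm * tot["tumor_cytoplasm"] +
    ab$stroma * tot["stroma"] + ab$background * tot["background"]
  blur2d(em, config$psf_sigma_px)
}

#' Render the 20-channel autofluorescence image of a phantom
#'
#' Linear mixing model: each tissue class emits its configured spectrum
#' scaled by its abundance map, plus a flat background level, PSF blur, and
#' optional Gaussian noise. Deterministic per seed.
#'
#' @inheritParams render_mif
#' @return an [image_bundle()] with 20 channels `AF01`..`AF20`
#' @export
render_af <- function(phantom, config = render_config()) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(config, "render_config"))
  h <- phantom$height_px; w <- phantom$width_px
  sp <- config$af_channel_spectra
  if (ncol(sp) != 20L) vs_abort("AF spectra matrix must have 20 columns")
  set.seed(config$seed + 1L)
  ab <- class_abundances(phantom)
  abn <- list(ab$nuclei, ab$tumor_cytoplasm, ab$stroma, ab$background)
  a <- array(0, c(h, w, 20L))
  for (ch in 1:20) {
    m <- matrix(config$background_af_level, h, w)
    for (k in 1:4) m <- m + abn[[k]] * sp[k, ch]
    a[, , ch] <- blur2d(m, config$psf_sigma_px)
  }
  if (config$noise_sd > 0) {
    # AF intensities are O(1); scale read noise accordingly
    a <- a + array(rnorm(h * w * 20, 0, config$noise_sd / 100), c(h, w, 20L))
    a <- pmax(a, 0)
  }
  image_bundle(a, channels = sprintf("AF%02d", 1:20),
               pixel_size_um = phantom$pixel_size_um,
               provenance = list(seed = config$seed, kind = "af"))
}

#' Render an H&E-like RGB image of a phantom
#'
#' Beer-Lambert rendering with hematoxylin absorbance on nuclei (dark
#' blue-purple) and eosin absorbance on cytoplasm and stroma (pink), over a
#' near-white page.
#'
#' @inheritParams render_mif
#' @return an [image_bundle()] with channels R, G, B in \[0, 1\]
#' @export
render_he <- function(phantom, config = render_config()) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(config, "render_config"))
  h <- phantom$height_px; w <- phantom$width_px
  set.seed(config$seed + 2L)
  ab <- class_abundances(phantom)
  a_hema <- blur2d(1.2 * pmin(ab$nuclei, 1), config$psf_sigma_px)
  a_eosin <- blur2d(0.6 * ab$tumor_cytoplasm + 0.35 * ab$stroma, config$psf_sigma_px)
  od_hema <- c(0.65, 0.70, 0.29)   # standard stain-deconvolution directions
  od_eosin <- c(0.07, 0.99, 0.11)
  white <- 0.95
  rgb <- array(0, c(h, w, 3L))
  for (c_ in 1:3) {
    od <- a_hema * od_hema[c_] + a_eosin * od_eosin[c_]
    m <- white * exp(-od)
    if (config$noise_sd > 0) m <- m + matrix(rnorm(h * w, 0, config$noise_sd / 400), h, w)
    rgb[, , c_] <- clamp(m, 0, 1)
  }
  image_bundle(rgb, channels = c("R", "G", "B"),
               pixel_size_um = phantom$pixel_size_um,
               provenance = list(seed = config$seed, kind = "he"))
}
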