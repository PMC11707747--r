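# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so tests are reproducible.

# smooth blob texture with rich gradients, for registration fixtures
textured_patch <- function(n = 128, n_blobs = 40, seed = 2) {
  set.seed(seed)
  a <- matrix(0, n, n)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 10, n - 10); cy <- runif(1, 10, n - 10)
    r2 <- outer((seq_len(n) - cy)^2, rep(1, n)) +
      outer(rep(1, n), (seq_len(n) - cx)^2)
    a <- a + runif(1, 0.5, 1.5) * exp(-r2 / (2 * runif(1, 4, 16)))
  }
  a
}

small_phantom <- function(seed = 21, ...) {
  make_phantom(phantom_config(seed = seed, ...))
}

noiseless_render_config <- function(seed = 21) {
  render_config(seed = seed, noise_sd = 0, cd8_nonspecific_amplitude = 0)
}

# tiny AF/H&E patch pairs for trainer tests
tiny_pairs <- function(n = 12, af_size = 64L, pad = 8L, seed = 11) {
  ph <- make_phantom(phantom_config(width_px = 256, height_px = 256,
                                    n_tumor = 25, n_t_cell = 12,
                                    n_cytotoxic = 6, n_other = 8, seed = seed))
  rc <- render_config(seed = seed)
  af <- render_af(ph, rc)
  he <- render_he(ph, rc)
  pol <- sampling_policy(seed = seed)
  wts <- build_sampling_weights(tissue_mask(af), pol)
  sample_paired_patches(af, he, n, wts, pol, af_size = af_size, pad = pad)
}

# hand-built cell table for TPS/CPS oracle tests: positions on a 100x100
# grid, labels painted as single pixels so the table is fully controlled
toy_cell_table <- function(n_tumor, n_tumor_pdl1, n_immune_pdl1,
                           n_immune_plain = 0) {
  n <- n_tumor + n_immune_pdl1 + n_immune_plain
  lab <- matrix(0L, 100, 100)
  xs <- 5 + 3 * (seq_len(n) - 1) %% 30
  ys <- 5 + 3 * (seq_len(n) - 1) %/% 30
  for (i in seq_len(n)) lab[ys[i], xs[i]] <- i
  tab <- tibble::tibble(
    id = seq_len(n), x = as.numeric(xs), y = as.numeric(ys),
    area_px = 1, area_um2 = 1,
    pos_PDL1 = c(rep(TRUE, n_tumor_pdl1), rep(FALSE, n_tumor - n_tumor_pdl1),
                 rep(TRUE, n_immune_pdl1), rep(FALSE, n_immune_plain)),
    pos_CD3 = rep(FALSE, n), pos_CD8 = rep(FALSE, n),
    in_tumor = c(rep(TRUE, n_tumor), rep(FALSE, n_immune_pdl1 + n_immune_plain)))
  attr(tab, "labels") <- lab
  attr(tab, "pixel_size_um") <- 1
  class(tab) <- c("cell_table", class(tab))
  tab
}

full_mask <- function(h = 100, w = 100) matrix(TRUE, h, w)
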