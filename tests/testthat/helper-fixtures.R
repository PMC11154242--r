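# shared fixtures built in code

# hand-built absorption grid for normalization identities
make_grid <- function(values, n_photons, dz = 0.05, dx = 1, dy = 1) {
  d <- dim(values)
  cfg <- simulation_config(n_photons = n_photons,
                           voxel_dx = dx, voxel_dy = dy, voxel_dz = dz,
                           grid_nx = d[1], grid_ny = d[2], grid_nz = d[3])
  structure(list(values = values, config = cfg,
                 wavelength = 405, tissue_label = "test"),
            class = "absorption_grid")
}

budget_sum <- function(b) {
  b$specular_reflected + b$diffuse_reflected + b$absorbed +
    b$transmitted_or_escaped
}

# noise-free exponential tile scan with constant rows per depth
exact_exp_profile <- function(delta, I0 = 100, bg = 0, tile_height = 212,
                              n_tiles = 6) {
  z <- (seq_len(n_tiles) - 0.5) * tile_height
  depth_fluor_profile(z, I0 * exp(-z / delta) + bg)
}

# independent Clopper-Pearson oracle: direct inversion of the binomial
# tail probabilities by root finding (no beta-quantile shortcut)
cp_oracle <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}
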