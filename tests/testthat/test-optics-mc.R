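test_that("validation rejects bad optical and simulation inputs", {
  expect_error(optical_properties(-1, 1), class = "pdtbedkit_validation_error")
  expect_error(optical_properties(1, 1, n = 0.9), class = "pdtbedkit_validation_error")
  expect_error(optical_properties(1, 1, g = 1), class = "pdtbedkit_validation_error")
  expect_error(simulation_config(voxel_dz = 0), class = "pdtbedkit_validation_error")
  expect_error(simulation_config(n_photons = 0), class = "pdtbedkit_validation_error")
  m <- default_tissue_models()$tumor
  expect_error(simulate_transport(m, 532, simulation_config(n_photons = 10)),
               class = "pdtbedkit_config_error")
})

test_that("vacuum identity: transparent matched medium transmits everything", {
  m <- tissue_model("vacuum", list(
    "405" = optical_properties(0, 0, n = 1)), ambient_n = 1)
  res <- simulate_transport(m, 405, simulation_config(n_photons = 1000,
                                                      rng_seed = 5))
  expect_equal(res$budget$specular_reflected, 0)
  expect_equal(res$budget$absorbed, 0)
  expect_equal(res$budget$transmitted_or_escaped, 1)
  expect_equal(sum(res$grid$values), 0)
})

test_that("normal-incidence specular reflectance is the analytic Fresnel value", {
  m <- tissue_model("t", list("660" = optical_properties(0.18, 0.67, n = 1.4)))
  res <- simulate_transport(m, 660, simulation_config(n_photons = 5000,
                                                      rng_seed = 2))
  expect_equal(res$budget$specular_reflected, ((1.4 - 1) / (1.4 + 1))^2,
               tolerance = 1e-12)
})

test_that("energy budget sums to one for every seed, beam and phase function", {
  cases <- list(
    list(props = optical_properties(0.92, 1.29, n = 1.4), beam = "infinite_uniform"),
    list(props = optical_properties(0.07, 0.58, n = 1.4), beam = "infinite_uniform"),
    list(props = optical_properties(0.18, 0.67, n = 1.4, g = 0.9), beam = "infinite_uniform"),
    list(props = optical_properties(0.57, 1.17, n = 1.4), beam = "disc"),
    list(props = optical_properties(0.5, 0, n = 1), beam = "infinite_uniform"))
  for (i in seq_along(cases)) {
    for (seed in c(1L, 42L)) {
      m <- tissue_model("t", setNames(list(cases[[i]]$props), "405"))
      cfg <- simulation_config(n_photons = 2e4, rng_seed = seed,
                               beam = cases[[i]]$beam,
                               grid_nx = if (cases[[i]]$beam == "disc") 20 else 1,
                               grid_ny = if (cases[[i]]$beam == "disc") 20 else 1)
      b <- simulate_transport(m, 405, cfg)$budget
      expect_lt(abs(budget_sum(b) - 1), 1e-6)
      expect_true(all(unlist(b) >= 0))
    }
  }
})

test_that("identical seed and config reproduce the grid bit for bit", {
  m <- default_tissue_models()$muscle
  cfg <- simulation_config(n_photons = 1e4, rng_seed = 99)
  r1 <- simulate_transport(m, 660, cfg)
  r2 <- simulate_transport(m, 660, cfg)
  expect_identical(r1$grid$values, r2$grid$values)
  expect_identical(r1$budget, r2$budget)
  r3 <- simulate_transport(m, 660, simulation_config(n_photons = 1e4,
                                                     rng_seed = 100))
  expect_false(identical(r1$grid$values, r3$grid$values))
})

test_that("absorption-only run reproduces Beer-Lambert within 3 MC sigma per bin", {
  mu_a <- 0.18
  n_ph <- 2e5
  m <- tissue_model("bl", list("660" = optical_properties(mu_a, 0, n = 1)),
                    ambient_n = 1)
  cfg <- simulation_config(n_photons = n_ph, rng_seed = 1, voxel_dz = 0.25,
                           grid_nz = 60)
  res <- simulate_transport(m, 660, cfg)
  prof <- depth_dose_profile(res$grid)
  dz <- 0.25
  edges <- seq(0, 60 * dz, by = dz)
  p_bin <- exp(-mu_a * edges[-length(edges)]) - exp(-mu_a * edges[-1])
  analytic <- p_bin / dz
  se <- sqrt(p_bin * (1 - p_bin) / n_ph) / dz
  expect_true(all(abs(prof$density - analytic) <= 3 * se))
  # surface bin approximates mu_a itself
  expect_equal(prof$density[1], mu_a, tolerance = 0.05)
})

test_that("deep log-slope in the diffusive regime approaches -mu_eff", {
  # muscle at 660 nm: mu_eff = sqrt(3 * 0.07 * (0.07 + 0.58)) ~ 0.37 mm^-1
  m <- default_tissue_models()$muscle
  cfg <- simulation_config(n_photons = 2e5, rng_seed = 8)
  prof <- depth_dose_profile(simulate_transport(m, 660, cfg)$grid)
  sel <- prof$z_centers >= 3 & prof$z_centers <= 8 & prof$density > 0
  fit <- lm(log(prof$density[sel]) ~ prof$z_centers[sel])
  mu_eff <- sqrt(3 * 0.07 * (0.07 + 0.58))
  expect_equal(unname(-coef(fit)[2]), mu_eff, tolerance = 0.15)
})

test_that("similarity invariance: (g=0, mu_s') matches (g=0.9, mu_s'/0.1) at depth", {
  base <- optical_properties(0.18, 0.67, n = 1.4, g = 0)
  hg <- optical_properties(0.18, 0.67, n = 1.4, g = 0.9)  # mu_s scaled internally
  cfg <- simulation_config(n_photons = 1e5, rng_seed = 31)
  p0 <- depth_dose_profile(simulate_transport(
    tissue_model("t", list("660" = base)), 660, cfg)$grid)
  p9 <- depth_dose_profile(simulate_transport(
    tissue_model("t", list("660" = hg)), 660,
    simulation_config(n_photons = 1e5, rng_seed = 32))$grid)
  # compare beyond one transport mean free path (1/(mu_a + mu_s') ~ 1.2 mm)
  mfp <- 1 / (0.18 + 0.67)
  sel <- p0$z_centers > 1.5 * mfp & p0$z_centers < 6
  a <- sum(p0$density[sel]); b <- sum(p9$density[sel])
  expect_equal(a, b, tolerance = 0.05)
})

test_that("depth profile normalization identities hold", {
  # all-zero grid -> all-zero profile (valid, message logged)
  g0 <- make_grid(array(0, dim = c(1, 1, 10)), n_photons = 100)
  expect_message(p0 <- depth_dose_profile(g0), "all zero")
  expect_equal(p0$density, rep(0, 10))

  # single voxel holding Nph * dz of weight -> density 1.0 mm^-1 there
  vals <- array(0, dim = c(1, 1, 10))
  n_ph <- 1000; dz <- 0.05
  vals[1, 1, 4] <- n_ph * dz
  p <- depth_dose_profile(make_grid(vals, n_photons = n_ph, dz = dz))
  expect_equal(p$density[4], 1.0)
  expect_equal(sum(p$density[-4]), 0)
  expect_equal(p$z_centers[1], dz / 2)
})

test_that("profile integral equals the absorbed budget fraction", {
  m <- default_tissue_models()$tumor
  cfg <- simulation_config(n_photons = 5e4, rng_seed = 12)
  res <- simulate_transport(m, 405, cfg)
  prof <- depth_dose_profile(res$grid)
  integral <- sum(prof$density) * cfg$voxel_dz
  # identical up to the tiny roulette renormalization of the budget
  expect_equal(integral, res$budget$absorbed, tolerance = 1e-3)
})

test_that("crossover_depth locates the analytic crossing of two exponentials", {
  z <- seq(0.025, 5, by = 0.05)
  a <- depth_profile(z, 2 * exp(-2 * z))
  b <- depth_profile(z, exp(-z))
  # linear interpolation between 0.05-mm bins of an exponential difference
  # carries a small curvature bias, hence the 0.5% tolerance
  expect_equal(crossover_depth(a, b, smooth_bins = 1), log(2), tolerance = 5e-3)
  expect_equal(crossover_depth(a, b, smooth_bins = 3), log(2), tolerance = 5e-3)

  # no crossing -> sentinel
  d <- crossover_depth(depth_profile(z, 2 * exp(-z)), depth_profile(z, exp(-z)))
  expect_true(is.na(d))
  expect_true(isTRUE(attr(d, "no_crossover")))

  # identical profiles -> degenerate comparison
  expect_error(crossover_depth(a, a), class = "pdtbedkit_validation_error")
  # wrong ordering at the surface
  expect_error(crossover_depth(b, a), class = "pdtbedkit_validation_error")
})

test_that("tumor crossover is shallower than muscle crossover", {
  models <- default_tissue_models()
  cfg <- simulation_config(n_photons = 1e5, rng_seed = 21)
  ct <- wavelength_comparison(models$tumor, cfg)$crossover_mm
  cm <- wavelength_comparison(models$muscle, cfg)$crossover_mm
  expect_lt(ct, cm)
})

test_that("exposure_time divides dose by fluence rate", {
  expect_equal(exposure_time(irradiation_plan(150, 260)), 150 / 0.26,
               tolerance = 1e-12)  # ~577 s, inside the half-hour limit
  expect_equal(exposure_time(irradiation_plan(150, 125)), 1200)
  expect_equal(exposure_time(irradiation_plan(0, 125)), 0)
  expect_error(exposure_time(irradiation_plan(150, 0)),
               class = "pdtbedkit_validation_error")
})
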