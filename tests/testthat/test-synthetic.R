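test_that("quality field is smooth, bounded and deterministic", {
  cfg <- tiny_config(seed = 7)
  qf1 <- gen_quality_field(cfg)
  qf2 <- gen_quality_field(cfg)
  expect_identical(qf1, qf2)
  expect_true(all(qf1$quality_field >= 0 & qf1$quality_field <= 1))
  expect_gt(lag1_autocorrelation(qf1$quality_field), 0.5)
  # zero amplitude degenerates to a constant field
  flat <- gen_quality_field(tiny_config(quality_amplitude = 0))
  expect_equal(min(flat$quality_field), max(flat$quality_field))
  expect_error(gen_quality_field(synthetic_config(grid_shape = c(5, 40))),
               "grid too small")
})

test_that("type mask and plot stratification reproduce the survey design", {
  cfg <- synthetic_config(seed = 3, grid_shape = c(30, 40), n_plots = 77,
                          frac_meadow = 49 / 77)
  qf <- gen_quality_field(cfg)
  tab <- gen_plot_table(cfg, qf)
  expect_equal(sum(tab$grassland_type == "AM"), 49)
  expect_equal(sum(tab$grassland_type == "AS"), 28)
  expect_equal(anyDuplicated(tab$plot_id), 0L)
  expect_true(all(indicator_names() %in% names(tab)))
  # more plots than pixels is rejected
  cfg_big <- synthetic_config(grid_shape = c(8, 8), n_plots = 100)
  expect_error(gen_plot_table(cfg_big, gen_quality_field(cfg_big)), "exceeds")
})

test_that("indicator-quality coupling follows the noise model", {
  qf <- gen_quality_field(tiny_config(seed = 11))
  noiseless <- gen_plot_table(tiny_config(seed = 11, noise_sd_indicator = 0), qf)
  q <- attr(noiseless, "true_quality")
  strong <- c("aboveground_biomass", "cover", "shannon", "soc", "total_n",
              "total_p", "soil_moisture")
  for (nm in strong) {
    expect_equal(abs(cor(noiseless[[nm]], q)), 1, tolerance = 1e-12)
  }
  # near-noise indicator stays weakly coupled at the default noise level
  cfg <- synthetic_config(seed = 11, grid_shape = c(30, 40), n_plots = 77)
  tab <- gen_plot_table(cfg, gen_quality_field(cfg))
  expect_lt(abs(cor(tab$avail_p, attr(tab, "true_quality"))), 0.3)
})

test_that("scene bands are monotone in quality and NDVI ranks quality", {
  cfg <- tiny_config(noise_sd_scene = 0)
  set.seed(1)
  hi <- gen_scene(1, cfg); lo <- gen_scene(0, cfg)
  ndvi <- function(s) mean(compute_vis(s, "NDVI")$NDVI)
  expect_gt(ndvi(hi), ndvi(lo))
  qs <- seq(0, 1, length.out = 20)
  mean_ndvi <- vapply(qs, function(q) ndvi(gen_scene(q, cfg)), 0)
  expect_equal(cor(mean_ndvi, qs, method = "spearman"), 1)
  # equal bands zero every normalized difference
  flat <- lapply(setNames(rep(0.3, 5), c("B", "G", "R", "RE", "NIR")),
                 matrix, nrow = 4, ncol = 4)
  vis <- compute_vis(flat, c("NDVI", "GNDVI", "NDRE", "NGRDI"))
  for (v in vis) expect_true(all(v == 0))
})

test_that("climate cube follows the lagged recursion and its fixed point", {
  cfg <- tiny_config(n_months = 60, noise_sd_climate = 0)
  cf <- const_coeff_fields(24, 24, a = 0, b = 0, c = 0.5, k = 1)
  cube <- gen_climate_cube(cfg, cf)
  # a = b = 0, k = 1, c = 0.5: LAI converges to k / (1 - c) = 2
  expect_equal(c(cube$lai[1, 1, ]), rep(2, 60), tolerance = 1e-9)
  expect_identical(gen_climate_cube(cfg, cf), cube)
  expect_error(gen_climate_cube(tiny_config(n_months = 20), cf), "n_months")
})

test_that("per-pixel OLS recovers the generating coefficients", {
  cfg <- synthetic_config(seed = 5, grid_shape = c(8, 8), n_months = 500,
                          noise_sd_climate = 0.05)
  cf <- const_coeff_fields(8, 8, a = 0.03, b = 0.006, c = 0.5, k = 0.3)
  cube <- gen_climate_cube(cfg, cf)
  # independent least-squares oracle on the design matrix of one pixel
  ts <- 2:500
  d <- data.frame(y = cube$lai[1, 1, ts], tem = cube$tem[1, 1, ts],
                  pre = cube$pre[1, 1, ts], lag = cube$lai[1, 1, ts - 1])
  cf_hat <- coef(lm(y ~ tem + pre + lag, d))
  expect_equal(unname(cf_hat[c("tem", "pre", "lag")]), c(0.03, 0.006, 0.5),
               tolerance = 0.05)
  # stationarity: no divergence beyond the fixed-point + noise envelope
  fp <- (0.03 * 8 + 0.006 * 60 + 0.3) / 0.5
  expect_true(all(abs(cube$lai) < fp + 10 * 1))
})

test_that("pressure inputs close the loop with the pressure module at zero noise", {
  cfg <- tiny_config(seed = 9, noise_sd_grazing = 0)
  qf <- gen_quality_field(cfg)
  cube <- gen_climate_cube(cfg, gen_coeff_fields(cfg))
  pin <- gen_pressure_inputs(cfg, qf, cube)
  rebuilt <- pressure_surface(pin$grazing, pin$tem_mean, pin$pre_mean,
                              qf$type_mask)
  expect_equal(rebuilt$pressure, pin$pressure_field, tolerance = 1e-8)
  # grazing strictly monotone along the gradient axis at zero noise
  expect_true(all(diff(pin$grazing[1, ]) > 0))
  expect_identical(gen_pressure_inputs(cfg, qf, cube), pin)
})

test_that("simulate_inputs is deterministic end to end", {
  cfg <- tiny_config(seed = 21)
  expect_identical(simulate_inputs(cfg), simulate_inputs(cfg))
})
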