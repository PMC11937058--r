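make_table <- function(...) {
  cols <- list(...)
  as.data.frame(c(list(plot_id = sprintf("P%02d", seq_along(cols[[1]]))), cols))
}

test_that("min-max standardization maps, inverts and round-trips correctly", {
  tab <- make_table(soc = c(2, 4, 6), bulk_density = c(1.0, 1.25, 1.5))
  std <- standardize_indicators(tab, indicators = c("soc", "bulk_density"))
  expect_equal(std$table$soc, c(0, 0.5, 1))
  # negative polarity: densest soil scores 0
  expect_equal(std$table$bulk_density, c(1, 0.5, 0))
  # stored parameters reproduce the training standardization exactly
  again <- apply_standardization(std$params, tab)
  expect_equal(again$soc, std$table$soc)
  expect_equal(again$bulk_density, std$table$bulk_density)
})

test_that("pH is scored by distance from neutral", {
  tab <- make_table(ph = c(7, 7.4, 7.8))
  std <- standardize_indicators(tab, indicators = "ph")
  expect_equal(std$table$ph, c(1, 0.5, 0))
})

test_that("degenerate indicator columns are rejected by name", {
  tab <- make_table(soc = c(1, 1, 1), total_n = c(1, 2, 3))
  expect_error(standardize_indicators(tab, indicators = c("soc", "total_n")),
               "constant indicator column: soc")
  tab$soc <- c("a", "b", "c")
  expect_error(standardize_indicators(tab, indicators = "soc"), "not numeric")
})

test_that("PCA selection matches a brute-force eigendecomposition oracle", {
  set.seed(42)
  n <- 200
  base <- runif(n)
  tab <- data.frame(x1 = base, x2 = 0.2 + 0.6 * base,  # perfectly correlated pair
                    n1 = runif(n), n2 = runif(n), n3 = runif(n))
  w <- pca_select_weights(tab, eigen_threshold = 1, loading_threshold = 0.5)
  # oracle: eigendecomposition of the correlation matrix
  Z <- scale(as.matrix(tab))
  ev <- eigen(cor(as.matrix(tab)), symmetric = TRUE)
  keep <- which(ev$values > 1)
  L <- abs(ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]), length(keep)))
  sel_oracle <- names(tab)[apply(L, 1, max) >= 0.5]
  expect_setequal(w$selected_indicators, sel_oracle)
  # the perfectly correlated pair is selected with equal weights
  expect_true(all(c("x1", "x2") %in% w$selected_indicators))
  expect_equal(w$weights[["x1"]], w$weights[["x2"]], tolerance = 1e-10)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
})

test_that("PCA weighting honours its output contract on unstructured data", {
  set.seed(99)
  tab <- as.data.frame(matrix(runif(14 * 77), 77, 14,
                              dimnames = list(NULL, indicator_names())))
  w <- pca_select_weights(tab)
  expect_true(all(w$weights >= 0))
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_true(all(w$selected_indicators %in% indicator_names()))
})

test_that("quality-loaded indicators are selected across seeds", {
  strong <- c("aboveground_biomass", "belowground_biomass", "cover", "shannon",
              "simpson", "pielou", "soc", "total_n", "total_p", "soil_moisture")
  hits <- vapply(1:50, function(s) {
    cfg <- synthetic_config(seed = s, grid_shape = c(30, 40), n_plots = 77,
                            noise_sd_indicator = 0.1)
    tab <- gen_plot_table(cfg, gen_quality_field(cfg))
    w <- pca_select_weights(standardize_indicators(tab))
    all(strong %in% w$selected_indicators)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("GQI is the convex combination of standardized indicators", {
  w <- structure(list(selected_indicators = c("a", "b", "c"),
                      weights = c(a = 0.5, b = 0.3, c = 0.2)),
                 class = "gqi_weights")
  tab <- data.frame(a = c(1, 1, 0), b = c(0, 1, 0), c = c(0.5, 1, 0))
  gqi <- compute_plot_gqi(tab, w)
  expect_equal(gqi$gqi, c(0.6, 1, 0))
  # column order is irrelevant
  expect_equal(compute_plot_gqi(tab[c("c", "a", "b")], w)$gqi, gqi$gqi)
  expect_error(compute_plot_gqi(tab[c("a", "b")], w), "missing selected")
})

test_that("raising a positive-polarity indicator never lowers the GQI", {
  cfg <- tiny_config(seed = 13)
  tab <- gen_plot_table(cfg, gen_quality_field(cfg))
  std <- standardize_indicators(tab)
  w <- pca_select_weights(std)
  base <- compute_plot_gqi(std, w)$gqi
  bumped <- tab
  bumped$soc <- bumped$soc + 5
  gqi2 <- compute_plot_gqi(apply_standardization(std$params, bumped), w)$gqi
  expect_true(all(gqi2 >= base - 1e-12))
})

test_that("at zero noise the GQI reproduces the latent quality ranking", {
  cfg <- tiny_config(seed = 17, noise_sd_indicator = 0)
  tab <- gen_plot_table(cfg, gen_quality_field(cfg))
  std <- standardize_indicators(tab)
  gqi <- compute_plot_gqi(std, pca_select_weights(std))
  rho <- cor(gqi$gqi, attr(tab, "true_quality"), method = "spearman")
  expect_equal(rho, 1)
  expect_true(all(gqi$gqi >= 0 & gqi$gqi <= 1))
})
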