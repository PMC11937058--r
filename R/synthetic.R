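#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: a survey of 77
#' plots split 49/28 between alpine meadow (AM) and alpine steppe (AS), 20
#' years x 5 growing-season months (May-September) of monthly climate/LAI
#' series, and moderate indicator measurement noise.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param grid_shape c(rows, cols) of the regional grid (each dimension >= 8).
#' @param n_plots number of survey plots (>= 10).
#' @param frac_meadow fraction of the landscape (and of plots) that is alpine
#'   meadow; the remainder is alpine steppe.
#' @param n_months number of growing-season months simulated (>= 30); 100 =
#'   20 years x 5 months.
#' @param noise_sd_indicator measurement noise of plot indicators, expressed
#'   on the latent quality scale (quality lives in \[0, 1\]).
#' @param noise_sd_climate innovation noise of the LAI recursion.
#' @param noise_sd_scene reflectance noise added to UAV scene bands.
#' @param noise_sd_regional noise added to the regional NDVI/EVI predictors.
#' @param noise_sd_grazing noise (sheep units km-2) around the grazing
#'   gradient.
#' @param quality_amplitude peak-to-peak amplitude of the latent quality
#'   field around 0.5 (0 gives a constant field).
#' @param scene_shape c(rows, cols) of each per-plot UAV scene.
#' @param coeff_ranges named list of c(lo, hi) uniform ranges for the true
#'   climate-model coefficients `a` (temperature), `b` (precipitation),
#'   `c` (lag; upper bound must stay below 1 for stationarity) and `k`
#'   (intercept).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             grid_shape = c(60L, 80L),
                             n_plots = 77L,
                             frac_meadow = 49 / 77,
                             n_months = 100L,
                             noise_sd_indicator = 0.05,
                             noise_sd_climate = 0.05,
                             noise_sd_scene = 0.01,
                             noise_sd_regional = 0.02,
                             noise_sd_grazing = 10,
                             quality_amplitude = 1,
                             scene_shape = c(12L, 12L),
                             coeff_ranges = list(a = c(0.01, 0.05),
                                                 b = c(0.002, 0.01),
                                                 c = c(0.2, 0.8),
                                                 k = c(0.1, 0.5))) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            n_plots >= 10, frac_meadow >= 0, frac_meadow <= 1,
            noise_sd_indicator >= 0, noise_sd_climate >= 0,
            quality_amplitude >= 0)
  req <- c("a", "b", "c", "k")
  if (!all(req %in% names(coeff_ranges))) {
    stop("coeff_ranges must name ranges for a, b, c and k")
  }
  if (coeff_ranges$c[2] >= 1) {
    stop("upper bound of the c range must be < 1 (stationarity of the LAI recursion)")
  }
  cfg <- list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
              n_plots = as.integer(n_plots), frac_meadow = frac_meadow,
              n_months = as.integer(n_months),
              noise_sd_indicator = noise_sd_indicator,
              noise_sd_climate = noise_sd_climate,
              noise_sd_scene = noise_sd_scene,
              noise_sd_regional = noise_sd_regional,
              noise_sd_grazing = noise_sd_grazing,
              quality_amplitude = quality_amplitude,
              scene_shape = as.integer(scene_shape),
              coeff_ranges = coeff_ranges)
  class(cfg) <- "synthetic_config"
  cfg
}

# Smooth [0,1] field from low-pass-filtered white noise; filter scale grid/8.
smooth_unit_field <- function(nr, nc, amplitude = 1) {
  z <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sigma = min(nr, nc) / 8)
  if (amplitude == 0 || sd(z) == 0) return(matrix(0.5, nr, nc))
  0.5 + amplitude * (minmax_rescale(z) - 0.5)
}

#' Generate the latent quality field and the grassland-type mask
#'
#' The quality field is low-pass-filtered Gaussian noise (filter scale about
#' one eighth of the grid) rescaled into \[0, 1\]; the mask splits the grid
#' into an alpine-meadow block (western columns) and an alpine-steppe block
#' according to `frac_meadow`.
#'
#' @param config a [synthetic_config()].
#' @return list with `quality_field` (numeric matrix in \[0, 1\]) and
#'   `type_mask` (character matrix of `"AM"` / `"AS"`).
#' @export
gen_quality_field <- function(config) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  if (nr < 8 || nc < 8) stop("grid too small: both dimensions must be >= 8")
  set.seed(config$seed + 11L)
  quality <- smooth_unit_field(nr, nc, config$quality_amplitude)
  n_am_cols <- round(config$frac_meadow * nc)
  type_mask <- matrix(ifelse(col(quality) <= n_am_cols, "AM", "AS"), nr, nc)
  list(quality_field = quality, type_mask = type_mask)
}

# Indicator recipe: name, affine map applied to the (noisy) quality signal,
# loading class. Strong indicators track quality directly; weak ones carry a
# small quality loading plus intrinsic scatter whose magnitude scales with
# noise_sd_indicator so the zero-noise configuration is fully deterministic.
indicator_recipes <- function() {
  list(
    aboveground_biomass = list(kind = "strong", lo = 50,   hi = 450),
    belowground_biomass = list(kind = "strong", lo = 200,  hi = 1700),
    cover               = list(kind = "strong", lo = 0.10, hi = 0.95),
    shannon             = list(kind = "strong", lo = 0.5,  hi = 3.0),
    simpson             = list(kind = "strong", lo = 0.30, hi = 0.90),
    pielou              = list(kind = "strong", lo = 0.30, hi = 0.90),
    soc                 = list(kind = "strong", lo = 5,    hi = 50),
    total_n             = list(kind = "strong", lo = 0.5,  hi = 5.0),
    total_p             = list(kind = "strong", lo = 0.2,  hi = 1.2),
    soil_moisture       = list(kind = "strong", lo = 0.05, hi = 0.55),
    avail_n             = list(kind = "weak", lo = 80,  hi = 140, w = 0.15, s = 0.30),
    avail_p             = list(kind = "weak", lo = 8,   hi = 14,  w = 0.05, s = 0.30),
    bulk_density        = list(kind = "weak", lo = 1.55, hi = 1.25, w = 0.20, s = 0.25),
    ph                  = list(kind = "weak", lo = 7.80, hi = 7.65, w = 0.25, s = 0.25)
  )
}

#' Names of the 14 plot indicator columns
#' @return character vector.
#' @export
indicator_names <- function() names(indicator_recipes())

#' Generate the plot-scale indicator table
#'
#' Samples `n_plots` distinct pixels (stratified so that
#' `round(frac_meadow * n_plots)` fall in alpine meadow) and produces the 14
#' vegetation/soil indicators. The ten indicators that proxy the key
#' quality dimensions (above/belowground biomass, cover, the three diversity
#' indices, SOC, total N, total P, soil moisture) are monotone affine
#' functions of local latent quality plus Gaussian noise
#' (`noise_sd_indicator`, on the quality scale); available N/P, bulk density
#' and pH carry only weak loadings. Bulk density and pH decrease (pH drifts
#' toward neutral) as quality increases, giving them negative polarity.
#'
#' @param config a [synthetic_config()].
#' @param ground_truth result of [gen_quality_field()] (or the full
#'   [simulate_inputs()] ground truth).
#' @return data.frame with plot_id, grassland_type, lon, lat, row, col and
#'   the 14 indicator columns; latent quality attached as attribute
#'   `true_quality`.
#' @export
gen_plot_table <- function(config, ground_truth) {
  q <- ground_truth$quality_field
  mask <- ground_truth$type_mask
  npix <- length(q)
  if (config$n_plots > npix) stop("n_plots exceeds the number of grid pixels")
  set.seed(config$seed + 23L)
  n_am <- round(config$frac_meadow * config$n_plots)
  idx_am <- sample(which(mask == "AM"), n_am)
  idx_as <- sample(which(mask == "AS"), config$n_plots - n_am)
  idx <- c(idx_am, idx_as)
  qv <- q[idx]
  n <- length(idx)
  rows <- (idx - 1L) %% nrow(q) + 1L
  cols <- (idx - 1L) %/% nrow(q) + 1L
  tab <- data.frame(
    plot_id = sprintf("P%03d", seq_len(n)),
    grassland_type = mask[idx],
    lon = 80 + cols * 0.05,
    lat = 36 - rows * 0.05,
    row = rows, col = cols,
    stringsAsFactors = FALSE
  )
  s_weak <- config$noise_sd_indicator / 0.05   # scales intrinsic weak scatter
  for (nm in indicator_names()) {
    r <- indicator_recipes()[[nm]]
    if (r$kind == "strong") {
      sig <- qv + rnorm(n, 0, config$noise_sd_indicator)
    } else {
      sig <- r$w * qv + s_weak * rnorm(n, 0, r$s)
    }
    val <- r$lo + (r$hi - r$lo) * sig
    if (nm %in% c("cover", "soil_moisture")) val <- pmin(pmax(val, 0), 1)
    if (nm == "bulk_density") val <- pmax(val, 0.2)
    tab[[nm]] <- val
  }
  attr(tab, "true_quality") <- qv
  tab
}

#' Generate a five-band UAV scene for one plot
#'
#' Band means are affine in plot quality with NIR increasing and red
#' decreasing such that NIR + R is constant, making NDVI exactly linear in
#' quality before noise. Reflectances are clipped to \[0, 1\].
#'
#' @param plot_quality scalar latent quality in \[0, 1\].
#' @param config a [synthetic_config()].
#' @return named list of matrices `B`, `G`, `R`, `RE`, `NIR`.
#' @export
gen_scene <- function(plot_quality, config) {
  stopifnot(plot_quality >= 0, plot_quality <= 1)
  nr <- config$scene_shape[1]; nc <- config$scene_shape[2]
  means <- c(B = 0.06 + 0.02 * plot_quality,
             G = 0.10 + 0.06 * plot_quality,
             R = 0.25 - 0.15 * plot_quality,
             RE = 0.18 + 0.12 * plot_quality,
             NIR = 0.25 + 0.15 * plot_quality)
  lapply(as.list(means), function(mu) {
    band <- mu + matrix(rnorm(nr * nc, 0, config$noise_sd_scene), nr, nc)
    pmin(pmax(band, 0), 1)
  })
}

#' Generate scenes and footprints for every plot
#'
#' @param config a [synthetic_config()].
#' @param plot_table result of [gen_plot_table()].
#' @return list with `scenes` (named list of scenes per plot_id) and
#'   `footprints` (data.frame plot_id, row0, col0, nrows, ncols; 0-based,
#'   half-open central windows).
#' @export
gen_scenes <- function(config, plot_table) {
  qv <- attr(plot_table, "true_quality")
  set.seed(config$seed + 31L)
  scenes <- lapply(seq_len(nrow(plot_table)), function(i) gen_scene(qv[i], config))
  names(scenes) <- plot_table$plot_id
  nr <- config$scene_shape[1]; nc <- config$scene_shape[2]
  fr <- max(2L, nr %/% 2L); fc <- max(2L, nc %/% 2L)
  footprints <- data.frame(plot_id = plot_table$plot_id,
                           row0 = (nr - fr) %/% 2L, col0 = (nc - fc) %/% 2L,
                           nrows = fr, ncols = fc, stringsAsFactors = FALSE)
  list(scenes = scenes, footprints = footprints)
}

#' Generate the true per-pixel climate-model coefficient fields
#'
#' Smooth fields mapped into the configured uniform ranges for a
#' (temperature), b (precipitation), c (lag) and k (intercept), plus smooth
#' mean temperature and precipitation surfaces.
#'
#' @param config a [synthetic_config()].
#' @return list of matrices `a`, `b`, `c`, `k`, `tem_mean`, `pre_mean`.
#' @export
gen_coeff_fields <- function(config) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  set.seed(config$seed + 41L)
  field_in <- function(rng) {
    z <- smooth_unit_field(nr, nc, 1)
    rng[1] + (rng[2] - rng[1]) * z
  }
  list(a = field_in(config$coeff_ranges$a),
       b = field_in(config$coeff_ranges$b),
       c = field_in(config$coeff_ranges$c),
       k = field_in(config$coeff_ranges$k),
       tem_mean = field_in(c(2, 12)),    # deg C, growing-season mean
       pre_mean = field_in(c(30, 90)))   # mm / month
}

#' Simulate the monthly growing-season climate/LAI cube
#'
#' Per pixel, temperature and precipitation are stationary AR(1) series
#' (autocorrelation 0.3) around the pixel's mean surface; LAI follows the
#' lagged recursion `LAI_t = a*tem_t + b*pre_t + c*LAI_(t-1) + k + eps_t`
#' with `eps ~ N(0, noise_sd_climate^2)`. A 24-step burn-in initialized at
#' the deterministic fixed point is discarded. Months are labelled cyclically
#' May..September across years.
#'
#' @param config a [synthetic_config()].
#' @param coeff_fields result of [gen_coeff_fields()].
#' @return list of class `climate_cube`: arrays `lai`, `tem`, `pre` of dim
#'   c(rows, cols, n_months) and `month_index` data.frame (year, month).
#' @export
gen_climate_cube <- function(config, coeff_fields) {
  if (config$n_months < 30) stop("n_months must be >= 30 for a stable lagged regression")
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  npix <- nr * nc
  burn <- 24L
  nt <- config$n_months + burn
  set.seed(config$seed + 53L)
  a <- c(coeff_fields$a); b <- c(coeff_fields$b)
  cc <- c(coeff_fields$c); k <- c(coeff_fields$k)
  mt <- c(coeff_fields$tem_mean); mp <- c(coeff_fields$pre_mean)
  phi <- 0.3; sd_tem <- 2.5; sd_pre <- 15
  tem <- matrix(0, npix, nt); pre <- matrix(0, npix, nt); lai <- matrix(0, npix, nt)
  tem[, 1] <- mt + rnorm(npix, 0, sd_tem / sqrt(1 - phi^2))
  pre[, 1] <- pmax(mp + rnorm(npix, 0, sd_pre / sqrt(1 - phi^2)), 0)
  lai[, 1] <- (a * mt + b * mp + k) / (1 - cc)
  for (t in 2:nt) {
    tem[, t] <- mt + phi * (tem[, t - 1] - mt) + rnorm(npix, 0, sd_tem)
    pre[, t] <- pmax(mp + phi * (pre[, t - 1] - mp) + rnorm(npix, 0, sd_pre), 0)
    lai[, t] <- a * tem[, t] + b * pre[, t] + cc * lai[, t - 1] +
      k + rnorm(npix, 0, config$noise_sd_climate)
  }
  keep <- (burn + 1L):nt
  shape <- c(nr, nc, config$n_months)
  months <- rep(5:9, length.out = config$n_months)
  years <- cumsum(c(1L, diff(months) < 0))
  cube <- list(lai = array(lai[, keep], shape),
               tem = array(tem[, keep], shape),
               pre = array(pre[, keep], shape),
               month_index = data.frame(year = years, month = months))
  class(cube) <- "climate_cube"
  cube
}

#' Generate regional predictor rasters (NDVI, EVI, LAI)
#'
#' NDVI and EVI are monotone affine functions of the latent quality field
#' plus Gaussian noise (`noise_sd_regional`); LAI is the temporal mean of the
#' simulated climate cube, tying the satellite LAI product to the climate
#' simulation rather than to quality.
#'
#' @param config a [synthetic_config()].
#' @param ground_truth list holding `quality_field`.
#' @param cube result of [gen_climate_cube()].
#' @return list of matrices `ndvi`, `evi`, `lai`.
#' @export
gen_regional_predictors <- function(config, ground_truth, cube) {
  q <- ground_truth$quality_field
  set.seed(config$seed + 61L)
  nz <- function() matrix(rnorm(length(q), 0, config$noise_sd_regional), nrow(q), ncol(q))
  list(ndvi = pmin(pmax(0.05 + 0.60 * q + nz(), -1), 1),
       evi  = pmin(pmax(0.02 + 0.45 * q + nz(), -1), 1),
       lai  = apply(cube$lai, c(1, 2), mean))
}

#' Generate pressure-layer inputs and the ground-truth pressure field
#'
#' Grazing intensity is a smooth west-east gradient (plus optional noise);
#' temperature and precipitation layers are the climate cube's temporal
#' means. The ground-truth pressure field is the per-type standardized
#' equal-weight aggregate of the noise-free layers, computed with the same
#' pressure-module functions used downstream, so at zero noise the pipeline
#' reproduces it exactly.
#'
#' @param config a [synthetic_config()].
#' @param ground_truth list holding `type_mask`.
#' @param cube result of [gen_climate_cube()].
#' @return list with `grazing`, `tem_mean`, `pre_mean` rasters and
#'   `pressure_field` (the ground truth).
#' @export
gen_pressure_inputs <- function(config, ground_truth, cube) {
  mask <- ground_truth$type_mask
  nr <- nrow(mask); nc <- ncol(mask)
  set.seed(config$seed + 71L)
  grad <- 50 + 300 * (col(mask) - 1) / (nc - 1)
  grazing <- grad + matrix(rnorm(nr * nc, 0, config$noise_sd_grazing), nr, nc)
  tem_mean <- apply(cube$tem, c(1, 2), mean)
  pre_mean <- apply(cube$pre, c(1, 2), mean)
  truth <- pressure_surface(grad, tem_mean, pre_mean, mask)
  list(grazing = grazing, tem_mean = tem_mean, pre_mean = pre_mean,
       pressure_field = truth$pressure)
}

#' Simulate every pipeline input with known ground truth
#'
#' Orchestrates the individual generators into a single reproducible bundle.
#'
#' @param config a [synthetic_config()].
#' @return list with `config`, `plot_table`, `scenes`, `footprints`,
#'   `predictors` (regional NDVI/EVI/LAI), `cube`, `pressure_inputs` and
#'   `ground_truth` (quality_field, type_mask, coeff_fields, pressure_field).
#' @export
simulate_inputs <- function(config = synthetic_config()) {
  qf <- gen_quality_field(config)
  plot_table <- gen_plot_table(config, qf)
  sc <- gen_scenes(config, plot_table)
  coef_fields <- gen_coeff_fields(config)
  cube <- gen_climate_cube(config, coef_fields)
  predictors <- gen_regional_predictors(config, qf, cube)
  pressure_inputs <- gen_pressure_inputs(config, qf, cube)
  list(config = config,
       plot_table = plot_table,
       scenes = sc$scenes,
       footprints = sc$footprints,
       predictors = predictors,
       cube = cube,
       pressure_inputs = pressure_inputs,
       ground_truth = list(quality_field = qf$quality_field,
                           type_mask = qf$type_mask,
                           coeff_fields = coef_fields,
                           pressure_field = pressure_inputs$pressure_field))
}
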