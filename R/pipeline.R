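#' Assemble a pipeline configuration
#'
#' A single list drives every stage of the pipeline; module blocks mirror
#' the function arguments of the corresponding stage. The global seed is
#' fanned out to the stages by fixed offsets so reruns are bit-identical.
#'
#' @param seed global integer seed.
#' @param out_dir directory receiving all stage artifacts.
#' @param synthetic named list of [synthetic_config()] overrides.
#' @param plot_gqi list(eigen_threshold, loading_threshold).
#' @param landscape list(train_frac, refine).
#' @param regional list(max_components).
#' @param resilience list(min_pairs, lag_rule).
#' @param pressure list(directions, weights).
#' @param zoning list(max_exact).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("gzoner_run_"),
                            synthetic = list(),
                            plot_gqi = list(eigen_threshold = 1.0, loading_threshold = 0.5),
                            landscape = list(train_frac = 0.7, refine = TRUE),
                            regional = list(max_components = 3),
                            resilience = list(min_pairs = 30, lag_rule = "within_season"),
                            pressure = list(directions = c(1, 1, 1), weights = rep(1, 3)),
                            zoning = list(max_exact = 10000L)) {
  synthetic$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              synthetic = do.call(synthetic_config, synthetic),
              plot_gqi = plot_gqi, landscape = landscape, regional = regional,
              resilience = resilience, pressure = pressure, zoning = zoning)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys follow the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. `seed`, `out_dir`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

stage_order <- c("simulate", "plot-gqi", "landscape", "regional",
                 "resilience", "pressure", "zone", "report")

artifact_path <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(config, file, produced_by) {
  p <- artifact_path(config, file)
  if (!file.exists(p)) {
    stop("missing artifact '", file, "': run stage '", produced_by, "' first")
  }
  p
}

write_manifest <- function(config, stage, params, inputs, outputs) {
  rel <- function(files) {
    sums <- tools::md5sum(file.path(config$out_dir, files))
    names(sums) <- files
    as.list(sums)
  }
  manifest <- list(stage = stage, seed = config$seed, parameters = params,
                   inputs = rel(inputs), outputs = rel(outputs),
                   package_version = as.character(utils::packageVersion("gzoner")))
  jsonlite::write_json(manifest, artifact_path(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_type_mask <- function(config) {
  codes <- read_ascii_grid(require_artifact(config, "type_mask.asc", "simulate"))
  m <- matrix(c("other", "AM", "AS")[codes + 1L], nrow(codes), ncol(codes))
  m
}

stage_simulate <- function(config) {
  sim <- simulate_inputs(config$synthetic)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pt <- sim$plot_table
  pt$true_quality <- attr(sim$plot_table, "true_quality")
  write.csv(pt, artifact_path(config, "plot_table.csv"), row.names = FALSE)
  write.csv(sim$footprints, artifact_path(config, "footprints.csv"), row.names = FALSE)
  mask_codes <- matrix(match(sim$ground_truth$type_mask, c("AM", "AS")),
                       nrow(sim$ground_truth$type_mask))
  mask_codes[is.na(mask_codes)] <- 0L
  write_ascii_grid(mask_codes, artifact_path(config, "type_mask.asc"))
  write_ascii_grid(sim$predictors$ndvi, artifact_path(config, "ndvi.asc"))
  write_ascii_grid(sim$predictors$evi, artifact_path(config, "evi.asc"))
  write_ascii_grid(sim$predictors$lai, artifact_path(config, "lai.asc"))
  write_ascii_grid(sim$pressure_inputs$grazing, artifact_path(config, "grazing.asc"))
  write_ascii_grid(sim$pressure_inputs$tem_mean, artifact_path(config, "tem_mean.asc"))
  write_ascii_grid(sim$pressure_inputs$pre_mean, artifact_path(config, "pre_mean.asc"))
  write_ascii_grid(sim$ground_truth$quality_field,
                   artifact_path(config, "true_quality_field.asc"))
  write_ascii_grid(sim$ground_truth$pressure_field,
                   artifact_path(config, "true_pressure_field.asc"))
  saveRDS(sim$cube, artifact_path(config, "cube.rds"))
  saveRDS(sim$scenes, artifact_path(config, "scenes.rds"))
  truth_summary <- list(
    seed = config$seed,
    quality_field = as.list(summary(c(sim$ground_truth$quality_field))),
    coeff_ranges = config$synthetic$coeff_ranges,
    n_plots = nrow(sim$plot_table)
  )
  jsonlite::write_json(truth_summary, artifact_path(config, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outs <- c("plot_table.csv", "footprints.csv", "type_mask.asc", "ndvi.asc",
            "evi.asc", "lai.asc", "grazing.asc", "tem_mean.asc", "pre_mean.asc",
            "true_quality_field.asc", "true_pressure_field.asc",
            "cube.rds", "scenes.rds", "ground_truth.json")
  write_manifest(config, "simulate", config$synthetic[c("seed", "grid_shape", "n_plots")],
                 character(0), outs)
  invisible(sim)
}

stage_plot_gqi <- function(config) {
  pt <- read.csv(require_artifact(config, "plot_table.csv", "simulate"),
                 stringsAsFactors = FALSE)
  std <- standardize_indicators(pt)
  w <- do.call(pca_select_weights,
               c(list(std), config$plot_gqi[c("eigen_threshold", "loading_threshold")]))
  gqi <- compute_plot_gqi(std, w)
  write.csv(gqi, artifact_path(config, "plot_gqi.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(selected_indicators = w$selected_indicators,
         weights = as.list(w$weights),
         standardization = w$standardization,
         eigenvalues = w$pca_report$eigenvalues,
         retained_components = w$pca_report$retained_components),
    artifact_path(config, "gqi_weights.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(config, "plot-gqi", config$plot_gqi, "plot_table.csv",
                 c("plot_gqi.csv", "gqi_weights.json"))
  invisible(gqi)
}

stage_landscape <- function(config) {
  scenes <- readRDS(require_artifact(config, "scenes.rds", "simulate"))
  fps <- read.csv(require_artifact(config, "footprints.csv", "simulate"),
                  stringsAsFactors = FALSE)
  gqi <- read.csv(require_artifact(config, "plot_gqi.csv", "plot-gqi"),
                  stringsAsFactors = FALSE)
  vi_table <- build_vi_table(scenes, fps)
  stopifnot(identical(vi_table$plot_id, gqi$plot_id))
  write.csv(vi_table, artifact_path(config, "vi_table.csv"), row.names = FALSE)
  seed <- config$seed + 301L
  val <- validate_split(vi_table, gqi$gqi, types = gqi$grassland_type,
                        train_frac = config$landscape$train_frac, seed = seed)
  model <- build_landscape_model(vi_table, gqi$gqi, seed = seed,
                                 refine = isTRUE(config$landscape$refine))
  pred <- data.frame(plot_id = gqi$plot_id,
                     grassland_type = gqi$grassland_type,
                     landscape_gqi = predict(model, newdata = vi_table))
  write.csv(pred, artifact_path(config, "landscape_gqi.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(selected_vis = model$selected_vis,
         coefficients = as.list(model$coefficients),
         aic = model$aic,
         rf_importances = as.list(model$rf_importances),
         train_r2 = val$train_r2, test_r2 = val$test_r2),
    artifact_path(config, "landscape_model.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  write_manifest(config, "landscape", config$landscape,
                 c("scenes.rds", "footprints.csv", "plot_gqi.csv"),
                 c("vi_table.csv", "landscape_gqi.csv", "landscape_model.json"))
  invisible(list(model = model, validation = val))
}

stage_regional <- function(config) {
  pt <- read.csv(require_artifact(config, "plot_table.csv", "simulate"),
                 stringsAsFactors = FALSE)
  lg <- read.csv(require_artifact(config, "landscape_gqi.csv", "landscape"),
                 stringsAsFactors = FALSE)
  ndvi <- read_ascii_grid(require_artifact(config, "ndvi.asc", "simulate"))
  evi <- read_ascii_grid(require_artifact(config, "evi.asc", "simulate"))
  lai <- read_ascii_grid(require_artifact(config, "lai.asc", "simulate"))
  mask <- read_type_mask(config)
  idx <- cbind(pt$row, pt$col)
  X <- data.frame(ndvi = ndvi[idx], evi = evi[idx], lai = lai[idx])
  y <- lg$landscape_gqi[match(pt$plot_id, lg$plot_id)]
  cv <- loocv_select(X, y, max_components = config$regional$max_components)
  model <- fit_plsr(X, y, n_components = cv$n_components)
  regional <- predict_regional(model, list(ndvi = ndvi, evi = evi, lai = lai), mask)
  write_ascii_grid(regional, artifact_path(config, "regional_gqi.asc"))
  jsonlite::write_json(
    list(n_components = model$n_components,
         coefficients = as.list(model$coefficients),
         loocv = cv$cv_table,
         loocv_r2 = cv$loocv_r2, loocv_rmse = cv$loocv_rmse,
         clip_fraction = attr(regional, "clip_fraction")),
    artifact_path(config, "plsr_model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(config, "regional", config$regional,
                 c("plot_table.csv", "landscape_gqi.csv", "ndvi.asc", "evi.asc",
                   "lai.asc", "type_mask.asc"),
                 c("regional_gqi.asc", "plsr_model.json"))
  invisible(list(model = model, cv = cv))
}

stage_resilience <- function(config) {
  cube <- readRDS(require_artifact(config, "cube.rds", "simulate"))
  mask <- read_type_mask(config)
  res <- resilience_surfaces(cube, mask,
                             min_pairs = config$resilience$min_pairs,
                             lag_rule = config$resilience$lag_rule)
  write_ascii_grid(res$ri, artifact_path(config, "ri.asc"))
  write_ascii_grid(res$si, artifact_path(config, "si.asc"))
  for (nm in c("a_norm", "b_norm", "c_norm")) {
    write_ascii_grid(res[[nm]], artifact_path(config, paste0(nm, ".asc")))
  }
  diag <- data.frame(pixel = seq_along(res$fit$r2),
                     r2 = c(res$fit$r2), n_obs = c(res$fit$n_obs),
                     reason = c(res$fit$reason))
  write.csv(diag, artifact_path(config, "resilience_diagnostics.csv"), row.names = FALSE)
  write_manifest(config, "resilience", config$resilience,
                 c("cube.rds", "type_mask.asc"),
                 c("ri.asc", "si.asc", "a_norm.asc", "b_norm.asc", "c_norm.asc",
                   "resilience_diagnostics.csv"))
  invisible(res)
}

stage_pressure <- function(config) {
  grazing <- read_ascii_grid(require_artifact(config, "grazing.asc", "simulate"))
  tem <- read_ascii_grid(require_artifact(config, "tem_mean.asc", "simulate"))
  pre <- read_ascii_grid(require_artifact(config, "pre_mean.asc", "simulate"))
  mask <- read_type_mask(config)
  ps <- pressure_surface(grazing, tem, pre, mask,
                         directions = config$pressure$directions,
                         weights = config$pressure$weights)
  write_ascii_grid(ps$pressure, artifact_path(config, "pressure.asc"))
  write_manifest(config, "pressure", config$pressure,
                 c("grazing.asc", "tem_mean.asc", "pre_mean.asc", "type_mask.asc"),
                 "pressure.asc")
  invisible(ps)
}

# classify one criterion raster per grassland type with its own breaks
classify_per_type <- function(raster, mask, max_exact, seed) {
  out <- matrix(NA_character_, nrow(raster), ncol(raster))
  brk <- list()
  for (ty in intersect(c("AM", "AS"), unique(c(mask)))) {
    sel <- mask == ty & !is.na(raster)
    b <- jenks_breaks(raster[sel], 3, max_exact = max_exact, sample_seed = seed)
    cls <- classify_three(raster, b)
    out[sel] <- cls[sel]
    brk[[ty]] <- b
  }
  attr(out, "levels") <- c("low", "moderate", "high")
  list(classified = out, breaks = brk)
}

stage_zone <- function(config) {
  quality <- read_ascii_grid(require_artifact(config, "regional_gqi.asc", "regional"))
  ri <- read_ascii_grid(require_artifact(config, "ri.asc", "resilience"))
  pressure <- read_ascii_grid(require_artifact(config, "pressure.asc", "pressure"))
  mask <- read_type_mask(config)
  seed <- config$seed + 401L
  q <- classify_per_type(quality, mask, config$zoning$max_exact, seed)
  r <- classify_per_type(ri, mask, config$zoning$max_exact, seed)
  p <- classify_per_type(pressure, mask, config$zoning$max_exact, seed)
  zones <- overlay_zones(q$classified, r$classified, p$classified)
  codes <- matrix(zone_codes()[zones], nrow(zones), ncol(zones))
  codes[is.na(codes)] <- 0L
  write_ascii_grid(codes, artifact_path(config, "zones.asc"))
  class_frac <- rbind(
    cbind(criterion = "quality", area_fractions(q$classified, mask)),
    cbind(criterion = "resilience", area_fractions(r$classified, mask)),
    cbind(criterion = "pressure", area_fractions(p$classified, mask)))
  write.csv(class_frac, artifact_path(config, "class_fractions.csv"), row.names = FALSE)
  zone_frac <- area_fractions(zones, mask)
  write.csv(zone_frac, artifact_path(config, "zone_fractions.csv"), row.names = FALSE)
  breaks_report <- lapply(list(quality = q, resilience = r, pressure = p),
                          function(cr) lapply(cr$breaks, function(b) {
                            list(thresholds = b$breaks, gvf = b$gvf, method = b$method)
                          }))
  jsonlite::write_json(c(breaks_report, list(zone_codes = as.list(zone_codes()))),
                       artifact_path(config, "breaks.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "zone", config$zoning,
                 c("regional_gqi.asc", "ri.asc", "pressure.asc", "type_mask.asc"),
                 c("zones.asc", "class_fractions.csv", "zone_fractions.csv",
                   "breaks.json"))
  invisible(list(zones = zones, class_fractions = class_frac,
                 zone_fractions = zone_frac))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `plot-gqi`, `landscape`, `regional`, `resilience`,
#' `pressure`, `zone`, `report`. Each stage reads its upstream artifacts
#' from `config$out_dir` (failing with the name of the stage to run first if
#' they are missing), writes its outputs there, and records a JSON manifest
#' with parameters, seed and MD5 checksums.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the stage's main result, invisibly.
#' @export
run_stage <- function(name, config) {
  switch(match.arg(name, stage_order),
         "simulate" = stage_simulate(config),
         "plot-gqi" = stage_plot_gqi(config),
         "landscape" = stage_landscape(config),
         "regional" = stage_regional(config),
         "resilience" = stage_resilience(config),
         "pressure" = stage_pressure(config),
         "zone" = stage_zone(config),
         "report" = zoning_report(config))
}

#' Run the whole pipeline
#'
#' Chains simulate, plot-gqi, landscape, regional, resilience, pressure and
#' zone on one configuration.
#'
#' @param config a [pipeline_config()].
#' @param report print the final summary (default TRUE).
#' @return list of stage results, invisibly.
#' @export
run_all <- function(config, report = TRUE) {
  res <- list()
  for (st in setdiff(stage_order, "report")) res[[st]] <- run_stage(st, config)
  if (report) zoning_report(config)
  invisible(res)
}

#' Print the per-type classification and zoning summary
#'
#' Regenerates the human-readable summary from the saved stage artifacts:
#' low/moderate/high fractions of each criterion, the five-zone area
#' fractions per grassland type, break diagnostics (GVF) and the
#' landscape/regional model fits.
#'
#' @param config a [pipeline_config()] whose `zone` stage has run.
#' @return list with `class_fractions` and `zone_fractions`, invisibly.
#' @export
zoning_report <- function(config) {
  cf <- read.csv(require_artifact(config, "class_fractions.csv", "zone"),
                 stringsAsFactors = FALSE)
  zf <- read.csv(require_artifact(config, "zone_fractions.csv", "zone"),
                 stringsAsFactors = FALSE)
  lm_js <- jsonlite::read_json(require_artifact(config, "landscape_model.json", "landscape"))
  pl_js <- jsonlite::read_json(require_artifact(config, "plsr_model.json", "regional"))
  br <- jsonlite::read_json(require_artifact(config, "breaks.json", "zone"))
  cat("=== Grassland multi-criteria assessment summary ===\n")
  cat(sprintf("Landscape model: train R2 = %.3f, test R2 = %.3f (%d indices)\n",
              lm_js$train_r2, lm_js$test_r2, length(lm_js$selected_vis)))
  cat(sprintf("Regional PLSR: %d component(s), LOOCV R2 = %.3f\n",
              pl_js$n_components, pl_js$loocv_r2))
  for (ty in unique(cf$type)) {
    cat("\n--- Grassland type:", ty, "---\n")
    for (cr in unique(cf$criterion)) {
      sub <- cf[cf$type == ty & cf$criterion == cr, ]
      if (!nrow(sub)) { cat(sprintf("%-11s: absent\n", cr)); next }
      gvf <- br[[cr]][[ty]]$gvf
      cat(sprintf("%-11s: %s (GVF %.3f)\n", cr,
                  paste(sprintf("%s %.2f%%", sub$label, sub$percent), collapse = ", "),
                  if (is.null(gvf)) NA_real_ else gvf))
    }
    subz <- zf[zf$type == ty, ]
    if (nrow(subz)) {
      cat("zones      :",
          paste(sprintf("%s %.2f%%", subz$label, subz$percent), collapse = ", "), "\n")
    } else cat("zones      : absent\n")
  }
  invisible(list(class_fractions = cf, zone_fractions = zf))
}
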