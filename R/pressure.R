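#' Min-max standardize a pressure layer over masked pixels
#'
#' @param raster numeric matrix.
#' @param direction +1 (larger raw value = more pressure) or -1 (the scaled
#'   value is flipped to `1 - x`).
#' @param mask logical matrix of pixels forming the standardization
#'   population (default: all non-nodata pixels).
#' @return matrix in \[0, 1\] over masked pixels, `NA` elsewhere.
#' @export
standardize_layer <- function(raster, direction = 1, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(raster)
  stop_if_grid_mismatch(raster, mask)
  v <- raster[mask]
  v <- v[!is.na(v)]
  if (length(unique(v)) < 2) stop("constant layer over the mask: cannot standardize")
  out <- matrix(NA_real_, nrow(raster), ncol(raster))
  sel <- mask & !is.na(raster)
  out[sel] <- (raster[sel] - min(v)) / (max(v) - min(v))
  if (direction < 0) out <- 1 - out
  out
}

#' Aggregate standardized pressure layers
#'
#' Standardizes each layer over the mask (honouring per-layer direction) and
#' combines them as a weighted mean (equal weights by default). Any nodata
#' input propagates to the output.
#'
#' @param layers named list of congruent rasters (e.g. grazing, tem, pre).
#' @param directions per-layer +1/-1 vector (recycled).
#' @param weights nonnegative per-layer weights; normalized to sum to 1.
#' @param mask logical population mask (default: pixels valid in all
#'   layers).
#' @return pressure matrix in \[0, 1\].
#' @export
aggregate_pressure <- function(layers, directions = 1,
                               weights = rep(1, length(layers)), mask = NULL) {
  do.call(stop_if_grid_mismatch, layers)
  if (any(weights < 0) || sum(weights) == 0) stop("weights must be nonnegative and not all zero")
  weights <- weights / sum(weights)
  directions <- rep_len(directions, length(layers))
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  }
  std <- Map(standardize_layer, layers, directions, MoreArgs = list(mask = mask))
  Reduce(`+`, Map(`*`, std, weights))
}

#' Per-type pressure surface from grazing and climate layers
#'
#' Standardizes and aggregates the three layers separately within the
#' alpine-meadow and alpine-steppe populations, then assembles one combined
#' surface.
#'
#' @param grazing,tem_mean,pre_mean input rasters.
#' @param type_mask character matrix over {"AM", "AS", "other"}.
#' @param directions +1/-1 per layer, order (grazing, temperature,
#'   precipitation). All +1 by default (literal reading: larger values =
#'   more pressure); `pressure_preset_drought()` offers (+1, +1, -1).
#' @param weights per-layer weights, equal by default.
#' @return list with `pressure` (combined matrix, `NA` outside AM/AS).
#' @export
pressure_surface <- function(grazing, tem_mean, pre_mean, type_mask,
                             directions = c(1, 1, 1), weights = rep(1, 3)) {
  stop_if_grid_mismatch(grazing, tem_mean, pre_mean, type_mask)
  layers <- list(grazing = grazing, tem = tem_mean, pre = pre_mean)
  out <- matrix(NA_real_, nrow(type_mask), ncol(type_mask))
  for (ty in intersect(c("AM", "AS"), unique(c(type_mask)))) {
    mask <- type_mask == ty
    agg <- aggregate_pressure(layers, directions, weights, mask = mask)
    out[mask] <- agg[mask]
  }
  list(pressure = out)
}

#' Direction preset treating low precipitation as pressure
#' @return named direction vector for [pressure_surface()].
#' @export
pressure_preset_drought <- function() c(grazing = 1, tem = 1, pre = -1)
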