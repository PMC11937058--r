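#' Usable lag pairs for the monthly growing-season recursion
#'
#' Growing seasons run May-September; with the default `"within_season"`
#' rule a month is paired with its predecessor only when both fall in the
#' same growing season (June..September paired with the previous month; May
#' serves only as a lag source), because the month preceding May is eight
#' calendar months away. `"naive"` pairs every consecutive index.
#'
#' @param month_index data.frame with `year` and `month` columns.
#' @param lag_rule `"within_season"` (default) or `"naive"`.
#' @return integer vector of time indices `t` usable as responses (each with
#'   lag `t - 1`).
#' @export
lag_pairs <- function(month_index, lag_rule = c("within_season", "naive")) {
  lag_rule <- match.arg(lag_rule)
  t_all <- seq_len(nrow(month_index))[-1]
  if (lag_rule == "naive") return(t_all)
  same_season <- month_index$year[t_all] == month_index$year[t_all - 1] &
    month_index$month[t_all] == month_index$month[t_all - 1] + 1
  t_all[same_season]
}

#' Fit the lagged climate regression per pixel
#'
#' Per pixel, ordinary least squares of `LAI_t` on temperature and
#' precipitation of the same month and LAI of the previous month:
#' `LAI_t = a*tem_t + b*pre_t + c*LAI_(t-1) + k`, with `k` the intercept.
#' Pixels with fewer than `min_pairs` usable lag pairs, or a singular design
#' (constant regressor), are set to nodata with a reason code.
#'
#' @param cube a `climate_cube` (arrays `lai`, `tem`, `pre` of dim
#'   c(rows, cols, time) plus `month_index`).
#' @param min_pairs minimum usable (t, t-1) pairs per pixel.
#' @param lag_rule see [lag_pairs()].
#' @return list of class `resilience_fit` with matrices `a`, `b`, `c`, `k`,
#'   `r2`, `n_obs` and character matrix `reason` (`"ok"`, `"too_few_pairs"`,
#'   `"singular"`).
#' @export
fit_pixel_ar <- function(cube, min_pairs = 30, lag_rule = "within_season") {
  dims <- dim(cube$lai)
  nr <- dims[1]; nc <- dims[2]; nt <- dims[3]
  ts <- lag_pairs(cube$month_index, lag_rule)
  npix <- nr * nc
  lai <- matrix(cube$lai, npix, nt)
  tem <- matrix(cube$tem, npix, nt)
  pre <- matrix(cube$pre, npix, nt)
  out <- replicate(6, matrix(NA_real_, nr, nc), simplify = FALSE)
  names(out) <- c("a", "b", "c", "k", "r2", "n_obs")
  reason <- matrix("ok", nr, nc)
  if (length(ts) < min_pairs) {
    reason[] <- "too_few_pairs"
    out$reason <- reason
    return(structure(out, class = "resilience_fit"))
  }
  for (p in seq_len(npix)) {
    yv <- lai[p, ts]
    Xp <- cbind(tem[p, ts], pre[p, ts], lai[p, ts - 1], 1)
    if (any(apply(Xp[, 1:3, drop = FALSE], 2, function(v) max(v) - min(v)) == 0)) {
      reason[p] <- "singular"
      next
    }
    fit <- lm.fit(Xp, yv)
    if (any(is.na(fit$coefficients))) { reason[p] <- "singular"; next }
    cf <- fit$coefficients
    out$a[p] <- cf[1]; out$b[p] <- cf[2]; out$c[p] <- cf[3]; out$k[p] <- cf[4]
    out$r2[p] <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
    out$n_obs[p] <- length(ts)
  }
  out$reason <- reason
  structure(out, class = "resilience_fit")
}

# Min-max normalize a coefficient raster within each grassland type.
normalize_by_type <- function(m, type_mask, what = "coefficient") {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (ty in intersect(c("AM", "AS"), unique(c(type_mask)))) {
    sel <- type_mask == ty & !is.na(m)
    v <- m[sel]
    if (length(v) < 2 || max(v) - min(v) <= 0) {
      stop("constant ", what, " field for type ", ty, ": normalization undefined")
    }
    out[sel] <- (v - min(v)) / (max(v) - min(v))
  }
  out
}

#' Min-max normalize fitted coefficients per grassland type
#'
#' Transforms each of the fitted `a`, `b`, `c` rasters to \[0, 1\]
#' separately within the alpine-meadow and alpine-steppe populations, as the
#' per-type classification downstream requires.
#'
#' @param fit a [fit_pixel_ar()] result.
#' @param type_mask character matrix over {"AM", "AS", "other"}.
#' @return list of matrices `a_norm`, `b_norm`, `c_norm`.
#' @export
normalize_coefficients <- function(fit, type_mask) {
  stop_if_grid_mismatch(fit$a, type_mask)
  list(a_norm = normalize_by_type(fit$a, type_mask, "a"),
       b_norm = normalize_by_type(fit$b, type_mask, "b"),
       c_norm = normalize_by_type(fit$c, type_mask, "c"))
}

#' Climate-sensitivity components from simple linear fits
#'
#' Per pixel and per climate variable, LAI is regressed on that variable
#' alone; the raw sensitivity is one minus the residual-variance ratio,
#' i.e. the R-squared of the fit (equivalently the squared Pearson
#' correlation). Raw sensitivities are then min-max scaled to \[0, 1\]
#' within each grassland type.
#'
#' @param cube a `climate_cube`.
#' @param type_mask type raster for the per-type scaling.
#' @param scale set `FALSE` to return the raw (unscaled) R-squared surfaces.
#' @return list with `sens_tem`, `sens_pre` matrices.
#' @export
sensitivity_components <- function(cube, type_mask = NULL, scale = TRUE) {
  dims <- dim(cube$lai)
  npix <- dims[1] * dims[2]
  lai <- matrix(cube$lai, npix, dims[3])
  raw <- function(x) {
    xm <- matrix(x, npix, dims[3])
    r <- vapply(seq_len(npix), function(p) {
      if (sd(lai[p, ]) == 0) return(NA_real_)
      if (sd(xm[p, ]) == 0) return(0)
      cor(lai[p, ], xm[p, ])^2
    }, 0)
    matrix(r, dims[1], dims[2])
  }
  st <- raw(cube$tem); sp <- raw(cube$pre)
  if (scale) {
    if (is.null(type_mask)) stop("type_mask needed to scale sensitivities per type")
    st <- normalize_by_type(st, type_mask, "sens(tem)")
    sp <- normalize_by_type(sp, type_mask, "sens(pre)")
  }
  list(sens_tem = st, sens_pre = sp)
}

#' Sensitivity index surface
#'
#' Pixelwise `SI = a_norm * sens(tem) + b_norm * sens(pre)`; with all inputs
#' in \[0, 1\] the range is within \[0, 2\].
#'
#' @param a_norm,b_norm normalized temperature/precipitation coefficients.
#' @param sens result of [sensitivity_components()] (or a list with
#'   `sens_tem`, `sens_pre`).
#' @return SI matrix.
#' @export
compute_si <- function(a_norm, b_norm, sens) {
  stop_if_grid_mismatch(a_norm, b_norm, sens$sens_tem, sens$sens_pre)
  a_norm * sens$sens_tem + b_norm * sens$sens_pre
}

#' Resilience index surface
#'
#' `RI = 1 - c_norm`: the smaller the (normalized) carry-over of last
#' month's LAI, the faster the ecosystem returns to its climate-driven state
#' after a disturbance.
#'
#' @param c_norm normalized lag-coefficient raster in \[0, 1\].
#' @return RI matrix.
#' @export
compute_ri <- function(c_norm) 1 - c_norm

#' Full resilience/sensitivity assessment of a climate cube
#'
#' Convenience wrapper: per-pixel lagged regression, per-type coefficient
#' normalization, sensitivity components, SI and RI surfaces.
#'
#' @param cube a `climate_cube`.
#' @param type_mask grassland-type raster.
#' @param ... passed to [fit_pixel_ar()].
#' @return list with `fit`, `a_norm`, `b_norm`, `c_norm`, `sens`, `si`, `ri`.
#' @export
resilience_surfaces <- function(cube, type_mask, ...) {
  fit <- fit_pixel_ar(cube, ...)
  norm <- normalize_coefficients(fit, type_mask)
  sens <- sensitivity_components(cube, type_mask)
  si <- compute_si(norm$a_norm, norm$b_norm, sens)
  ri <- compute_ri(norm$c_norm)
  c(list(fit = fit), norm, list(sens = sens, si = si, ri = ri))
}
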