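#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification minimizing the within-class sum of squared
#' deviations, computed by exact dynamic programming on the sorted values.
#' Inputs larger than `max_exact` are reduced to a deterministic random
#' sample of `max_exact` values (method tag `"sampled"`); the exact DP runs
#' on the sample and the resulting thresholds apply to the full data.
#'
#' @param values numeric vector (NAs dropped).
#' @param n_classes number of classes (default 3).
#' @param max_exact largest n handled exactly.
#' @param sample_seed seed for the deterministic sample when n > max_exact.
#' @return object of class `jenks_breaks`: `breaks` (the `n_classes - 1`
#'   interior thresholds, each the upper value of a class), `gvf` (goodness
#'   of variance fit, `1 - SSW/SST`), `method` (`"exact"`/`"sampled"`),
#'   `n_classes`.
#' @export
jenks_breaks <- function(values, n_classes = 3, max_exact = 10000L,
                         sample_seed = 1L) {
  x <- values[!is.na(values)]
  if (length(unique(x)) < n_classes) {
    stop("need at least ", n_classes, " distinct values for ", n_classes, " classes")
  }
  method <- "exact"
  xs <- x
  if (length(xs) > max_exact) {
    method <- "sampled"
    set.seed(sample_seed)
    xs <- sample(xs, max_exact)
    if (length(unique(xs)) < n_classes) xs <- c(xs, range(x))
  }
  xs <- sort(xs)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  # SS of xs[i..j], vectorized over i for fixed j
  ss_to <- function(i, j) {
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    s2 - s^2 / (j - i + 1)
  }
  # D[m, j]: minimal SSW partitioning xs[1..j] into m classes
  D <- matrix(Inf, n_classes, n)
  pos <- matrix(0L, n_classes, n)       # start index of the last class
  D[1, ] <- vapply(seq_len(n), function(j) ss_to(1L, j), 0)
  for (m in 2:n_classes) {
    for (j in m:n) {
      i <- m:j                           # last class is xs[i..j]
      tot <- D[m - 1, i - 1] + ss_to(i, j)
      best <- which.min(tot)
      D[m, j] <- tot[best]
      pos[m, j] <- i[best]
    }
  }
  # recover class upper boundaries
  uppers <- numeric(n_classes - 1)
  j <- n
  for (m in n_classes:2) {
    i <- pos[m, j]
    uppers[m - 1] <- xs[i - 1]
    j <- i - 1L
  }
  sst <- sum((x - mean(x))^2)
  lab <- findInterval(x, uppers, left.open = TRUE) + 1L  # x <= t1 -> class 1
  ssw <- sum(unlist(lapply(split(x, lab), function(v) sum((v - mean(v))^2))))
  structure(list(breaks = uppers, gvf = if (sst > 0) 1 - ssw / sst else 1,
                 method = method, n_classes = n_classes),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat("Jenks natural breaks (", x$method, "): thresholds ",
      paste(signif(x$breaks, 6), collapse = ", "),
      "; GVF = ", round(x$gvf, 4), "\n", sep = "")
  invisible(x)
}

#' Classify a criterion raster into three ordered classes
#'
#' Boundary convention: intervals are closed on the right of each break,
#' i.e. `x <= t1` is low, `t1 < x <= t2` moderate, `x > t2` high. Nodata is
#' preserved.
#'
#' @param raster numeric matrix.
#' @param breaks a [jenks_breaks()] result (3 classes) or numeric c(t1, t2).
#' @param labels class labels, low to high.
#' @return character matrix of labels with `labels` attached as attribute
#'   `levels`.
#' @export
classify_three <- function(raster, breaks, labels = c("low", "moderate", "high")) {
  if (inherits(breaks, "jenks_breaks")) breaks <- breaks$breaks
  if (length(breaks) != length(labels) - 1) {
    stop("number of labels does not match the break count")
  }
  idx <- findInterval(raster, breaks, left.open = TRUE) + 1L
  out <- matrix(labels[idx], nrow(raster), ncol(raster))
  out[is.na(raster)] <- NA
  attr(out, "levels") <- labels
  out
}

#' Zone codes of the adaptive-management overlay
#'
#' Integer code table used when zone maps are written as rasters:
#' 1 = LQZ (Low-Quality Zone), 2 = QILZ (Quality Improvement-Limited Zone),
#' 3 = QRPZ (Quality Restoration Potential Zone), 4 = HQSZ (High-Quality
#' Stable Zone), 5 = HQPZ (High-Quality Pressure Zone).
#'
#' @return named integer vector.
#' @export
zone_codes <- function() c(LQZ = 1L, QILZ = 2L, QRPZ = 3L, HQSZ = 4L, HQPZ = 5L)

#' Overlay classified quality, resilience and pressure into five zones
#'
#' Rule table: low quality is LQZ regardless of the other criteria; moderate
#' quality splits on resilience (low/moderate resilience = QILZ, high
#' resilience = QRPZ); high quality splits on pressure (low pressure = HQSZ,
#' moderate/high pressure = HQPZ). Every pixel classified in all three
#' inputs receives exactly one zone.
#'
#' @param quality,resilience,pressure congruent character matrices with
#'   labels in {"low", "moderate", "high"}.
#' @return character matrix over {"LQZ", "QILZ", "QRPZ", "HQSZ", "HQPZ"}.
#' @export
overlay_zones <- function(quality, resilience, pressure) {
  stop_if_grid_mismatch(quality, resilience, pressure)
  lv <- c("low", "moderate", "high")
  for (m in list(quality, resilience, pressure)) {
    if (!all(m[!is.na(m)] %in% lv)) {
      stop("classified inputs must use labels low/moderate/high")
    }
  }
  out <- matrix(NA_character_, nrow(quality), ncol(quality))
  ok <- !is.na(quality) & !is.na(resilience) & !is.na(pressure)
  out[ok & quality == "low"] <- "LQZ"
  out[ok & quality == "moderate" & resilience %in% c("low", "moderate")] <- "QILZ"
  out[ok & quality == "moderate" & resilience == "high"] <- "QRPZ"
  out[ok & quality == "high" & pressure == "low"] <- "HQSZ"
  out[ok & quality == "high" & pressure %in% c("moderate", "high")] <- "HQPZ"
  attr(out, "levels") <- names(zone_codes())
  out
}

#' Area fractions of a categorical raster per grassland type
#'
#' @param classified character matrix of labels (zones or classes).
#' @param type_mask congruent character matrix over {"AM", "AS", "other"};
#'   `NULL` pools everything under type `"all"`.
#' @param levels label order for the output; defaults to the matrix's
#'   `levels` attribute or the sorted unique labels.
#' @return data.frame (type, label, count, percent) with percentages of the
#'   type's classified pixels rounded to 2 decimals; types with no
#'   classified pixels are omitted.
#' @export
area_fractions <- function(classified, type_mask = NULL, levels = NULL) {
  if (is.null(type_mask)) {
    type_mask <- matrix("all", nrow(classified), ncol(classified))
  }
  stop_if_grid_mismatch(classified, type_mask)
  if (is.null(levels)) {
    levels <- attr(classified, "levels")
    if (is.null(levels)) levels <- sort(unique(c(classified[!is.na(classified)])))
  }
  res <- list()
  for (ty in sort(unique(c(type_mask[type_mask %in% c("AM", "AS", "all")])))) {
    lab <- classified[type_mask == ty]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) next
    counts <- table(factor(lab, levels = levels))
    res[[ty]] <- data.frame(type = ty, label = levels,
                            count = as.integer(counts),
                            percent = round(100 * as.integer(counts) / length(lab), 2),
                            stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no classified pixels in any type population")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
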