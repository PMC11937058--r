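#' Write a matrix as an ESRI ASCII grid
#'
#' Rasters in this package are plain numeric matrices (row 1 = northernmost
#' row, `NA` = nodata). The ESRI ASCII grid format is a simple, widely read
#' plain-text raster exchange format; it is the package's on-disk raster
#' representation.
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @param cellsize cell edge length in map units.
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata value written for `NA` cells.
#' @param digits significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1, xll = 0, yll = 0,
                             nodata = -9999, digits = 10) {
  stopifnot(is.matrix(m))
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  vals <- m
  vals[is.na(vals)] <- nodata
  body <- apply(formatC(vals, format = "g", digits = digits), 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a matrix
#'
#' @param path file written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @return numeric matrix with nodata cells set to `NA`; cellsize and corner
#'   coordinates attached as attributes `cellsize`, `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- h[["cellsize"]]
  attr(m, "xll") <- h[["xllcorner"]]
  attr(m, "yll") <- h[["yllcorner"]]
  m
}

#' Min-max rescale a vector to [0, 1]
#'
#' @param x numeric vector (NAs allowed).
#' @param from optional c(min, max) to standardize against; defaults to the
#'   observed range of `x`.
#' @return rescaled vector.
#' @keywords internal
minmax_rescale <- function(x, from = range(x, na.rm = TRUE)) {
  if (!is.finite(from[1]) || !is.finite(from[2]) || from[2] <= from[1]) {
    stop("min-max rescaling needs at least two distinct finite values")
  }
  (x - from[1]) / (from[2] - from[1])
}

#' Gaussian smoothing of a matrix (separable kernel, renormalized edges)
#'
#' Truncated at three standard deviations; edge cells renormalize by the
#' in-bounds kernel mass so the filter has no boundary bias.
#'
#' @param m numeric matrix (no NAs).
#' @param sigma kernel standard deviation in cells.
#' @return smoothed matrix of the same shape.
#' @keywords internal
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  smooth_1d <- function(mat) { # along columns of mat
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * mat[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(m))))
}

#' Lag-1 spatial autocorrelation of a raster
#'
#' Direct-summation analogue of Moran's I for a rook-contiguity lag of one
#' cell: the Pearson correlation between cell values and their horizontal and
#' vertical neighbours, pooled.
#'
#' @param m numeric matrix.
#' @return scalar correlation.
#' @export
lag1_autocorrelation <- function(m) {
  a <- c(m[, -ncol(m)], m[-nrow(m), ])
  b <- c(m[, -1], m[-1, ])
  ok <- !is.na(a) & !is.na(b)
  cor(a[ok], b[ok])
}

stop_if_grid_mismatch <- function(...) {
  dims <- lapply(list(...), dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("rasters are not on a congruent grid")
  }
  invisible(TRUE)
}
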