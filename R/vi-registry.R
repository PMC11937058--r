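#' Vegetation-index registry for five-band (B, G, R, RE, NIR) imagery
#'
#' Returns the built-in registry of canonical multispectral vegetation
#' indices, each an arithmetic combination of the blue, green, red, red-edge
#' and near-infrared reflectance bands. Every entry carries the formula both
#' as an R function and as a human-readable string; users can extend the
#' candidate set by passing extra entries of the same shape to
#' [compute_vis()].
#'
#' Divisions are guarded downstream: non-finite results become nodata.
#'
#' @return named list; each element has `fun(B, G, R, RE, NIR)` and
#'   `formula` (string).
#' @export
vi_registry <- function() {
  def <- function(formula) {
    list(fun = eval(parse(text = paste("function(B, G, R, RE, NIR)", formula))),
         formula = formula)
  }
  list(
    NDVI        = def("(NIR - R) / (NIR + R)"),
    GNDVI       = def("(NIR - G) / (NIR + G)"),
    NDRE        = def("(NIR - RE) / (NIR + RE)"),
    EVI         = def("2.5 * (NIR - R) / (NIR + 6 * R - 7.5 * B + 1)"),
    EVI2        = def("2.5 * (NIR - R) / (NIR + 2.4 * R + 1)"),
    SAVI        = def("1.5 * (NIR - R) / (NIR + R + 0.5)"),
    OSAVI       = def("1.16 * (NIR - R) / (NIR + R + 0.16)"),
    MSAVI       = def("(2 * NIR + 1 - sqrt((2 * NIR + 1)^2 - 8 * (NIR - R))) / 2"),
    RVI         = def("NIR / R"),
    DVI         = def("NIR - R"),
    GDVI        = def("NIR - G"),
    CIgreen     = def("NIR / G - 1"),
    CIrededge   = def("NIR / RE - 1"),
    MCARI       = def("((RE - R) - 0.2 * (RE - G)) * (RE / R)"),
    TCARI       = def("3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))"),
    TCARI_OSAVI = def("(3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))) / (1.16 * (NIR - R) / (NIR + R + 0.16))"),
    NGRDI       = def("(G - R) / (G + R)"),
    VARI        = def("(G - R) / (G + R - B)"),
    ExG         = def("2 * G - R - B"),
    ExR         = def("1.4 * R - G"),
    ExGR        = def("(2 * G - R - B) - (1.4 * R - G)"),
    GLI         = def("(2 * G - R - B) / (2 * G + R + B)"),
    RGBVI       = def("(G^2 - B * R) / (G^2 + B * R)"),
    TVI         = def("sqrt((NIR - R) / (NIR + R) + 0.5)"),
    MTVI2       = def("1.5 * (1.2 * (NIR - G) - 2.5 * (R - G)) / sqrt((2 * NIR + 1)^2 - (6 * NIR - 5 * sqrt(R)) - 0.5)"),
    SIPI        = def("(NIR - B) / (NIR - R)"),
    PSRI        = def("(R - G) / RE"),
    GRVI        = def("G / R"),
    WDRVI       = def("(0.2 * NIR - R) / (0.2 * NIR + R)"),
    NLI         = def("(NIR^2 - R) / (NIR^2 + R)"),
    RDVI        = def("(NIR - R) / sqrt(NIR + R)"),
    MSR         = def("(NIR / R - 1) / sqrt(NIR / R + 1)"),
    GOSAVI      = def("(NIR - G) / (NIR + G + 0.16)"),
    NDWI        = def("(G - NIR) / (G + NIR)"),
    LCI         = def("(NIR - RE) / (NIR + R)"),
    NAVI        = def("1 - R / NIR"),
    ARVI        = def("(NIR - (2 * R - B)) / (NIR + (2 * R - B))")
  )
}

#' Compute vegetation-index rasters from a five-band scene
#'
#' @param scene named list of congruent matrices `B`, `G`, `R`, `RE`, `NIR`
#'   with reflectance in \[0, 1\] (`NA` = nodata).
#' @param indices character vector of registry names (default: all), or a
#'   registry-shaped named list for custom indices.
#' @return named list of index rasters; cells where a formula is undefined
#'   (zero denominators, negative radicands) are nodata.
#' @export
compute_vis <- function(scene, indices = NULL) {
  stopifnot(all(c("B", "G", "R", "RE", "NIR") %in% names(scene)))
  do.call(stop_if_grid_mismatch, scene[c("B", "G", "R", "RE", "NIR")])
  reg <- vi_registry()
  if (is.null(indices)) indices <- names(reg)
  if (is.list(indices)) {
    reg <- indices
    indices <- names(indices)
  }
  unknown <- setdiff(indices, names(reg))
  if (length(unknown)) stop("unknown vegetation index: ", paste(unknown, collapse = ", "))
  out <- lapply(indices, function(nm) {
    v <- suppressWarnings(
      reg[[nm]]$fun(scene$B, scene$G, scene$R, scene$RE, scene$NIR))
    v[!is.finite(v)] <- NA
    v
  })
  names(out) <- indices
  out
}

#' Extract per-plot vegetation-index means over footprints
#'
#' @param vi_rasters named list of congruent index rasters (from
#'   [compute_vis()]).
#' @param footprints data.frame with plot_id, row0, col0, nrows, ncols
#'   (0-based, half-open windows into the rasters).
#' @return data.frame (one row per plot) of footprint means ignoring nodata;
#'   plots whose footprint is entirely nodata in any index are dropped with
#'   a warning.
#' @export
extract_plot_vis <- function(vi_rasters, footprints) {
  do.call(stop_if_grid_mismatch, vi_rasters)
  dims <- dim(vi_rasters[[1]])
  rows <- lapply(seq_len(nrow(footprints)), function(i) {
    fp <- footprints[i, ]
    r <- (fp$row0 + 1):(fp$row0 + fp$nrows)
    cl <- (fp$col0 + 1):(fp$col0 + fp$ncols)
    if (max(r) > dims[1] || max(cl) > dims[2] || fp$row0 < 0 || fp$col0 < 0) {
      stop("footprint outside raster bounds for plot ", fp$plot_id)
    }
    vapply(vi_rasters, function(m) mean(m[r, cl], na.rm = TRUE), 0)
  })
  tab <- cbind(data.frame(plot_id = footprints$plot_id, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  bad <- apply(is.na(tab[-1]) | is.nan(as.matrix(tab[-1])), 1, any)
  if (any(bad)) {
    warning("dropping plot(s) with fully-nodata footprint: ",
            paste(tab$plot_id[bad], collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  tab
}

#' Build the plot x vegetation-index table from per-plot scenes
#'
#' Convenience wrapper for surveys where each plot has its own UAV scene:
#' computes the index rasters per scene and averages them over that plot's
#' footprint.
#'
#' @param scenes named list (by plot_id) of five-band scenes.
#' @param footprints footprint table as in [extract_plot_vis()]; windows are
#'   interpreted within each plot's own scene.
#' @param indices registry subset (default all).
#' @return data.frame: plot_id plus one column per index.
#' @export
build_vi_table <- function(scenes, footprints, indices = NULL) {
  rows <- lapply(footprints$plot_id, function(pid) {
    vis <- compute_vis(scenes[[pid]], indices)
    extract_plot_vis(vis, footprints[footprints$plot_id == pid, , drop = FALSE])
  })
  do.call(rbind, rows)
}
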