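#' Default indicator polarity
#'
#' Positive polarity means larger raw values indicate better grassland
#' condition. Bulk density (compaction) and pH distance from neutral are
#' treated as negative polarity: the pH column is first mapped to
#' `|pH - 7|` and both are inverted before scaling, so after standardization
#' larger always means better.
#'
#' @return named vector of +1/-1 over the 14 indicators.
#' @export
default_polarity <- function() {
  p <- setNames(rep(1, length(indicator_names())), indicator_names())
  p[c("bulk_density", "ph")] <- -1
  p
}

orient_indicator <- function(x, name, polarity) {
  if (name == "ph" && polarity[[name]] < 0) x <- abs(x - 7)
  if (polarity[[name]] < 0) x <- -x
  x
}

#' Standardize plot indicators to [0, 1]
#'
#' Min-max standardization (the default) maps each oriented indicator column
#' to \[0, 1\] and stores the (min, max) pair for reuse on new data; negative
#' polarity columns are inverted (and pH replaced by its distance from 7)
#' before scaling. A z-score option is provided for sensitivity analyses but
#' does not bound the result.
#'
#' @param table plot table containing the indicator columns.
#' @param method "minmax" (default) or "zscore".
#' @param indicators columns to standardize; defaults to all 14.
#' @param polarity named +1/-1 vector, see [default_polarity()].
#' @return list of class `std_indicators`: `table` (standardized columns plus
#'   plot_id/grassland_type), `params` (per-column method, polarity and
#'   (min, max) or (mean, sd)).
#' @export
standardize_indicators <- function(table, method = c("minmax", "zscore"),
                                   indicators = indicator_names(),
                                   polarity = default_polarity()) {
  method <- match.arg(method)
  if (nrow(table) < 3) stop("need at least 3 plots to standardize")
  missing_cols <- setdiff(indicators, names(table))
  if (length(missing_cols)) {
    stop("missing indicator column(s): ", paste(missing_cols, collapse = ", "))
  }
  polarity <- polarity[indicators]
  polarity[is.na(polarity)] <- 1
  names(polarity) <- indicators
  out <- table[intersect(c("plot_id", "grassland_type"), names(table))]
  params <- list()
  for (nm in indicators) {
    x <- table[[nm]]
    if (!is.numeric(x)) stop("indicator column is not numeric: ", nm)
    v <- orient_indicator(x, nm, polarity)
    if (max(v) - min(v) <= 0) stop("constant indicator column: ", nm)
    if (method == "minmax") {
      prm <- list(method = method, polarity = polarity[[nm]],
                  min = min(v), max = max(v))
      out[[nm]] <- (v - prm$min) / (prm$max - prm$min)
    } else {
      prm <- list(method = method, polarity = polarity[[nm]],
                  mean = mean(v), sd = sd(v))
      out[[nm]] <- (v - prm$mean) / prm$sd
    }
    params[[nm]] <- prm
  }
  structure(list(table = out, params = params), class = "std_indicators")
}

#' Apply stored standardization parameters to new data
#'
#' @param params `params` element of a [standardize_indicators()] result.
#' @param table plot table with the same indicator columns.
#' @return data.frame of standardized columns (plus id columns if present).
#' @export
apply_standardization <- function(params, table) {
  out <- table[intersect(c("plot_id", "grassland_type"), names(table))]
  for (nm in names(params)) {
    prm <- params[[nm]]
    v <- orient_indicator(table[[nm]], nm, setNames(prm$polarity, nm))
    out[[nm]] <- if (prm$method == "minmax") {
      (v - prm$min) / (prm$max - prm$min)
    } else {
      (v - prm$mean) / prm$sd
    }
  }
  out
}

#' Select indicators and derive convex weights by PCA
#'
#' Runs a correlation-matrix PCA of the standardized indicator table (unit
#' variance scaling inside the PCA, so the Kaiser eigenvalue-greater-than-one
#' rule applies). Components with eigenvalue above `eigen_threshold` are
#' retained; loadings are component correlations (eigenvector times the
#' component standard deviation) and an indicator is selected when its
#' maximum absolute loading across retained components reaches
#' `loading_threshold`. Weights are proportional to the sum over retained
#' components of (component variance fraction x |loading|), normalized to
#' sum to one.
#'
#' @param std a [standardize_indicators()] result (or a plain data.frame of
#'   standardized indicator columns).
#' @param eigen_threshold minimum eigenvalue for a component to be retained.
#' @param loading_threshold minimum absolute loading for selection.
#' @return object of class `gqi_weights`: `selected_indicators`, `weights`
#'   (named, nonnegative, sum 1), `standardization` (parameter list if
#'   available) and `pca_report` (eigenvalues, variance fractions, retained
#'   components, loading matrix).
#' @export
pca_select_weights <- function(std, eigen_threshold = 1.0, loading_threshold = 0.5) {
  params <- NULL
  if (inherits(std, "std_indicators")) {
    params <- std$params
    tab <- std$table
  } else {
    tab <- std
  }
  X <- as.matrix(tab[vapply(tab, is.numeric, TRUE)])
  if (nrow(X) < 10) stop("need at least 10 plots for PCA weighting")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  varfrac <- eig / sum(eig)
  retained <- which(eig > eigen_threshold)
  if (!length(retained)) {
    stop("no principal component passes the eigenvalue threshold; eigenvalues: ",
         paste(signif(eig, 4), collapse = ", "))
  }
  loadings <- pc$rotation %*% diag(pc$sdev, length(eig))  # component correlations
  colnames(loadings) <- colnames(pc$rotation)
  L <- abs(loadings[, retained, drop = FALSE])
  selected <- rownames(L)[apply(L, 1, max) >= loading_threshold]
  if (!length(selected)) stop("no indicator reaches the loading threshold on a retained component")
  raw_w <- drop(L[selected, , drop = FALSE] %*% varfrac[retained])
  weights <- raw_w / sum(raw_w)
  structure(list(selected_indicators = selected,
                 weights = weights,
                 standardization = params,
                 pca_report = list(eigenvalues = eig,
                                   variance_fractions = varfrac,
                                   retained_components = retained,
                                   loadings = loadings)),
            class = "gqi_weights")
}

#' @export
print.gqi_weights <- function(x, ...) {
  cat("GQI weights (", length(x$selected_indicators), " indicators selected, ",
      length(x$pca_report$retained_components), " components retained)\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Score plots with the Grassland Quality Index
#'
#' The GQI of a plot is the weighted sum of its standardized selected
#' indicators; with min-max standardization and convex weights it lies in
#' \[0, 1\].
#'
#' @param std_table standardized table (the `table` element of
#'   [standardize_indicators()], or any data.frame with the selected
#'   columns).
#' @param weights a [pca_select_weights()] result.
#' @return data.frame with plot_id (if present) and `gqi`.
#' @export
compute_plot_gqi <- function(std_table, weights) {
  if (inherits(std_table, "std_indicators")) std_table <- std_table$table
  sel <- weights$selected_indicators
  missing_cols <- setdiff(sel, names(std_table))
  if (length(missing_cols)) {
    stop("missing selected indicator column(s): ", paste(missing_cols, collapse = ", "))
  }
  gqi <- as.matrix(std_table[sel]) %*% weights$weights[sel]
  out <- data.frame(gqi = drop(gqi))
  if ("plot_id" %in% names(std_table)) out <- cbind(std_table["plot_id"], out)
  if ("grassland_type" %in% names(std_table)) {
    out$grassland_type <- std_table$grassland_type
  }
  out
}
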