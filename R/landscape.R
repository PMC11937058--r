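#' Bidirectional stepwise-AIC variable selection
#'
#' Starts from the intercept-only model and, at each step, evaluates every
#' single-variable addition and deletion, applying the move that lowers the
#' AIC the most; the search stops when no move improves the AIC. Ties are
#' broken deterministically: deletions are preferred over additions, then
#' lexicographic variable name. Zero-variance candidates are dropped before
#' the search with a warning. AIC is computed as in [stats::extractAIC()]
#' (`n log(RSS/n) + 2p`), so results agree with [stats::step()].
#'
#' @param vi_table data.frame of candidate predictors (plot_id and other
#'   non-numeric columns are ignored).
#' @param y numeric response (e.g. plot-scale GQI), or a data.frame holding
#'   a `gqi` column aligned with `vi_table`.
#' @return list of class `stepwise_fit`: `selected` (in inclusion order),
#'   `fit` (the final `lm`), `aic`, `trace` (data.frame of moves).
#' @export
stepwise_aic <- function(vi_table, y) {
  if (is.data.frame(y)) y <- y$gqi
  X <- vi_table[setdiff(names(vi_table), c("plot_id", "grassland_type"))]
  X <- X[vapply(X, is.numeric, TRUE)]
  if (anyNA(X) || anyNA(y)) stop("missing values in candidates or response")
  keep <- vapply(X, function(v) sd(v) > 0, TRUE)
  if (any(!keep)) {
    warning("dropping zero-variance candidate(s): ",
            paste(names(X)[!keep], collapse = ", "))
    X <- X[keep]
  }
  n <- length(y)
  dat <- cbind(data.frame(.y = y), X)
  # floor the RSS at numerical noise relative to SST so a perfect fit does
  # not keep "improving" through meaningless sub-epsilon residual shrinkage
  rss_floor <- 1e-10 * max(sum((y - mean(y))^2), .Machine$double.xmin)
  aic_of <- function(vars) {
    f <- if (length(vars)) paste(".y ~", paste(vars, collapse = " + ")) else ".y ~ 1"
    fit <- lm(as.formula(f), data = dat)
    rss <- max(sum(residuals(fit)^2), rss_floor)
    list(aic = n * log(rss / n) + 2 * (length(vars) + 1), fit = fit)
  }
  current <- character(0)
  cur <- aic_of(current)
  trace <- list()
  repeat {
    drops <- sort(current)
    adds <- sort(setdiff(names(X), current))
    moves <- c(lapply(drops, function(v) list(op = "-", var = v, set = setdiff(current, v))),
               lapply(adds, function(v) list(op = "+", var = v, set = c(current, v))))
    if (!length(moves)) break
    aics <- vapply(moves, function(mv) aic_of(mv$set)$aic, 0)
    best <- which.min(aics)  # ties: drops precede adds, each lexicographic
    if (aics[best] >= cur$aic - 1e-10) break
    current <- moves[[best]]$set
    cur <- aic_of(current)
    trace[[length(trace) + 1L]] <- data.frame(op = moves[[best]]$op,
                                              variable = moves[[best]]$var,
                                              aic = cur$aic)
  }
  structure(list(selected = current, fit = cur$fit, aic = cur$aic,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(op = character(), variable = character(), aic = numeric())),
            class = "stepwise_fit")
}

#' Refine a stepwise-selected index set with random-forest importance
#'
#' Fits a 500-tree random forest on the stepwise-selected indices, measures
#' permutation importance (mean increase in training MSE over 10 fixed-seed
#' shuffles per variable), retains the indices whose importance exceeds the
#' mean importance (never emptying the set: if none exceed the mean, the
#' single most important index is kept), and refits an ordinary least squares
#' model on the retained set. The final landscape predictor is the OLS
#' regression, not the forest.
#'
#' @param vi_table candidate table as in [stepwise_aic()].
#' @param y response vector (or data.frame with `gqi`).
#' @param stepwise_set character vector of stepwise-selected indices; an
#'   empty set passes through to an intercept-only model.
#' @param seed integer seed controlling the forest and the shuffles.
#' @param ntree,nperm forest size and number of permutation shuffles.
#' @return object of class `landscape_model`: `selected_vis`,
#'   `coefficients` (incl. intercept), `aic`, `rf_importances`, `train_r2`,
#'   `fit` (the `lm`).
#' @export
rf_refine <- function(vi_table, y, stepwise_set, seed = 1L,
                      ntree = 500L, nperm = 10L) {
  if (is.data.frame(y)) y <- y$gqi
  X <- vi_table[setdiff(names(vi_table), c("plot_id", "grassland_type"))]
  finish <- function(retained, importances) {
    dat <- cbind(data.frame(.y = y), X[retained])
    f <- if (length(retained)) paste(".y ~", paste(retained, collapse = " + ")) else ".y ~ 1"
    fit <- lm(as.formula(f), data = dat)
    rss <- sum(residuals(fit)^2)
    n <- length(y)
    structure(list(selected_vis = retained,
                   coefficients = coef(fit),
                   aic = n * log(rss / n) + 2 * (length(retained) + 1),
                   rf_importances = importances,
                   train_r2 = 1 - rss / sum((y - mean(y))^2),
                   fit = fit),
              class = "landscape_model")
  }
  if (length(stepwise_set) <= 1L) {
    imp <- setNames(rep(NA_real_, length(stepwise_set)), stepwise_set)
    return(finish(stepwise_set, imp))
  }
  Xs <- as.matrix(X[stepwise_set])
  set.seed(seed)
  rf <- randomForest::randomForest(Xs, y, ntree = ntree)
  base_mse <- mean((predict(rf, Xs) - y)^2)
  imp <- vapply(seq_along(stepwise_set), function(j) {
    set.seed(seed + 1000L + j)
    mean(vapply(seq_len(nperm), function(s) {
      Xp <- Xs
      Xp[, j] <- sample(Xp[, j])
      mean((predict(rf, Xp) - y)^2) - base_mse
    }, 0))
  }, 0)
  imp <- pmax(imp, 0)
  names(imp) <- stepwise_set
  retained <- stepwise_set[imp > mean(imp)]
  if (!length(retained)) retained <- stepwise_set[which.max(imp)]
  finish(sort(retained), imp)
}

#' @export
print.landscape_model <- function(x, ...) {
  cat("Landscape GQI model:", length(x$selected_vis), "indices, train R2 =",
      round(x$train_r2, 4), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
predict.landscape_model <- function(object, newdata, ...) {
  predict(object$fit, newdata = newdata)
}

#' Fit the full landscape-scale GQI model
#'
#' Stepwise-AIC selection over the candidate vegetation indices followed by
#' random-forest refinement and an OLS refit.
#'
#' @inheritParams stepwise_aic
#' @param seed seed for the refinement forest.
#' @param refine set `FALSE` to stop at the stepwise OLS fit.
#' @return a `landscape_model`, with the stepwise result attached as
#'   attribute `stepwise`.
#' @export
build_landscape_model <- function(vi_table, y, seed = 1L, refine = TRUE) {
  sw <- stepwise_aic(vi_table, y)
  model <- if (refine && length(sw$selected) > 1L) {
    rf_refine(vi_table, y, sw$selected, seed = seed)
  } else {
    yv <- if (is.data.frame(y)) y$gqi else y
    structure(list(selected_vis = sw$selected,
                   coefficients = coef(sw$fit),
                   aic = sw$aic,
                   rf_importances = setNames(numeric(0), character(0)),
                   train_r2 = 1 - sum(residuals(sw$fit)^2) /
                     sum((yv - mean(yv))^2),
                   fit = sw$fit),
              class = "landscape_model")
  }
  attr(model, "stepwise") <- sw
  model
}

#' Train/test validation of the landscape model
#'
#' Splits the plots into training and test folds stratified by grassland
#' type (per-type training counts are `round(train_frac * n_type)`), runs
#' the full model builder inside the training fold only, and reports
#' `R^2 = 1 - SSE/SST` on each fold.
#'
#' @param vi_table candidate table (one row per plot).
#' @param y response vector or data.frame with `gqi`.
#' @param types character vector of grassland types per plot (used for
#'   stratification; a single type is allowed).
#' @param builder function(vi_table, y, seed) returning a model with a
#'   `predict` method; defaults to [build_landscape_model()].
#' @param train_frac training fraction in (0, 1).
#' @param seed seed for the split and the builder.
#' @return list with `train_r2`, `test_r2`, `train_idx`, `model`.
#' @export
validate_split <- function(vi_table, y, types = NULL,
                           builder = build_landscape_model,
                           train_frac = 0.7, seed = 1L) {
  if (is.data.frame(y)) y <- y$gqi
  n <- length(y)
  if (n < 10) stop("need at least 10 plots for a split validation")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (is.null(types)) types <- rep("all", n)
  set.seed(seed)
  train_idx <- sort(unlist(lapply(split(seq_len(n), types), function(ix) {
    sample(ix, round(train_frac * length(ix)))
  }), use.names = FALSE))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(train_idx) < 3 || length(test_idx) < 3) {
    stop("a validation fold has fewer than 3 plots")
  }
  model <- builder(vi_table[train_idx, , drop = FALSE], y[train_idx], seed = seed)
  r2 <- function(idx) {
    pred <- predict(model, newdata = vi_table[idx, , drop = FALSE])
    1 - sum((y[idx] - pred)^2) / sum((y[idx] - mean(y[idx]))^2)
  }
  list(train_r2 = r2(train_idx), test_r2 = r2(test_idx),
       train_idx = train_idx, model = model)
}
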