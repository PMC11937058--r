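#' Fit a PLS1 regression (NIPALS)
#'
#' Partial least squares regression with a single response, fitted by the
#' NIPALS algorithm on centered/scaled predictors. With as many components
#' as (independent) predictors the fit reproduces ordinary least squares.
#' Coefficients are back-transformed to the original predictor scale.
#'
#' @param X matrix or data.frame of predictors (rows = observations).
#' @param y numeric response.
#' @param n_components number of latent components (capped at the number of
#'   usable predictors).
#' @return object of class `plsr_model`: `coefficients` (named, first
#'   element `(Intercept)`), `n_components`, `centers`/`scales`, `weights`,
#'   `x_loadings`, `y_loadings`, `fitted`, `predictors`.
#' @export
fit_plsr <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) < 8) stop("need at least 8 observations to fit PLSR")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(X)) stop("no non-constant predictors left")
  n_components <- min(n_components, ncol(X))
  mx <- colMeans(X); my <- mean(y)
  Xs <- scale(X, center = mx, scale = sds)
  u <- y - my
  E <- Xs
  W <- P <- matrix(0, ncol(X), n_components,
                   dimnames = list(colnames(X), NULL))
  q <- numeric(n_components)
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(E, u))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- h - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p <- drop(crossprod(E, t_)) / tt
    qh <- sum(u * t_) / tt
    E <- E - tcrossprod(t_, p)
    u <- u - qh * t_
    W[, h] <- w; P[, h] <- p; q[h] <- qh
  }
  if (n_components < 1) {
    # response orthogonal to every predictor: the PLS solution is the null model
    b_std <- rep(0, ncol(X))
  } else {
    W <- W[, seq_len(n_components), drop = FALSE]
    P <- P[, seq_len(n_components), drop = FALSE]
    q <- q[seq_len(n_components)]
    b_std <- drop(W %*% solve(crossprod(P, W), q))
  }
  beta <- b_std / sds
  intercept <- my - sum(beta * mx)
  coefs <- c("(Intercept)" = intercept, setNames(beta, colnames(X)))
  fitted <- drop(intercept + as.matrix(X) %*% beta)
  structure(list(coefficients = coefs, n_components = n_components,
                 centers = mx, scales = sds, weights = W, x_loadings = P,
                 y_loadings = q, fitted = fitted, predictors = colnames(X)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("PLS1 model with", x$n_components, "component(s)\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!all(object$predictors %in% names(newdata))) {
    if (ncol(newdata) == length(object$predictors)) {
      names(newdata) <- object$predictors  # positional match for unnamed input
    } else {
      stop("newdata lacks predictor column(s): ",
           paste(setdiff(object$predictors, names(newdata)), collapse = ", "))
    }
  }
  X <- as.matrix(newdata[object$predictors])
  drop(object$coefficients[1] + X %*% object$coefficients[-1])
}

#' Choose the PLS component count by leave-one-out cross-validation
#'
#' For each candidate component count, the model is refitted n times leaving
#' one observation out; the count minimizing the LOOCV RMSE is chosen and
#' the cross-validated `R^2 = 1 - PRESS/SST` reported.
#'
#' @param X predictors, `y` response as in [fit_plsr()].
#' @param y numeric response.
#' @param max_components largest component count tried (bounded by the
#'   number of predictors).
#' @return list: `n_components`, `loocv_r2`, `loocv_rmse`, `cv_table`
#'   (per-count PRESS/RMSE/R2), `predictions` (LOO predictions for the
#'   chosen count).
#' @export
loocv_select <- function(X, y, max_components = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 8) stop("need at least 8 observations for LOOCV")
  ks <- seq_len(min(max_components, ncol(X)))
  sst <- sum((y - mean(y))^2)
  preds <- matrix(NA_real_, n, length(ks))
  for (i in seq_len(n)) {
    for (k in ks) {
      m <- fit_plsr(X[-i, , drop = FALSE], y[-i], n_components = k)
      preds[i, k] <- predict(m, X[i, , drop = FALSE])
    }
  }
  press <- colSums((y - preds)^2)
  rmse <- sqrt(press / n)
  best <- which.min(rmse)
  list(n_components = ks[best],
       loocv_r2 = 1 - press[best] / sst,
       loocv_rmse = rmse[best],
       cv_table = data.frame(n_components = ks, press = press,
                             rmse = rmse, r2 = 1 - press / sst),
       predictions = preds[, best])
}

#' Predict the regional GQI surface
#'
#' Applies a fitted PLSR model pixelwise over the regional predictor rasters,
#' scoring only pixels whose grassland type is AM or AS. Predictions are
#' clipped to \[0, 1\] (the GQI scale); the clipped fraction is attached as
#' attribute `clip_fraction`. Nodata in any predictor propagates.
#'
#' @param model a `plsr_model` fitted on columns named as in `predictors`.
#' @param predictors named list of congruent rasters (typically `ndvi`,
#'   `evi`, `lai`).
#' @param type_mask character matrix over {"AM", "AS", "other"}.
#' @return numeric matrix of predicted GQI (`NA` outside AM/AS).
#' @export
predict_regional <- function(model, predictors, type_mask) {
  do.call(stop_if_grid_mismatch, c(predictors, list(type_mask)))
  Xfull <- sapply(predictors[model$predictors], c)
  pred <- drop(model$coefficients[1] + Xfull %*% model$coefficients[-1])
  pred[!(c(type_mask) %in% c("AM", "AS"))] <- NA
  clipped <- sum(pred < 0 | pred > 1, na.rm = TRUE) / sum(!is.na(pred))
  pred <- pmin(pmax(pred, 0), 1)
  out <- matrix(pred, nrow(type_mask), ncol(type_mask))
  attr(out, "clip_fraction") <- clipped
  out
}
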