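# NIPALS partial least squares, single response.
#
# The same core serves regression (shikimate on reflectance or ChlF
# parameters) and discriminant analysis (dummy-coded class response).
# X is mean-centered by default; autoscaling is available for tables with
# heterogeneous units (the ChlF panel). Coefficients and intercept are
# always returned on the original scale, so prediction is a single
# affine map.

# workhorse: returns per-LV weights/loadings and cumulative original-scale
# coefficient matrix (p x A) so callers can read off any smaller model
nipals_pls <- function(X, y, n_lv, scale = FALSE, tol = 1e-12) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X); y_mean <- mean(y)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s < tol] <- 1
    s
  } else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean

  A <- min(n_lv, n - 1, p)
  W <- P <- matrix(0, p, max(A, 1))
  qvec <- numeric(max(A, 1))
  Tm <- matrix(0, n, max(A, 1))
  a <- 0
  for (k in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < tol) break
    pv <- crossprod(Xc, t) / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - q * t
    a <- a + 1
    W[, a] <- w; P[, a] <- pv; qvec[a] <- q; Tm[, a] <- t
  }
  coefs <- matrix(0, p, max(a, 1))
  if (a > 0) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))   # X-rotation: T = Xc %*% R
    for (k in seq_len(a))
      coefs[, k] <- R[, seq_len(k), drop = FALSE] %*% qvec[seq_len(k)]
    coefs <- coefs / x_scale
  }
  list(n_lv = a, coefs = coefs, x_mean = x_mean, y_mean = y_mean,
       x_scale = x_scale,
       weights = W[, seq_len(max(a, 1)), drop = FALSE],
       x_loadings = P[, seq_len(max(a, 1)), drop = FALSE],
       y_loadings = qvec[seq_len(max(a, 1))],
       scores = Tm[, seq_len(max(a, 1)), drop = FALSE])
}

#' Fit a PLS regression model
#'
#' NIPALS decomposition of mean-centered (optionally autoscaled) data.
#' If the requested number of latent variables exceeds the achievable rank
#' the model is fitted with the achievable count and a warning is issued.
#'
#' @param X samples x features matrix (column names become feature names).
#' @param y numeric response.
#' @param n_lv number of latent variables.
#' @param scale autoscale columns to unit variance (default FALSE:
#'   reflectance shares units across bands; use TRUE for heterogeneous
#'   tables such as the ChlF panel).
#' @return An object of class `pls_model` with original-scale
#'   `coefficients` and `intercept`, per-LV `weights`, `x_loadings`,
#'   `y_loadings`, the centering/scaling vectors, `feature_names` and
#'   `mode` (`"regression"`).
#' @export
fit_plsr <- function(X, y, n_lv, scale = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("X and y must be finite")
  if (n_lv < 1) stop("n_lv must be >= 1")
  fit <- nipals_pls(X, y, n_lv, scale = scale)
  if (fit$n_lv < min(n_lv, nrow(X) - 1, ncol(X)))
    warning(sprintf("rank allowed only %d of %d requested latent variables",
                    fit$n_lv, n_lv))
  b <- fit$coefs[, max(fit$n_lv, 1)]
  structure(list(
    n_lv = fit$n_lv,
    coefficients = stats::setNames(b, colnames(X)),
    intercept = fit$y_mean - sum(fit$x_mean * b),
    x_mean = fit$x_mean, y_mean = fit$y_mean, x_scale = fit$x_scale,
    weights = fit$weights, x_loadings = fit$x_loadings,
    y_loadings = fit$y_loadings,
    feature_names = colnames(X), scaled = scale,
    mode = "regression"), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s, %d LV, %d features\n", x$mode, x$n_lv,
              length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' `y_hat = X %*% coefficients + intercept`. When `newdata` has column
#' names and the model carries feature names, columns are matched by name
#' and a missing feature is an error listing what is absent.
#'
#' @param object a `pls_model`.
#' @param newdata matrix (samples x features), numeric vector (one
#'   sample), or [spectrum()] (features extracted by wavelength, 1.5 nm
#'   tolerance).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum")) {
    wl <- as.numeric(object$feature_names)
    if (anyNA(wl)) stop("model features are not wavelengths")
    idx <- band_index(newdata$wavelengths, wl)
    newdata <- matrix(newdata$values[idx], nrow = 1,
                      dimnames = list(NULL, object$feature_names))
  }
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  fn <- object$feature_names
  if (!is.null(fn) && !is.null(colnames(newdata))) {
    missing <- setdiff(fn, colnames(newdata))
    if (length(missing))
      stop("newdata lacks model features: ", paste(missing, collapse = ", "))
    newdata <- newdata[, fn, drop = FALSE]
  } else if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$coefficients))
  }
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' Choose the latent-variable count by leave-one-out cross-validation
#'
#' For each left-out sample a NIPALS model with up to `max_lv` components
#' is fitted on the remainder and the held-out prediction recorded per
#' component count. Returns the count minimizing the LOO RMSECV; ties are
#' broken toward fewer components.
#'
#' @param X samples x features matrix.
#' @param y numeric response.
#' @param max_lv largest component count considered.
#' @param scale autoscale columns (as in [fit_plsr()]).
#' @return list with `n_lv` and `rmsecv` (one value per component count).
#' @export
select_lv_loocv <- function(X, y, max_lv, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  max_lv <- min(max_lv, n - 2, ncol(X))
  if (max_lv < 1) stop("too few samples for cross-validation")
  pred <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    fit <- nipals_pls(X[-i, , drop = FALSE], y[-i], max_lv, scale = scale)
    if (fit$n_lv == 0) { pred[i, ] <- fit$y_mean; next }
    xi <- X[i, ]
    for (k in seq_len(max_lv)) {
      kk <- min(k, fit$n_lv)
      b <- fit$coefs[, kk]
      pred[i, k] <- sum(xi * b) + fit$y_mean - sum(fit$x_mean * b)
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  list(n_lv = which.min(rmsecv), rmsecv = rmsecv)
}

#' Residual-based outlier screening
#'
#' Fits a PLSR model on all samples and flags those whose absolute
#' residual exceeds `k_sd` standard deviations of the residuals. A single
#' pass: flagged samples are reported, not iteratively re-screened.
#'
#' @param X samples x features matrix; `y` response.
#' @param y numeric response.
#' @param n_lv latent variables for the screening fit.
#' @param k_sd flagging threshold in residual standard deviations
#'   (default 3).
#' @param scale autoscale columns.
#' @return Integer indices of flagged samples (possibly empty).
#' @export
detect_outliers <- function(X, y, n_lv, k_sd = 3, scale = FALSE) {
  if (nrow(as.matrix(X)) < 10) stop("need at least 10 samples")
  fit <- fit_plsr(X, y, n_lv, scale = scale)
  res <- y - predict(fit, as.matrix(X))
  which(abs(res) > k_sd * stats::sd(res))
}

#' Fit a PLS discriminant model
#'
#' Regression on the dummy-coded class response (healthy = 1, damaged =
#' 2); the decision rule lives in [classify_plsda()].
#'
#' @param X samples x features matrix.
#' @param labels integer/factor class labels coded 1 (healthy: all TG
#'   plants plus WT water controls) and 2 (damaged: WT glyphosate).
#' @param n_lv latent variables.
#' @param scale autoscale columns.
#' @return A `pls_model` with `mode = "discriminant"`.
#' @export
fit_plsda <- function(X, labels, n_lv, scale = FALSE) {
  labels <- as.integer(as.character(factor(labels)))
  if (!all(labels %in% c(1L, 2L))) stop("labels must be coded 1 or 2")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit a discriminant model")
  m <- fit_plsr(X, as.numeric(labels), n_lv, scale = scale)
  m$mode <- "discriminant"
  m
}

#' Classify with a PLS-DA model
#'
#' Applies the interval decision rule on the continuous dummy prediction:
#' values in (0.5, 1.5] are class 1 (healthy), values in (1.5, 2.5] class
#' 2 (damaged), anything outside (0.5, 2.5] is unclassified (`NA`), which
#' counts as incorrect in [classification_accuracy()]. Boundaries are
#' upper-inclusive.
#'
#' @param model a `pls_model` with `mode = "discriminant"`.
#' @param X samples x features matrix.
#' @return list with `class` (integer, NA when unclassified), `y_hat`
#'   (continuous score) and `valid` (logical).
#' @export
classify_plsda <- function(model, X) {
  if (!identical(model$mode, "discriminant"))
    stop("model is not a discriminant model")
  y_hat <- predict(model, X)
  cls <- rep(NA_integer_, length(y_hat))
  cls[y_hat > 0.5 & y_hat <= 1.5] <- 1L
  cls[y_hat > 1.5 & y_hat <= 2.5] <- 2L
  list(class = cls, y_hat = y_hat, valid = !is.na(cls))
}

#' Regression performance metrics
#'
#' `R2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)` and
#' `RMSE = sqrt(mean((y - y_hat)^2))`, in response units.
#'
#' @param y_true,y_hat numeric vectors of equal length (n >= 2).
#' @return list with `r2`, `rmse`, `n`.
#' @export
regression_metrics <- function(y_true, y_hat) {
  stopifnot(length(y_true) == length(y_hat), length(y_true) >= 2)
  ss_res <- sum((y_true - y_hat)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  list(r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(ss_res / length(y_true)),
       n = length(y_true))
}

#' Classification accuracy
#'
#' Fraction of correctly classified samples among all samples; an
#' unclassified (`NA`) prediction counts as incorrect.
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return Fraction in \[0, 1\].
#' @export
classification_accuracy <- function(labels_true, labels_pred) {
  stopifnot(length(labels_true) == length(labels_pred))
  ok <- !is.na(labels_pred) & labels_pred == labels_true
  mean(ok)
}

#' Calibration/prediction model metrics
#'
#' Bundles [regression_metrics()] for the two subsets the chemometric
#' workflow reports on.
#'
#' @param y_cal,y_cal_hat calibration-set reference and predicted values.
#' @param y_pred,y_pred_hat prediction-set reference and predicted values.
#' @return list of class `model_metrics`: `r2_cal`, `rmse_cal`, `n_cal`,
#'   `r2_pred`, `rmse_pred`, `n_pred`.
#' @export
model_metrics <- function(y_cal, y_cal_hat, y_pred, y_pred_hat) {
  mc <- regression_metrics(y_cal, y_cal_hat)
  mp <- regression_metrics(y_pred, y_pred_hat)
  structure(list(r2_cal = mc$r2, rmse_cal = mc$rmse, n_cal = mc$n,
                 r2_pred = mp$r2, rmse_pred = mp$rmse, n_pred = mp$n),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("R2c = %.3f (RMSEC = %.2f, n = %d); R2p = %.3f (RMSEP = %.2f, n = %d)\n",
              x$r2_cal, x$rmse_cal, x$n_cal, x$r2_pred, x$rmse_pred, x$n_pred))
  invisible(x)
}

#' Write / read a PLS model as JSON
#'
#' Serializes coefficients, intercept, feature names, latent-variable
#' count, centering/scaling vectors, mode and free-form metadata.
#'
#' @param model a `pls_model`.
#' @param path JSON path.
#' @param metadata optional named list stored alongside the model.
#' @return `path` (write) or a `pls_model` (read).
#' @export
write_pls_model <- function(model, path, metadata = NULL) {
  obj <- list(
    mode = model$mode, n_lv = model$n_lv,
    feature_names = model$feature_names,
    coefficients = unname(model$coefficients),
    intercept = model$intercept,
    x_mean = unname(model$x_mean), y_mean = model$y_mean,
    x_scale = unname(model$x_scale),
    metadata = metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    n_lv = obj$n_lv %||% NA_integer_,
    coefficients = stats::setNames(as.numeric(obj$coefficients),
                                   obj$feature_names),
    intercept = as.numeric(obj$intercept),
    x_mean = if (!is.null(obj$x_mean)) as.numeric(obj$x_mean) else NULL,
    y_mean = obj$y_mean, x_scale = obj$x_scale,
    feature_names = obj$feature_names,
    metadata = obj$metadata,
    mode = obj$mode %||% "regression"), class = "pls_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The published 11-wavelength shikimate calibration model
#'
#' Loads the fixed reference calibration equation shipped with the
#' package: an 11-wavelength PLSR model for shikimic acid concentration in
#' maize canopies (fresh-weight units) reported in the glyphosate-
#' tolerance screening study this pipeline re-implements. One band was
#' printed as "5343 nm" in the source and is recorded here as 534 nm (see
#' the fixture metadata).
#'
#' @return A `pls_model` with 11 coefficients and an intercept.
#' @export
#' @examples
#' m <- reference_equation_model()
#' predict(m, rep(0, 11))   # the intercept
reference_equation_model <- function() {
  read_pls_model(system.file("extdata", "reference_equation_model.json",
                             package = "shikimap", mustWork = TRUE))
}
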