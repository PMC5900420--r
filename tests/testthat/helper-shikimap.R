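# shared fixture builders (all generated in code, nothing on disk)

# tiny reflectance cube with a known constant value
make_uniform_cube <- function(rows = 4, cols = 5, bands = 6, value = 0.5) {
  hypercube(array(value, c(rows, cols, bands)),
            seq(500, 600, length.out = bands))
}

# cube of counts midway between dark and white references
make_calibration_trio <- function(rows = 3, cols = 3, bands = 4) {
  wl <- seq(450, 900, length.out = bands)
  dark <- hypercube(array(100, c(rows, cols, bands)), wl)
  white <- hypercube(array(4100, c(rows, cols, bands)), wl)
  mid <- hypercube(array(2100, c(rows, cols, bands)), wl)
  list(dark = dark, white = white, mid = mid, wl = wl)
}

# minimal hand-built discriminant model: y_hat = x (single feature)
make_identity_plsda <- function() {
  structure(list(n_lv = 1L,
                 coefficients = c(f1 = 1),
                 intercept = 0,
                 feature_names = "f1",
                 mode = "discriminant"),
            class = "pls_model")
}

# two Gaussian clusters separated by delta standard deviations
make_two_clusters <- function(n_per = 30, p = 4, delta = 6, sd = 1,
                              seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per, p),
               matrix(rnorm(n_per * p, delta * sd, sd), n_per, p))
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, labels = rep(c(1L, 2L), each = n_per))
  })
}

# score-recursion prediction oracle: rebuilds y_hat from the per-LV
# weights/loadings instead of the collapsed coefficient vector
predict_by_recursion <- function(model, X) {
  E <- sweep(sweep(as.matrix(X), 2, model$x_mean), 2, model$x_scale, "/")
  y_hat <- rep(model$y_mean, nrow(E))
  for (a in seq_len(model$n_lv)) {
    t_a <- E %*% model$weights[, a]
    y_hat <- y_hat + model$y_loadings[a] * t_a
    E <- E - tcrossprod(t_a, model$x_loadings[, a])
  }
  as.numeric(y_hat)
}
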