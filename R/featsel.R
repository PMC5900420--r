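# Variable selection.
#
# Two selectors drive the pipeline: the successive projections algorithm
# (SPA) picks minimally collinear wavelength chains scored by validation
# RMSE of a multiple linear regression, and random frog samples feature
# subsets with a reversible-jump-style chain whose per-feature inclusion
# frequency is a selection probability. Backward refinement then prunes
# an SPA selection while cross-validated performance stays acceptable.

new_selection_result <- function(indices, names, trace, method, ...) {
  structure(list(selected_indices = as.integer(indices),
                 selected_names = names,
                 criterion_trace = trace,
                 method = method, ...),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s)%s\n", x$method,
              length(x$selected_indices),
              if (length(x$selected_indices))
                paste0(" [", paste(utils::head(x$selected_names, 8),
                                   collapse = ", "),
                       if (length(x$selected_names) > 8) ", ..." else "", "]")
              else ""))
  invisible(x)
}

#' Successive projections algorithm wavelength selection
#'
#' Forward selection that minimizes collinearity: starting from every
#' column in turn, the chain grows by repeatedly projecting all unchosen
#' columns onto the orthogonal complement of the span of the chosen ones
#' and appending the column with the largest residual norm (ties broken
#' toward the lowest column index). Every chain prefix with `k_min` to
#' `k_max` members is scored by the validation-set RMSE of a multiple
#' linear regression (with intercept) fitted on the calibration set; the
#' minimizing chain is returned. Columns are scaled to unit norm
#' internally for the projection phase only. A chain that becomes rank
#' deficient simply stops early. SPA is deterministic: no randomness is
#' involved.
#'
#' @param X_cal,y_cal calibration features/response.
#' @param X_val,y_val validation features/response used for scoring.
#' @param k_min,k_max candidate chain lengths (defaults 1 and 30).
#' @return A `selection_result` with `criterion_trace` holding the best
#'   validation RMSE per chain length.
#' @export
spa_select <- function(X_cal, y_cal, X_val, y_val, k_min = 1, k_max = 30) {
  X_cal <- as.matrix(X_cal); X_val <- as.matrix(X_val)
  n <- nrow(X_cal); p <- ncol(X_cal)
  k_max <- min(k_max, n - 1, p)
  k_min <- max(1, min(k_min, k_max))
  cn <- colnames(X_cal)
  if (is.null(cn)) cn <- paste0("f", seq_len(p))

  nrm <- sqrt(colSums(X_cal^2))
  nrm[nrm == 0] <- 1
  Xn <- sweep(X_cal, 2, nrm, "/")

  chains <- vector("list", p)
  for (j in seq_len(p)) {
    chain <- j
    R <- Xn
    u <- R[, j]
    for (step in seq_len(k_max - 1)) {
      uu <- sum(u^2)
      if (uu < 1e-24) break
      R <- R - tcrossprod(u / uu, crossprod(R, u))   # deflate span(u)
      norms <- colSums(R^2)
      norms[chain] <- -1
      nxt <- which.max(norms)
      if (norms[nxt] < 1e-20) break                  # rank exhausted
      chain <- c(chain, nxt)
      u <- R[, nxt]
    }
    chains[[j]] <- chain
  }

  best <- list(rmse = Inf, chain = integer(0))
  trace <- rep(Inf, k_max)
  for (j in seq_len(p)) {
    chain <- chains[[j]]
    for (k in seq(k_min, min(k_max, length(chain)))) {
      idx <- chain[seq_len(k)]
      fit <- stats::lm.fit(cbind(1, X_cal[, idx, drop = FALSE]), y_cal)
      pr <- cbind(1, X_val[, idx, drop = FALSE]) %*% fit$coefficients
      rmse <- sqrt(mean((y_val - pr)^2))
      if (is.finite(rmse)) {
        if (rmse < trace[k]) trace[k] <- rmse
        if (rmse < best$rmse) best <- list(rmse = rmse, chain = idx)
      }
    }
  }
  new_selection_result(best$chain, cn[best$chain],
                       trace = stats::setNames(trace[k_min:k_max],
                                               k_min:k_max),
                       method = "SPA",
                       rmse = best$rmse, k_min = k_min, k_max = k_max)
}

# leave-one-out RMSECV and Q2 of a PLSR at a fixed component count
loo_press <- function(X, y, n_lv, scale = FALSE) {
  X <- as.matrix(X); n <- nrow(X)
  A <- max(1, min(n_lv, n - 2, ncol(X)))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- nipals_pls(X[-i, , drop = FALSE], y[-i], A, scale = scale)
    b <- fit$coefs[, max(fit$n_lv, 1)]
    pred[i] <- sum(X[i, ] * b) + fit$y_mean - sum(fit$x_mean * b)
  }
  press <- sum((y - pred)^2)
  list(rmsecv = sqrt(press / n),
       q2 = 1 - press / sum((y - mean(y))^2))
}

#' Backward refinement of a wavelength selection
#'
#' Iteratively removes the feature whose removal least increases the
#' leave-one-out RMSECV of a PLSR fit, stopping when the cross-validated
#' R2 would fall below `r2_floor` or `max_drop` features have been
#' removed. The trace records cross-validated R2 and RMSECV per subset
#' size, which is monotone non-increasing in size count.
#'
#' @param sel a `selection_result` (non-empty).
#' @param X,y full feature matrix and response the selection refers to.
#' @param max_drop maximum removals (default unlimited).
#' @param r2_floor cross-validated R2 below which refinement stops
#'   (default 0.75).
#' @param n_lv_max component cap for the internal PLSR (default 10).
#' @param scale autoscale columns.
#' @return A `selection_result` with `method = "backward_refine"`.
#' @export
backward_refine <- function(sel, X, y, max_drop = Inf, r2_floor = 0.75,
                            n_lv_max = 10, scale = FALSE) {
  stopifnot(inherits(sel, "selection_result"),
            length(sel$selected_indices) > 0)
  X <- as.matrix(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(X)))
  cur <- sel$selected_indices
  cur_stats <- loo_press(X[, cur, drop = FALSE], y, n_lv_max, scale)
  trace <- data.frame(size = length(cur), rmsecv = cur_stats$rmsecv,
                      q2 = cur_stats$q2)
  drops <- 0
  while (drops < max_drop && length(cur) > 1) {
    cand <- lapply(seq_along(cur), function(i)
      loo_press(X[, cur[-i], drop = FALSE], y, n_lv_max, scale))
    rms <- vapply(cand, `[[`, numeric(1), "rmsecv")
    i_best <- which.min(rms)
    if (cand[[i_best]]$q2 < r2_floor) break
    cur <- cur[-i_best]
    drops <- drops + 1
    trace <- rbind(trace, data.frame(size = length(cur),
                                     rmsecv = cand[[i_best]]$rmsecv,
                                     q2 = cand[[i_best]]$q2))
  }
  new_selection_result(cur, cn[cur], trace = trace,
                       method = "backward_refine",
                       r2_floor = r2_floor)
}

#' Random frog feature selection
#'
#' Reversible-jump-style subset sampler. A current subset `V` is
#' perturbed each iteration: a candidate size is drawn from
#' `round(Normal(|V|, size_jitter * |V|))` clamped to \[1, p\]; to grow,
#' a random pool of non-members (twice the deficit) is ranked by absolute
#' PLSR coefficient on autoscaled data in a fit on `V` plus the pool and
#' the top entrants join; to shrink, the bottom-ranked members of a fit
#' on `V` leave. The candidate replaces `V` with probability 1 when its
#' cross-validated RMSE is no worse, and with probability
#' `accept_damp * RMSECV(V) / RMSECV(V*)` otherwise. The selection
#' probability of a feature is the fraction of iterations in which it was
#' a member. Cross-validation folds are redrawn every iteration
#' (Monte-Carlo CV) and both subsets are scored on the same draw: a noisy
#' objective keeps the chain sampling around good subsets rather than
#' freezing on the optimum of one fixed partition, which on signal-free
#' data would concentrate all probability on a spurious subset.
#'
#' @param X samples x features matrix; `y` response.
#' @param y numeric response.
#' @param n_iterations chain length (>= 1; default 10000).
#' @param init_size initial subset size (default 10).
#' @param size_jitter relative sd of the candidate-size proposal
#'   (default 0.3).
#' @param accept_damp damping of uphill acceptance (default 0.1).
#' @param n_lv components of the internal PLSR (default 3).
#' @param cv_folds folds for the internal RMSECV (default 5).
#' @param scale autoscale columns (default TRUE: ChlF parameters carry
#'   heterogeneous units).
#' @param seed integer seed; the run is a pure function of it.
#' @return A `selection_result` whose `criterion_trace` is the named
#'   per-feature selection probability vector; `selected_indices` orders
#'   all features by decreasing probability.
#' @export
random_frog <- function(X, y, n_iterations = 10000, init_size = 10,
                        size_jitter = 0.3, accept_damp = 0.1,
                        n_lv = 3, cv_folds = 5, scale = TRUE, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (init_size < 1 || init_size > p) stop("init_size must be in [1, p]")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(p))

  with_seed(seed, {
    # Monte-Carlo CV: folds are redrawn every iteration so the chain
    # samples around good subsets instead of locking onto the single
    # subset that happens to minimise one fixed partition's RMSECV (on
    # signal-free data a fixed objective concentrates all probability on
    # a spurious optimum)
    rmsecv <- function(idx, folds) {
      press <- 0
      for (f in seq_len(cv_folds)) {
        te <- folds == f
        fit <- nipals_pls(X[!te, idx, drop = FALSE], y[!te], n_lv,
                          scale = scale)
        b <- fit$coefs[, max(fit$n_lv, 1)]
        pr <- X[te, idx, drop = FALSE] %*% b + fit$y_mean -
          sum(fit$x_mean * b)
        press <- press + sum((y[te] - pr)^2)
      }
      sqrt(press / n)
    }
    # |coef| ranking in autoscaled space, on a random 70% subsample: a
    # feature's rank must be re-earned on every proposal, so only
    # features whose coefficients are stable under resampling (true
    # signal) persist in the subset
    coef_rank <- function(idx) {
      sub <- sample.int(n, max(4L, floor(0.7 * n)))
      fit <- nipals_pls(X[sub, idx, drop = FALSE], y[sub], n_lv,
                        scale = scale)
      b <- fit$coefs[, max(fit$n_lv, 1)] * fit$x_scale
      stats::setNames(abs(b), as.character(idx))
    }

    V <- sort(sample.int(p, init_size))
    counts <- numeric(p)
    for (it in seq_len(n_iterations)) {
      # proposal sd floored at 1: a relative sd alone degenerates as
      # |V| -> 1 (round(N(1, 0.3)) almost never leaves 1) and freezes
      # the chain
      m_star <- round(stats::rnorm(1, length(V),
                                   max(1, size_jitter * length(V))))
      m_star <- max(1, min(p, m_star))
      delta <- m_star - length(V)
      V_star <- V
      if (delta > 0) {
        nonmem <- setdiff(seq_len(p), V)
        pool <- if (length(nonmem) > 2 * delta)
          sample(nonmem, 2 * delta) else nonmem
        ranks <- coef_rank(c(V, pool))
        pool_rank <- ranks[as.character(pool)]
        add <- pool[order(pool_rank, decreasing = TRUE)][
          seq_len(min(delta, length(pool)))]
        V_star <- sort(c(V, add))
      } else if (delta < 0) {
        ranks <- coef_rank(V)
        drop_f <- V[order(ranks)][seq_len(-delta)]
        V_star <- sort(setdiff(V, drop_f))
      }
      if (!identical(V_star, V)) {
        folds <- sample(rep(seq_len(cv_folds), length.out = n))
        rmse_V <- rmsecv(V, folds)
        rmse_star <- rmsecv(V_star, folds)
        accept <- if (rmse_star <= rmse_V) TRUE
                  else stats::runif(1) < accept_damp * rmse_V / rmse_star
        if (accept) V <- V_star
      }
      counts[V] <- counts[V] + 1
    }
    prob <- counts / n_iterations
    ord <- order(prob, decreasing = TRUE)
    new_selection_result(ord, cn[ord],
                         trace = stats::setNames(prob, cn),
                         method = "random_frog",
                         n_iterations = n_iterations,
                         init_size = init_size, size_jitter = size_jitter,
                         accept_damp = accept_damp, n_lv = n_lv,
                         cv_folds = cv_folds, seed = seed)
  })
}

#' Threshold a random-frog selection
#'
#' Keeps the features whose selection probability strictly exceeds the
#' threshold (default 0.4), sorted by decreasing probability. An empty
#' result is allowed and flagged via the `empty` field.
#'
#' @param sel a `selection_result` from [random_frog()].
#' @param threshold probability cut (default 0.4).
#' @return A `selection_result`.
#' @export
threshold_features <- function(sel, threshold = 0.4) {
  stopifnot(inherits(sel, "selection_result"),
            identical(sel$method, "random_frog"))
  prob <- sel$criterion_trace
  keep <- which(prob > threshold)
  keep <- keep[order(prob[keep], decreasing = TRUE)]
  new_selection_result(keep, names(prob)[keep],
                       trace = prob[keep],
                       method = "random_frog",
                       threshold = threshold,
                       empty = length(keep) == 0)
}

#' Pearson correlation among selected features
#'
#' @param X_selected samples x features matrix (>= 2 features, each with
#'   nonzero variance).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X_selected) {
  X_selected <- as.matrix(X_selected)
  if (ncol(X_selected) < 2) stop("need at least 2 features")
  if (any(apply(X_selected, 2, stats::sd) == 0))
    stop("features must have nonzero variance")
  stats::cor(X_selected)
}

#' Serialize a selection result to JSON
#'
#' Stores indices, names, the criterion trace and any hyperparameters
#' recorded on the result.
#'
#' @param sel a `selection_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(sel, path) {
  obj <- unclass(sel)
  if (is.data.frame(obj$criterion_trace))
    obj$criterion_trace <- as.list(obj$criterion_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
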