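#' SPXY calibration/prediction partitioning
#'
#' Kennard-Stone greedy max-min selection on the joint X-y distance
#' `d(i, j) = dX(i, j) / max(dX) + dy(i, j) / max(dy)` (both Euclidean).
#' The first two calibration picks are the pair at maximal joint
#' distance; each further pick maximizes the minimum distance to the
#' already-selected set. The calibration set therefore spans the joint
#' space of spectra and response; the remainder forms the prediction set.
#' Deterministic: ties are broken toward the lowest row index.
#'
#' @param X samples x features matrix.
#' @param y numeric response (for PLS-DA partitioning, the dummy-coded
#'   class labels).
#' @param calibration_fraction fraction in (0, 1); calibration size is
#'   `round(fraction * n)`.
#' @return list of class `split_result` with sorted integer
#'   `calibration_indices` and `prediction_indices` (disjoint, covering
#'   all samples).
#' @export
#' @examples
#' s <- spxy_split(matrix(rnorm(40), 20), rnorm(20), 2/3)
#' length(s$calibration_indices)  # 13
spxy_split <- function(X, y, calibration_fraction) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop("calibration_fraction must be in (0, 1)")
  n_cal <- round(calibration_fraction * n)
  n_cal <- max(2L, min(as.integer(n_cal), n - 1L))

  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(y))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0) {
    warning("all samples identical; returning the leading rows as calibration")
    return(structure(list(calibration_indices = seq_len(n_cal),
                          prediction_indices = seq(n_cal + 1L, n)),
                     class = "split_result"))
  }
  d <- (if (mx > 0) dx / mx else 0) + (if (my > 0) dy / my else 0)

  # seed pair: maximal joint distance, lowest indices on ties
  w <- which(d == max(d), arr.ind = TRUE)
  w <- w[w[, 1] < w[, 2], , drop = FALSE]
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  sel <- as.integer(w[1, ])

  mind <- pmin(d[, sel[1]], d[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind)           # ties -> lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(calibration_indices = sort(sel),
                 prediction_indices = setdiff(seq_len(n), sel)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction\n",
              length(x$calibration_indices), length(x$prediction_indices)))
  invisible(x)
}
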