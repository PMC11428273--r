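#' Root mean square error
#' @param y,yhat numeric vectors of equal length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("length mismatch: ", length(y), " vs ", length(yhat))
  if (!length(y)) stop("empty input")
  sqrt(mean((as.numeric(y) - as.numeric(yhat))^2))
}

#' Mean absolute error
#' @param y,yhat numeric vectors of equal length.
#' @return `mean(abs(y - yhat))`.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("length mismatch: ", length(y), " vs ", length(yhat))
  if (!length(y)) stop("empty input")
  mean(abs(as.numeric(y) - as.numeric(yhat)))
}

#' Dynamic time warping distance
#'
#' Minimum cumulative absolute difference over monotone alignments of two
#' sequences, computed by dynamic programming on the pairwise cost matrix
#' `C[i, j] = |y[i] - yhat[j]|` with steps (1,0), (0,1), (1,1) from (1,1) to
#' (T1, T2). Measures similarity of *shape*: a sequence and a locally
#' time-shifted copy of it score near zero. No warping-window constraint is
#' applied.
#'
#' @param y,yhat numeric vectors (lengths may differ).
#' @return Non-negative scalar; 0 iff the sequences align exactly.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)) # 0: the repeat is absorbed
#' @export
dtw_distance <- function(y, yhat) {
  y <- as.numeric(y)
  yhat <- as.numeric(yhat)
  n <- length(y)
  m <- length(yhat)
  if (!n || !m) stop("empty input")
  cost <- abs(outer(y, yhat, `-`))
  acc <- matrix(Inf, n + 1L, m + 1L)
  acc[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc[i + 1L, j + 1L] <- cost[i, j] +
        min(acc[i, j + 1L], acc[i + 1L, j], acc[i, j])
    }
  }
  acc[n + 1L, m + 1L]
}

#' Bundle of forecast metrics
#'
#' RMSE and MAE quantify pointwise deviation; DTW quantifies shape
#' similarity under local time shifts. Metrics are computed on whatever
#' scale the inputs are on; the pipeline reports them on the normalized
#' `[0, 1]` scale, per window, then averaged.
#'
#' @param y,yhat numeric vectors of equal length.
#' @return A `forecast_eval` list: `rmse`, `mae`, `dtw`, `n_points`.
#' @export
evaluate_forecast <- function(y, yhat) {
  structure(list(rmse = rmse(y, yhat), mae = mae(y, yhat),
                 dtw = dtw_distance(y, yhat), n_points = length(y)),
            class = "forecast_eval")
}

#' @export
print.forecast_eval <- function(x, ...) {
  cat(sprintf("<forecast_eval> RMSE %.4g | MAE %.4g | DTW %.4g (n = %d)\n",
              x$rmse, x$mae, x$dtw, x$n_points))
  invisible(x)
}
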