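#' Max-min normalization
#'
#' Affine rescaling of a series to `[0, 1]`:
#' `ybar = (y - y_min) / (y_max - y_min)`. The fitted range is returned so
#' forecasts on the normalized scale can be mapped back. In the pipeline the
#' range is fitted on the training portion of a series only, to avoid
#' leaking the test range into training.
#'
#' @param y numeric vector with `max(y) > min(y)`.
#' @param params optional previously fitted parameters (list with `y_min`,
#'   `y_max`); when given, `y` is scaled with them instead of refitting.
#' @return List with `values` (normalized vector) and `params`.
#' @examples
#' normalize_minmax(c(0, 5, 10))$values
#' @export
normalize_minmax <- function(y, params = NULL) {
  y <- as.numeric(y)
  if (is.null(params)) {
    y_min <- min(y)
    y_max <- max(y)
    if (y_max <= y_min)
      stop("degenerate range: series is constant (y_max = y_min = ", y_min, ")")
    params <- list(y_min = y_min, y_max = y_max)
  } else {
    if (params$y_max <= params$y_min) stop("degenerate normalization params")
  }
  list(values = (y - params$y_min) / (params$y_max - params$y_min),
       params = params)
}

#' Invert max-min normalization
#'
#' `y = ybar * (y_max - y_min) + y_min`. Values outside `[0, 1]`
#' extrapolate linearly, so out-of-range forecasts remain meaningful.
#'
#' @param ybar numeric vector on the normalized scale.
#' @param params list with `y_min`, `y_max` from [normalize_minmax()].
#' @return Numeric vector on the original scale.
#' @export
denormalize_minmax <- function(ybar, params) {
  if (params$y_max <= params$y_min) stop("degenerate normalization params")
  as.numeric(ybar) * (params$y_max - params$y_min) + params$y_min
}

#' Sliding-window specification
#'
#' A forecasting window has length `L = D + H`: `D` historical timepoints
#' (all regions) as input and the following `H` timepoints of the target
#' region as output.
#'
#' @param D history length (positive integer).
#' @param H forecast horizon (positive integer).
#' @param stride step between consecutive window starts; 1 maximizes the
#'   number of training windows.
#' @return A `window_spec`.
#' @export
window_spec <- function(D, H, stride = 1L) {
  if (D < 1L || H < 1L || stride < 1L)
    stop("D, H and stride must be positive integers")
  structure(list(D = as.integer(D), H = as.integer(H),
                 stride = as.integer(stride)),
            class = "window_spec")
}

#' Build sliding windows from a multivariate block
#'
#' Segments an m x T block into overlapping windows. Each window's input is
#' the D-step history of *all* regions (the target's own history plus the
#' auxiliary regions); its output is the next H values of the target region
#' only. Windows are ordered by start index.
#'
#' @param block numeric m x T matrix (regions x timepoints).
#' @param target_region index of the row to forecast.
#' @param spec a [window_spec()].
#' @return A `window_set`: `inputs` (n x m x D array), `targets` (n x H
#'   matrix), `anchors` (length-n vector: last observed target value per
#'   window), `starts`, `target_region`, `spec`.
#' @export
make_windows <- function(block, target_region, spec) {
  block <- as.matrix(block)
  m <- nrow(block)
  T <- ncol(block)
  if (target_region < 1L || target_region > m)
    stop("target_region out of range 1..", m)
  L <- spec$D + spec$H
  if (T < L)
    stop("series too short: T = ", T, " but window length D + H = ", L,
         " requires T >= ", L)
  starts <- seq.int(1L, T - L + 1L, by = spec$stride)
  n <- length(starts)
  inputs <- array(0, dim = c(n, m, spec$D))
  targets <- matrix(0, n, spec$H)
  for (i in seq_len(n)) {
    s <- starts[i]
    inputs[i, , ] <- block[, s:(s + spec$D - 1L), drop = FALSE]
    targets[i, ] <- block[target_region, (s + spec$D):(s + L - 1L)]
  }
  structure(list(inputs = inputs, targets = targets,
                 anchors = inputs[, target_region, spec$D],
                 starts = starts, target_region = as.integer(target_region),
                 spec = spec),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<window_set> %d windows: inputs %d x %d x %d, horizon %d, target region %d\n",
              d[1L], d[1L], d[2L], d[3L], ncol(x$targets), x$target_region))
  invisible(x)
}

#' Subset a window set
#' @param ws a `window_set`.
#' @param idx integer indices of windows to keep.
#' @return A `window_set` with the selected windows.
#' @export
subset_windows <- function(ws, idx) {
  structure(list(inputs = ws$inputs[idx, , , drop = FALSE],
                 targets = ws$targets[idx, , drop = FALSE],
                 anchors = ws$anchors[idx],
                 starts = ws$starts[idx],
                 target_region = ws$target_region, spec = ws$spec),
            class = "window_set")
}

#' Chronological train/validation/test split
#'
#' Splits windows by time order: the earliest fraction trains, the middle
#' validates, the latest tests. (A random-by-window split would let training
#' windows overlap future test timepoints; chronological order preserves
#' forecasting integrity. Consecutive windows still share timepoints across
#' split boundaries, which is inherent to overlapping windows.)
#'
#' @param ws a `window_set`.
#' @param fractions length-3 positive vector `(train, val, test)` summing
#'   to 1; the canonical split is 7:2:1.
#' @param shuffle if `TRUE`, windows are permuted before splitting (provided
#'   for comparison with random splitting; off by default).
#' @param seed seed used when `shuffle = TRUE`.
#' @return List of three `window_set`s: `train`, `val`, `test`.
#' @export
split_windows <- function(ws, fractions = c(0.7, 0.2, 0.1),
                          shuffle = FALSE, seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be three positive numbers")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- dim(ws$inputs)[1L]
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop("split produces an empty subset (n = ", n, ", sizes ",
         n_train, "/", n_val, "/", n_test, ")")
  ord <- seq_len(n)
  if (shuffle) {
    set.seed(seed)
    ord <- sample(n)
  }
  list(train = subset_windows(ws, ord[seq_len(n_train)]),
       val = subset_windows(ws, ord[n_train + seq_len(n_val)]),
       test = subset_windows(ws, ord[n_train + n_val + seq_len(n_test)]))
}
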