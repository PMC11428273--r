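#' Loss weights for the hybrid objective
#'
#' The generator objective is a weighted sum of four terms:
#' `lambda_ae` x absolute-error (per-window Euclidean distance),
#' `lambda_t` x trend (sign-agreement of successive differences),
#' `lambda_dis` x distribution (gap between window means), and
#' `lambda_g` x adversarial (sigmoid cross-entropy against the
#' discriminator). Defaults are 50, 3, 1, 1.
#'
#' @param lambda_ae,lambda_t,lambda_dis,lambda_g non-negative reals.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_ae = 50, lambda_t = 3,
                         lambda_dis = 1, lambda_g = 1) {
  w <- list(lambda_ae = lambda_ae, lambda_t = lambda_t,
            lambda_dis = lambda_dis, lambda_g = lambda_g)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Sigmoid cross-entropy
#'
#' `-sum_i [B_i log sigmoid(A_i) + (1 - B_i) log(1 - sigmoid(A_i))]` over
#' logits `A` and binary labels `B`, computed in the numerically stabilized
#' form `max(A, 0) - A * B + log(1 + exp(-|A|))` so large-magnitude logits
#' neither overflow nor lose precision.
#'
#' @param logits numeric vector of unbounded scores.
#' @param labels vector of 0/1 labels, same length.
#' @return Non-negative scalar (a sum, not a mean).
#' @examples
#' sigmoid_cross_entropy(0, 1) # -log(0.5) = 0.6931
#' @export
sigmoid_cross_entropy <- function(logits, labels) {
  a <- as.numeric(logits)
  b <- as.numeric(labels)
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  if (!all(b %in% c(0, 1))) stop("labels must be 0 or 1")
  if (!all(is.finite(a))) stop("logits must be finite")
  sum(pmax(a, 0) - a * b + log1p(exp(-abs(a))))
}

#' Generator adversarial loss
#'
#' Cross-entropy of the discriminator's logits on *generated* windows
#' against all-ones labels: the generator is rewarded when the
#' discriminator scores its forecasts as real.
#'
#' @param logits_fake discriminator logits for generated windows.
#' @return Non-negative scalar.
#' @export
generator_adv_loss <- function(logits_fake) {
  sigmoid_cross_entropy(logits_fake, rep(1, length(logits_fake)))
}

#' Discriminator loss
#'
#' Cross-entropy of fake logits against 0 plus real logits against 1; zero
#' only when the discriminator separates the two perfectly.
#'
#' @param logits_fake,logits_real discriminator logits.
#' @return Non-negative scalar.
#' @export
discriminator_loss <- function(logits_fake, logits_real) {
  sigmoid_cross_entropy(logits_fake, rep(0, length(logits_fake))) +
    sigmoid_cross_entropy(logits_real, rep(1, length(logits_real)))
}

#' Absolute-error loss
#'
#' Euclidean distance `||y - yhat||_2` per window (the unsquared norm, not
#' MSE), averaged over windows when matrices are given (rows = windows).
#'
#' @param y,yhat numeric vectors (one window) or matrices (windows x H).
#' @return Non-negative scalar.
#' @export
absolute_error_loss <- function(y, yhat) {
  y <- rbind_window(y)
  yhat <- rbind_window(yhat)
  if (!all(dim(y) == dim(yhat)))
    stop("shape mismatch: ", paste(dim(y), collapse = "x"), " vs ",
         paste(dim(yhat), collapse = "x"))
  mean(sqrt(rowSums((y - yhat)^2)))
}

rbind_window <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

#' Three-valued sign comparison
#'
#' `1` if `x > y`, `0` if `x == y`, `-1` if `x < y` — the direction of a
#' step from `y` to `x`.
#'
#' @param x,y finite numerics (vectorized).
#' @return Values in `{-1, 0, 1}`.
#' @export
sign_pair <- function(x, y) {
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  sign(x - y)
}

#' Trend loss
#'
#' Compares the fluctuation direction of forecast and truth over the
#' horizon. For each adjacent pair — anchored at the last observed value, so
#' the first forecast step also has a direction — the penalty is
#' `|sign_pair(yhat_next, yhat_prev) - sign_pair(y_next, y_prev)|`, averaged
#' over the H pairs (and over windows for matrix input). The result lies in
#' `[0, 2]`: 0 when every step agrees in direction, 2 when every step is
#' opposite. Because only signs enter, the loss is invariant to any strictly
#' increasing transform applied to both series.
#'
#' @param y,yhat numeric vectors (one window) or matrices (windows x H).
#' @param anchor last observed target value(s) before the horizon (scalar or
#'   one per window).
#' @return Scalar in `[0, 2]`.
#' @export
trend_loss <- function(y, yhat, anchor) {
  y <- rbind_window(y)
  yhat <- rbind_window(yhat)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch between y and yhat")
  H <- ncol(y)
  if (H < 1L) stop("horizon must be >= 1")
  anchor <- rep_len(as.numeric(anchor), nrow(y))
  prev_y <- cbind(anchor, y[, -H, drop = FALSE])
  prev_yhat <- cbind(anchor, yhat[, -H, drop = FALSE])
  mean(abs(sign_pair(yhat, prev_yhat) - sign_pair(y, prev_y)))
}

#' Distribution loss
#'
#' Absolute gap between the mean of the true window and the mean of the
#' forecast window, averaged over windows: a first-moment match of the
#' forecast distribution to the data distribution.
#'
#' @param y,yhat numeric vectors (one window) or matrices (windows x H).
#' @return Non-negative scalar.
#' @export
distribution_loss <- function(y, yhat) {
  y <- rbind_window(y)
  yhat <- rbind_window(yhat)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch between y and yhat")
  mean(abs(rowMeans(y) - rowMeans(yhat)))
}

#' Total generator loss
#'
#' The weighted hybrid objective
#' `lambda_ae * L_ae + lambda_t * L_t + lambda_dis * L_dis + lambda_g * L_g`.
#' Setting `lambda_t = 0` removes the trend term (the "no trend loss"
#' ablation); `lambda_g = 0` removes the adversarial term.
#'
#' @param y,yhat true and forecast windows (vectors or windows x H matrices).
#' @param disc_logits_fake discriminator logits for the forecasts (or `NULL`
#'   for a purely supervised objective; the adversarial component is then 0).
#' @param weights a [loss_weights()].
#' @param anchor last observed value(s) before the horizon.
#' @return List with `total` and the unweighted `components`
#'   (`ae`, `trend`, `dist`, `adv`).
#' @export
generator_total_loss <- function(y, yhat, disc_logits_fake = NULL,
                                 weights = loss_weights(), anchor) {
  comp <- list(
    ae = absolute_error_loss(y, yhat),
    trend = trend_loss(y, yhat, anchor),
    dist = distribution_loss(y, yhat),
    adv = if (is.null(disc_logits_fake)) 0
          else generator_adv_loss(disc_logits_fake))
  total <- weights$lambda_ae * comp$ae + weights$lambda_t * comp$trend +
    weights$lambda_dis * comp$dist + weights$lambda_g * comp$adv
  list(total = total, components = comp)
}
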