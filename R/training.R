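#' Training configuration
#'
#' Training is two-phase: a supervised phase minimising the weighted
#' supervised loss (absolute error + trend + distribution), then a joint
#' adversarial phase alternating discriminator steps with generator steps on
#' the full hybrid objective. Both phases use Adam with an inverse-time-decay
#' learning rate `lr(step) = lr_init / (1 + decay_rate * step / decay_steps)`.
#' The parameters with the best validation RMSE are retained.
#'
#' @param lr_init initial learning rate (default 0.01).
#' @param decay_rate,decay_steps inverse-time-decay parameters.
#' @param batch_size windows per gradient step (default 128).
#' @param supervised_epochs,joint_epochs epochs per phase (>= 0).
#' @param d_steps_per_g_step discriminator updates per generator update in
#'   the joint phase.
#' @param grad_clip optional max absolute value applied to gradients.
#' @param weight_decay decoupled L2 weight decay applied after each Adam
#'   update (0 disables).
#' @param trend_epsilon scale of the differentiable `tanh(delta / eps)`
#'   surrogate used for the sign-based trend loss during optimisation
#'   (reported trend losses always use the exact sign form).
#' @param seed integer seed controlling initialisation and batch order.
#' @return A `train_config`.
#' @export
train_config <- function(lr_init = 0.01, decay_rate = 1, decay_steps = 50L,
                         batch_size = 128L, supervised_epochs = 50L,
                         joint_epochs = 50L, d_steps_per_g_step = 1L,
                         grad_clip = NULL, weight_decay = 0,
                         trend_epsilon = 0.01, seed = 1L) {
  if (lr_init <= 0 || decay_rate < 0 || decay_steps < 1L)
    stop("invalid learning-rate schedule")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (supervised_epochs < 0L || joint_epochs < 0L) stop("epochs must be >= 0")
  if (d_steps_per_g_step < 1L) stop("d_steps_per_g_step must be >= 1")
  if (trend_epsilon <= 0) stop("trend_epsilon must be positive")
  if (weight_decay < 0) stop("weight_decay must be >= 0")
  structure(list(lr_init = lr_init, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 batch_size = as.integer(batch_size),
                 supervised_epochs = as.integer(supervised_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 grad_clip = grad_clip, weight_decay = weight_decay,
                 trend_epsilon = trend_epsilon,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Inverse-time-decay learning rate
#' @param step 0-based global step index.
#' @param config a [train_config()].
#' @return The learning rate at `step`; monotone non-increasing in `step`.
#' @export
lr_schedule <- function(step, config) {
  config$lr_init / (1 + config$decay_rate * step / config$decay_steps)
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = NULL, weight_decay = 0) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (!is.null(clip)) g <- pmin(pmax(g, -clip), clip)
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0)
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
  }
  list(opt = opt, params = params)
}

# ---- loss graphs ------------------------------------------------------------

# supervised (+ optional adversarial) generator loss on one batch
gen_loss_graph <- function(tp, P, Pd, state, Xb, yb, anchors, weights,
                           trend_eps, adversarial) {
  g <- gen_forward_graph(tp, P, state$gen_spec, Xb)
  yhat <- g$yhat
  yconst <- ag_const(tp, yb)
  H <- ncol(yb)

  d <- ag_sub(tp, yhat, yconst)
  lae <- ag_mean(tp, ag_sqrt_shift(tp, ag_rowsums(tp, ag_mul(tp, d, d))))

  dyh <- ag_coldiff_anchor(tp, yhat, matrix(anchors, ncol = 1L))
  soft <- ag_tanh(tp, ag_smul(tp, dyh, 1 / trend_eps))
  sgn_y <- sign(yb - cbind(anchors, yb[, -H, drop = FALSE]))
  lt <- ag_mean(tp, ag_abs(tp, ag_sub(tp, soft, ag_const(tp, sgn_y))))

  mdiff <- ag_sub(tp, ag_smul(tp, ag_rowsums(tp, yhat), 1 / H),
                  ag_const(tp, matrix(rowMeans(yb), ncol = 1L)))
  ldis <- ag_mean(tp, ag_abs(tp, mdiff))

  total <- ag_add(tp, ag_add(tp, ag_smul(tp, lae, weights$lambda_ae),
                             ag_smul(tp, lt, weights$lambda_t)),
                  ag_smul(tp, ldis, weights$lambda_dis))
  ladv <- NULL
  if (adversarial && weights$lambda_g > 0) {
    logits <- disc_forward_graph(tp, Pd, state$disc_spec, yhat)
    ladv <- ag_sce_mean(tp, logits, rep(1, nrow(yb)))
    total <- ag_add(tp, total, ag_smul(tp, ladv, weights$lambda_g))
  }
  list(total = total, yhat = yhat, lae = lae, lt = lt, ldis = ldis,
       ladv = ladv)
}

collect_grads <- function(P) lapply(P, function(nd) nd$grad)

batch_indices <- function(n, batch_size) {
  starts <- seq.int(1L, n, by = batch_size)
  lapply(starts, function(s) s:min(s + batch_size - 1L, n))
}

predict_batched <- function(state, X, batch_size = 256L) {
  n <- dim(X)[1L]
  out <- matrix(0, n, state$gen_spec$H)
  for (idx in batch_indices(n, batch_size))
    out[idx, ] <- generator_forward(state, X[idx, , , drop = FALSE])
  out
}

#' Fit a forecasting model on one windowed task
#'
#' Phase 1 minimises the supervised objective (the adversarial weight is
#' excluded); phase 2 alternates discriminator updates (cross-entropy on
#' real vs generated horizon windows) with generator updates on the full
#' hybrid loss. After every epoch the validation RMSE is computed and the
#' best-validation generator parameters are restored at the end. The run is
#' reproducible given the config seed. Logged trend losses use the exact
#' sign form; optimisation uses the `tanh` surrogate.
#'
#' @param splits list with `train` and `val` [make_windows()] window sets on
#'   the normalized scale (a `test` element is ignored here).
#' @param gen_spec a [generator_spec()] matching the window dimensions.
#' @param disc_spec optional [discriminator_spec()].
#' @param weights a [loss_weights()].
#' @param config a [train_config()].
#' @return A trained `boldcast_model` with `history` (one row per gradient
#'   step: phase, epoch, step, lr, exact-sign loss components, total,
#'   discriminator loss) and `val_rmse` (per-epoch trace).
#' @export
fit_forecaster <- function(splits, gen_spec, disc_spec = NULL,
                           weights = loss_weights(), config = train_config()) {
  if (is.null(splits$train) || is.null(splits$val))
    stop("splits must contain non-empty train and val window sets")
  n_train <- dim(splits$train$inputs)[1L]
  n_val <- dim(splits$val$inputs)[1L]
  if (n_train < 1L || n_val < 1L) stop("empty train or validation split")

  state <- model_state(gen_spec, disc_spec, config$seed)
  if (config$supervised_epochs == 0L && config$joint_epochs == 0L)
    return(state)

  set.seed(config$seed)
  opt_g <- adam_new(state$gen_params)
  opt_d <- adam_new(state$disc_params)
  gstep <- 0L
  hist <- list()
  val_rmse <- numeric(0)
  # the initial state is a selection candidate too: an epoch whose updates
  # only hurt validation can never displace the starting point
  best <- list(rmse = rmse(splits$val$targets,
                           predict_batched(state, splits$val$inputs)),
               params = state$gen_params)

  log_row <- function(phase, epoch, lr, gl, d_loss) {
    yhat <- gl$yhat$value
    yb <- attr(gl, "yb")
    anchors <- attr(gl, "anchors")
    data.frame(phase = phase, epoch = epoch, step = gstep, lr = lr,
               ae = absolute_error_loss(yb, yhat),
               trend = trend_loss(yb, yhat, anchors),
               dist = distribution_loss(yb, yhat),
               adv = if (is.null(gl$ladv)) NA_real_ else gl$ladv$value[1L],
               total = gl$total$value[1L],
               d_loss = d_loss)
  }

  epoch_val <- function(epoch) {
    yhat <- predict_batched(state, splits$val$inputs)
    r <- rmse(splits$val$targets, yhat)
    val_rmse[length(val_rmse) + 1L] <<- r
    if (r < best$rmse) best <<- list(rmse = r, params = state$gen_params)
    r
  }

  run_g_step <- function(idx, phase, epoch, adversarial) {
    Xb <- splits$train$inputs[idx, , , drop = FALSE]
    yb <- splits$train$targets[idx, , drop = FALSE]
    anchors <- splits$train$anchors[idx]
    tp <- ag_tape()
    P <- param_nodes(tp, state$gen_params)
    Pd <- if (adversarial) param_nodes(tp, state$disc_params) else NULL
    gl <- gen_loss_graph(tp, P, Pd, state, Xb, yb, anchors, weights,
                         config$trend_epsilon, adversarial)
    if (!is.finite(gl$total$value[1L]))
      stop("training diverged: non-finite generator loss at step ", gstep)
    ag_backward(tp, gl$total)
    lr <- lr_schedule(gstep, config)
    upd <- adam_step(opt_g, state$gen_params, collect_grads(P), lr,
                     clip = config$grad_clip,
                     weight_decay = config$weight_decay)
    opt_g <<- upd$opt
    state$gen_params <<- upd$params
    gstep <<- gstep + 1L
    attr(gl, "yb") <- yb
    attr(gl, "anchors") <- anchors
    list(gl = gl, lr = lr)
  }

  run_d_step <- function(idx) {
    Xb <- splits$train$inputs[idx, , , drop = FALSE]
    yb <- splits$train$targets[idx, , drop = FALSE]
    fake <- generator_forward(state, Xb)  # detached: values only
    tp <- ag_tape()
    Pd <- param_nodes(tp, state$disc_params)
    lf <- disc_forward_graph(tp, Pd, state$disc_spec, ag_const(tp, fake))
    lr_ <- disc_forward_graph(tp, Pd, state$disc_spec, ag_const(tp, yb))
    loss <- ag_add(tp, ag_sce_mean(tp, lf, rep(0, nrow(yb))),
                   ag_sce_mean(tp, lr_, rep(1, nrow(yb))))
    if (!is.finite(loss$value[1L]))
      stop("training diverged: non-finite discriminator loss")
    ag_backward(tp, loss)
    lr <- lr_schedule(gstep, config)
    upd <- adam_step(opt_d, state$disc_params, collect_grads(Pd), lr,
                     clip = config$grad_clip,
                     weight_decay = config$weight_decay)
    opt_d <<- upd$opt
    state$disc_params <<- upd$params
    loss$value[1L]
  }

  for (epoch in seq_len(config$supervised_epochs)) {
    ord <- sample(n_train)
    for (idx in batch_indices(n_train, config$batch_size)) {
      r <- run_g_step(ord[idx], "supervised", epoch, adversarial = FALSE)
      hist[[length(hist) + 1L]] <- log_row("supervised", epoch, r$lr, r$gl,
                                           NA_real_)
    }
    epoch_val(epoch)
  }

  for (epoch in seq_len(config$joint_epochs)) {
    ord <- sample(n_train)
    for (idx in batch_indices(n_train, config$batch_size)) {
      d_loss <- NA_real_
      for (k in seq_len(config$d_steps_per_g_step))
        d_loss <- run_d_step(ord[idx])
      r <- run_g_step(ord[idx], "joint", epoch, adversarial = TRUE)
      hist[[length(hist) + 1L]] <- log_row("joint", epoch, r$lr, r$gl, d_loss)
    }
    epoch_val(config$supervised_epochs + epoch)
  }

  state$gen_params <- best$params
  state$history <- do.call(rbind, hist)
  state$val_rmse <- val_rmse
  state
}

#' Forecast from a trained model
#'
#' One inference-mode generator pass on a history window (normalized scale).
#'
#' @param object a `boldcast_model`.
#' @param X m x D matrix (one window) or batch x m x D array.
#' @param ... unused.
#' @return Length-H numeric vector for a single window, otherwise a
#'   batch x H matrix.
#' @export
predict.boldcast_model <- function(object, X, ...) {
  single <- is.matrix(X)
  out <- generator_forward(object, X)
  if (single) as.vector(out) else out
}

#' Persistence baseline forecast
#'
#' Repeats each window's last observed target value across the horizon — the
#' standard no-skill reference a forecaster must beat.
#'
#' @param ws a `window_set`.
#' @return n x H matrix of baseline forecasts.
#' @export
persistence_forecast <- function(ws) {
  matrix(ws$anchors, nrow = length(ws$anchors), ncol = ncol(ws$targets))
}

# ---- per-subject frequency-specific models ---------------------------------

#' Train per-(region, IMF) models for one subject
#'
#' The full frequency-specific protocol for a single subject: decompose every
#' region with VMD, keep the modes below `f_max_hz`, pair them rank-wise
#' across regions (rank 1 = lowest band everywhere), max-min-normalize each
#' region's mode series with a range fitted on the training fraction of the
#' timepoints, window, split chronologically, and fit one model per
#' (target region, mode rank).
#'
#' @param subject a [roi_series()].
#' @param wspec a [window_spec()].
#' @param targets region indices to model (default: all regions, as required
#'   for series prolongation).
#' @param vmd_cfg a [vmd_config()].
#' @param f_max_hz low-frequency cutoff for mode selection.
#' @param weights a [loss_weights()].
#' @param config a [train_config()].
#' @param fractions chronological train/val/test fractions.
#' @param gen_args named list of extra [generator_spec()] arguments
#'   (e.g. `gru_hidden`, `attn_channels`).
#' @return A `subject_models` object holding the trained states, the
#'   normalization parameters, and the normalized mode blocks needed for
#'   prolongation.
#' @export
train_subject_models <- function(subject, wspec, targets = NULL,
                                 vmd_cfg = vmd_config(),
                                 f_max_hz = 0.05,
                                 weights = loss_weights(),
                                 config = train_config(),
                                 fractions = c(0.7, 0.2, 0.1),
                                 gen_args = list()) {
  validate_roi_series(subject)
  m <- nrow(subject$data)
  T <- ncol(subject$data)
  if (is.null(targets)) targets <- seq_len(m)
  dec <- lapply(seq_len(m), function(r) {
    res <- vmd_decompose(subject$data[r, ], vmd_cfg)
    list(result = res,
         selected = select_low_modes(res, subject$tr_seconds, f_max_hz))
  })
  n_sel <- min(vapply(dec, function(d) length(d$selected), integer(1)))
  if (n_sel < 1L)
    stop("no mode below ", f_max_hz, " Hz for at least one region; ",
         "nothing to forecast")
  n_fit <- max(2L, floor(fractions[1L] * T))

  blocks <- vector("list", n_sel)
  norm_params <- vector("list", n_sel)
  for (k in seq_len(n_sel)) {
    blk <- matrix(0, m, T)
    np <- vector("list", m)
    for (r in seq_len(m)) {
      series <- dec[[r]]$result$modes[dec[[r]]$selected[k], ]
      nrm <- normalize_minmax(series[seq_len(n_fit)])
      np[[r]] <- nrm$params
      blk[r, ] <- normalize_minmax(series, nrm$params)$values
    }
    blocks[[k]] <- blk
    norm_params[[k]] <- np
  }

  models <- list()
  for (k in seq_len(n_sel)) {
    for (r in targets) {
      spec <- do.call(generator_spec,
                      c(list(m = m, D = wspec$D, H = wspec$H,
                             target_region = r), gen_args))
      splits <- split_windows(make_windows(blocks[[k]], r, wspec), fractions)
      st <- fit_forecaster(splits, spec, weights = weights, config = config)
      models[[paste0("r", r, ".imf", k)]] <-
        list(state = st, region = r, imf_rank = k, splits = splits)
    }
  }
  structure(list(models = models, blocks = blocks, norm_params = norm_params,
                 wspec = wspec, n_sel = n_sel, targets = targets,
                 subject_id = subject$subject_id,
                 region_labels = subject$region_labels,
                 tr_seconds = subject$tr_seconds, f_max_hz = f_max_hz,
                 fractions = fractions),
            class = "subject_models")
}

#' @export
print.subject_models <- function(x, ...) {
  cat(sprintf("<subject_models> subject '%s': %d models (%d regions x %d low modes)\n",
              x$subject_id, length(x$models), length(x$targets), x$n_sel))
  invisible(x)
}

#' Prolong a subject's series with model forecasts
#'
#' For every region and every selected low-frequency mode, the final D
#' normalized mode values are fed to that (region, mode) model; the H-step
#' forecasts of *all* regions are appended to the rolling history and the
#' process repeats until `extension_length` points exist (autoregressive
#' rollout). Per-region forecasts are denormalized and the selected modes
#' superposed, giving the extension that is concatenated to the original
#' series.
#'
#' @param models a [train_subject_models()] result covering every region.
#' @param subject the same [roi_series()] the models were trained on.
#' @param extension_length number of timepoints to append (> 0).
#' @return A [roi_series()] with `T + extension_length` timepoints; the
#'   attribute `imf_forecasts` holds the per-mode denormalized extensions
#'   (list of m x extension matrices) whose sum is the appended block.
#' @export
extend_series <- function(models, subject, extension_length) {
  stopifnot(inherits(models, "subject_models"))
  validate_roi_series(subject)
  if (extension_length <= 0) stop("extension_length must be positive")
  if (!identical(subject$subject_id, models$subject_id) ||
      !identical(subject$region_labels, models$region_labels))
    stop("subject does not match the one the models were trained on")
  m <- length(models$region_labels)
  missing <- setdiff(seq_len(m), models$targets)
  if (length(missing))
    stop("no trained model for region(s) ",
         paste(models$region_labels[missing], collapse = ", "),
         "; prolongation needs every region")
  D <- models$wspec$D
  H <- models$wspec$H
  n_steps <- ceiling(extension_length / H)

  imf_ext <- vector("list", models$n_sel)
  for (k in seq_len(models$n_sel)) {
    blk <- models$blocks[[k]]
    B <- blk[, (ncol(blk) - D + 1L):ncol(blk), drop = FALSE]
    preds <- matrix(0, m, n_steps * H)
    for (s in seq_len(n_steps)) {
      step_pred <- matrix(0, m, H)
      for (r in seq_len(m)) {
        st <- models$models[[paste0("r", r, ".imf", k)]]$state
        step_pred[r, ] <- predict(st, B)
      }
      preds[, ((s - 1L) * H + 1L):(s * H)] <- step_pred
      B <- cbind(B, step_pred)[, (ncol(B) + H - D + 1L):(ncol(B) + H),
                               drop = FALSE]
    }
    preds <- preds[, seq_len(extension_length), drop = FALSE]
    for (r in seq_len(m))
      preds[r, ] <- denormalize_minmax(preds[r, ], models$norm_params[[k]][[r]])
    imf_ext[[k]] <- preds
  }
  extension <- Reduce(`+`, imf_ext)
  out <- roi_series(subject$subject_id, cbind(subject$data, extension),
                    subject$region_labels, subject$tr_seconds)
  attr(out, "imf_forecasts") <- imf_ext
  out
}
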