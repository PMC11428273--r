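# Generator and discriminator architectures, built on the autodiff tape in
# autograd.R. The generator applies a temporal attention layer (1 x m
# convolution mixing regions per time step, gated through a CBAM block), a
# spatial attention layer (D x 1 convolution mixing time per region, CBAM
# gated, exposing a per-region attention vector), then a 2-layer GRU encoder
# with a fully-connected latent head, and a 2-layer GRU decoder unrolled H
# steps. The discriminator is a 3-layer GRU over H-length windows with a
# sigmoid head.

#' Generator architecture specification
#'
#' @param m number of input regions.
#' @param D history length (timepoints per window).
#' @param H forecast horizon.
#' @param target_region which input row the decoder is anchored to (its last
#'   observed value seeds the autoregressive decoder).
#' @param gru_hidden GRU state size (encoder and decoder; default 96).
#' @param fc_nodes width of the fully-connected latent layer (default 96).
#' @param attn_channels channels produced by the attention convolutions.
#' @param cbam_reduction channel-attention bottleneck ratio; must be smaller
#'   than `attn_channels`.
#' @param spatial_kernel width of the CBAM spatial-attention convolution.
#' @param enc_conv_channels channels of the encoder's 1 x m input convolution.
#' @return A `generator_spec`. GRU depth is fixed at 2 and the activation at
#'   ReLU.
#' @export
generator_spec <- function(m, D, H, target_region = 1L,
                           gru_hidden = 96L, fc_nodes = 96L,
                           attn_channels = 16L, cbam_reduction = 8L,
                           spatial_kernel = 7L, enc_conv_channels = 16L) {
  if (m < 1L || D < 4L || H < 1L)
    stop("need m >= 1, D >= 4, H >= 1")
  if (target_region < 1L || target_region > m)
    stop("target_region out of range 1..", m)
  if (cbam_reduction >= attn_channels)
    stop("cbam_reduction (", cbam_reduction,
         ") must be smaller than attn_channels (", attn_channels, ")")
  if (spatial_kernel %% 2L == 0L) stop("spatial_kernel must be odd")
  structure(list(m = as.integer(m), D = as.integer(D), H = as.integer(H),
                 target_region = as.integer(target_region),
                 gru_hidden = as.integer(gru_hidden), gru_layers = 2L,
                 fc_nodes = as.integer(fc_nodes),
                 attn_channels = as.integer(attn_channels),
                 cbam_reduction = as.integer(cbam_reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 enc_conv_channels = as.integer(enc_conv_channels)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' @param H window length scored by the discriminator.
#' @param gru_hidden GRU state size. GRU depth is fixed at 3; the output is
#'   a sigmoid score per window, strictly in (0, 1).
#' @return A `discriminator_spec`.
#' @export
discriminator_spec <- function(H, gru_hidden = 96L) {
  if (H < 1L) stop("H must be >= 1")
  structure(list(H = as.integer(H), gru_hidden = as.integer(gru_hidden),
                 gru_layers = 3L),
            class = "discriminator_spec")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# orthogonal init for recurrent weights: keeps state norms stable over long
# unrolls, which matters for the slow low-frequency signals forecast here
orthogonal <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

gru_params <- function(prefix, input_dim, hidden) {
  p <- list()
  for (gate in c("z", "r", "h")) {
    p[[paste0(prefix, ".Wx", gate)]] <- glorot(input_dim, hidden)
    p[[paste0(prefix, ".Wh", gate)]] <- orthogonal(hidden)
    p[[paste0(prefix, ".b", gate)]] <- matrix(0, 1L, hidden)
  }
  p
}

cbam_params <- function(prefix, channels, reduction, kernel) {
  hidden <- max(1L, channels %/% reduction)
  p <- list()
  p[[paste0(prefix, ".mlp.W1")]] <- glorot(channels, hidden)
  p[[paste0(prefix, ".mlp.W2")]] <- glorot(hidden, channels)
  p[[paste0(prefix, ".conv.W")]] <- glorot(2L * kernel, 1L)
  p[[paste0(prefix, ".conv.b")]] <- matrix(0, 1L, 1L)
  p
}

init_generator_params <- function(spec, seed) {
  set.seed(seed)
  C <- spec$attn_channels
  p <- c(
    list(`ta.conv.W` = glorot(spec$m, C), `ta.conv.b` = matrix(0, 1L, C)),
    cbam_params("ta.cbam", C, spec$cbam_reduction, spec$spatial_kernel),
    list(`sa.conv.W` = glorot(spec$D, C), `sa.conv.b` = matrix(0, 1L, C)),
    cbam_params("sa.cbam", C, spec$cbam_reduction, spec$spatial_kernel),
    list(`enc.conv.W` = glorot(spec$m, spec$enc_conv_channels),
         `enc.conv.b` = matrix(0, 1L, spec$enc_conv_channels)),
    gru_params("enc.gru1", spec$enc_conv_channels, spec$gru_hidden),
    gru_params("enc.gru2", spec$gru_hidden, spec$gru_hidden),
    list(`enc.fc.W` = glorot(spec$gru_hidden, spec$fc_nodes),
         `enc.fc.b` = matrix(0, 1L, spec$fc_nodes)),
    gru_params("dec.gru1", 1L + spec$fc_nodes, spec$gru_hidden),
    gru_params("dec.gru2", spec$gru_hidden, spec$gru_hidden),
    # near-zero residual head: the untrained decoder starts at the
    # persistence solution and training learns increments from there
    list(`dec.out.W` = 0.01 * glorot(spec$gru_hidden, 1L),
         `dec.out.b` = matrix(0, 1L, 1L)))
  p
}

init_discriminator_params <- function(spec, seed) {
  set.seed(seed)
  c(gru_params("d.gru1", 1L, spec$gru_hidden),
    gru_params("d.gru2", spec$gru_hidden, spec$gru_hidden),
    gru_params("d.gru3", spec$gru_hidden, spec$gru_hidden),
    list(`d.out.W` = glorot(spec$gru_hidden, 1L),
         `d.out.b` = matrix(0, 1L, 1L)))
}

#' Initialize a model state
#'
#' Bundles generator and discriminator parameters (seeded Glorot-uniform
#' weights, zero biases), their architecture specifications, the seed, and
#' an (initially empty) training history. States serialize with
#' [save_model()] / [load_model()].
#'
#' @param gen_spec a [generator_spec()].
#' @param disc_spec a [discriminator_spec()]; defaults to one matching the
#'   generator's horizon.
#' @param seed integer seed for parameter initialization.
#' @return A `boldcast_model`.
#' @export
model_state <- function(gen_spec, disc_spec = NULL, seed = 1L) {
  stopifnot(inherits(gen_spec, "generator_spec"))
  if (is.null(disc_spec))
    disc_spec <- discriminator_spec(gen_spec$H, gen_spec$gru_hidden)
  stopifnot(inherits(disc_spec, "discriminator_spec"))
  if (disc_spec$H != gen_spec$H)
    stop("discriminator window length must equal the generator horizon")
  structure(list(gen_spec = gen_spec, disc_spec = disc_spec,
                 seed = as.integer(seed),
                 gen_params = init_generator_params(gen_spec, seed),
                 disc_params = init_discriminator_params(disc_spec, seed + 1L),
                 history = NULL, val_rmse = numeric(0)),
            class = "boldcast_model")
}

#' @export
print.boldcast_model <- function(x, ...) {
  cat(sprintf(paste0("<boldcast_model> m=%d D=%d H=%d target=%d | ",
                     "GRU hidden %d, FC %d | %s\n"),
              x$gen_spec$m, x$gen_spec$D, x$gen_spec$H,
              x$gen_spec$target_region, x$gen_spec$gru_hidden,
              x$gen_spec$fc_nodes,
              if (is.null(x$history)) "untrained"
              else sprintf("trained (%d logged steps)", nrow(x$history))))
  invisible(x)
}

#' Save / load a model state
#' @param state a `boldcast_model`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `boldcast_model`, bit-identical to the saved one.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "boldcast_model"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "boldcast_model"))
  state
}

# ---- graph builders ---------------------------------------------------------

param_nodes <- function(tp, params) lapply(params, function(v) ag_param(tp, v))

# one batched GRU step; x: batch x in, h: batch x hidden (nodes)
gru_cell <- function(tp, P, prefix, x, h) {
  gate <- function(g, act) {
    pre <- ag_add_bias(tp,
      ag_add(tp, ag_matmul(tp, x, P[[paste0(prefix, ".Wx", g)]]),
             ag_matmul(tp, h, P[[paste0(prefix, ".Wh", g)]])),
      P[[paste0(prefix, ".b", g)]])
    act(tp, pre)
  }
  z <- gate("z", ag_sigmoid)
  r <- gate("r", ag_sigmoid)
  rh <- ag_mul(tp, r, h)
  pre_h <- ag_add_bias(tp,
    ag_add(tp, ag_matmul(tp, x, P[[paste0(prefix, ".Wxh")]]),
           ag_matmul(tp, rh, P[[paste0(prefix, ".Whh")]])),
    P[[paste0(prefix, ".bh")]])
  htil <- ag_tanh(tp, pre_h)
  ag_add(tp, ag_mul(tp, ag_oneminus(tp, z), h), ag_mul(tp, z, htil))
}

# CBAM over a list of feature nodes (one batch x C node per position).
# Channel attention: shared MLP on average- and max-pooled channel vectors,
# summed, sigmoid-gated. Spatial attention: channel-wise mean/max per
# position, a width-k convolution over positions, sigmoid gate per position.
# Returns gated features, per-position gates, and the channel gate.
cbam_graph <- function(tp, P, prefix, feats, kernel) {
  L <- length(feats)
  avg <- ag_smul(tp, Reduce(function(a, b) ag_add(tp, a, b), feats), 1 / L)
  mx <- Reduce(function(a, b) ag_max2(tp, a, b), feats)
  mlp <- function(v) {
    ag_matmul(tp, ag_relu(tp, ag_matmul(tp, v, P[[paste0(prefix, ".mlp.W1")]])),
              P[[paste0(prefix, ".mlp.W2")]])
  }
  ac <- ag_sigmoid(tp, ag_add(tp, mlp(avg), mlp(mx)))
  fprime <- lapply(feats, function(f) ag_mul(tp, f, ac))
  C <- ncol(feats[[1L]]$value)
  batch <- nrow(feats[[1L]]$value)
  pooled <- lapply(fprime, function(f) {
    ag_cbind(tp, list(ag_smul(tp, ag_rowsums(tp, f), 1 / C),
                      ag_rowmax(tp, f)))  # batch x 2
  })
  kh <- (kernel - 1L) %/% 2L
  zero2 <- ag_const(tp, matrix(0, batch, 2L))
  gates <- vector("list", L)
  for (i in seq_len(L)) {
    win <- lapply((i - kh):(i + kh), function(j) {
      if (j < 1L || j > L) zero2 else pooled[[j]]
    })
    pre <- ag_add_bias(tp,
      ag_matmul(tp, ag_cbind(tp, win), P[[paste0(prefix, ".conv.W")]]),
      P[[paste0(prefix, ".conv.b")]])
    gates[[i]] <- ag_sigmoid(tp, pre)  # batch x 1
  }
  out <- mapply(function(f, s) ag_scale_rows(tp, f, s), fprime, gates,
                SIMPLIFY = FALSE)
  list(out = out, gates = gates, channel_gate = ac)
}

# slice timepoint t of a batch x m x D array as a batch x m matrix
slice_t <- function(X, t) matrix(X[, , t], dim(X)[1L], dim(X)[2L])

# full generator graph; X: batch x m x D numeric array (normalized scale)
gen_forward_graph <- function(tp, P, spec, X) {
  batch <- dim(X)[1L]
  Xt <- lapply(seq_len(spec$D), function(t) ag_const(tp, slice_t(X, t)))

  # temporal attention: 1 x m conv per time step -> CBAM over time positions
  feats_t <- lapply(Xt, function(x) {
    ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, x, P$ta.conv.W), P$ta.conv.b))
  })
  cb_t <- cbam_graph(tp, P, "ta.cbam", feats_t, spec$spatial_kernel)
  X1 <- mapply(function(x, s) ag_scale_rows(tp, x, s), Xt, cb_t$gates,
               SIMPLIFY = FALSE)

  # spatial attention: D x 1 conv per region -> CBAM over region positions
  feats_s <- lapply(seq_len(spec$m), function(r) {
    xr <- ag_cbind(tp, lapply(X1, function(x) ag_col(tp, x, r)))  # batch x D
    ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, xr, P$sa.conv.W), P$sa.conv.b))
  })
  cb_s <- cbam_graph(tp, P, "sa.cbam", feats_s, spec$spatial_kernel)
  A <- ag_cbind(tp, cb_s$gates)  # batch x m region attention
  X2 <- lapply(X1, function(x) ag_mul(tp, x, A))

  # encoder: 1 x m conv on the attended block, then 2-layer GRU, FC latent
  h1 <- ag_const(tp, matrix(0, batch, spec$gru_hidden))
  h2 <- h1
  for (t in seq_len(spec$D)) {
    et <- ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, X2[[t]], P$enc.conv.W),
                                  P$enc.conv.b))
    h1 <- gru_cell(tp, P, "enc.gru1", et, h1)
    h2 <- gru_cell(tp, P, "enc.gru2", h1, h2)
  }
  latent <- ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, h2, P$enc.fc.W),
                                    P$enc.fc.b))

  # decoder: 2-layer GRU unrolled H steps from the encoder state,
  # autoregressive on its own output, seeded with the last observed value;
  # the head is residual (each step emits an increment on the previous
  # value), so the decoder learns local slope corrections
  d1 <- h1
  d2 <- h2
  prev <- ag_const(tp, matrix(X[, spec$target_region, spec$D], batch, 1L))
  outs <- vector("list", spec$H)
  for (s in seq_len(spec$H)) {
    din <- ag_cbind(tp, list(prev, latent))
    d1 <- gru_cell(tp, P, "dec.gru1", din, d1)
    d2 <- gru_cell(tp, P, "dec.gru2", d1, d2)
    outs[[s]] <- ag_add(tp, prev,
                        ag_add_bias(tp, ag_matmul(tp, d2, P$dec.out.W),
                                    P$dec.out.b))
    prev <- outs[[s]]
  }
  yhat <- ag_cbind(tp, outs)  # batch x H
  list(yhat = yhat,
       region_attention = colMeans(A$value),
       temporal_weights = colMeans(do.call(cbind,
                                           lapply(cb_t$gates, `[[`, "value"))))
}

# discriminator graph; W: batch x H node (may carry gradients from G)
disc_forward_graph <- function(tp, P, spec, W) {
  batch <- nrow(W$value)
  h1 <- ag_const(tp, matrix(0, batch, spec$gru_hidden))
  h2 <- h1
  h3 <- h1
  for (t in seq_len(spec$H)) {
    xt <- ag_col(tp, W, t)
    h1 <- gru_cell(tp, P, "d.gru1", xt, h1)
    h2 <- gru_cell(tp, P, "d.gru2", h1, h2)
    h3 <- gru_cell(tp, P, "d.gru3", h2, h3)
  }
  ag_add_bias(tp, ag_matmul(tp, ag_relu(tp, h3), P$d.out.W), P$d.out.b)
}

as_batch_array <- function(X, spec) {
  if (is.matrix(X)) {
    if (!all(dim(X) == c(spec$m, spec$D)))
      stop("input must be m x D = ", spec$m, " x ", spec$D, ", got ",
           paste(dim(X), collapse = " x "))
    X <- array(X, dim = c(1L, spec$m, spec$D))
  }
  if (length(dim(X)) != 3L || dim(X)[2L] != spec$m || dim(X)[3L] != spec$D)
    stop("input must be batch x m x D with m = ", spec$m, ", D = ", spec$D)
  X
}

#' Generator forward pass
#'
#' Runs the dual-attention GRU encoder-decoder in inference mode:
#' deterministic given the model state. Inputs are expected on the
#' normalized `[0, 1]` scale.
#'
#' @param state a [model_state()].
#' @param X one window (m x D matrix) or a batch (batch x m x D array).
#' @return batch x H matrix of forecasts, with attributes
#'   `region_attention` (mean per-region attention, in (0, 1)) and
#'   `temporal_weights` (mean per-time-step attention).
#' @export
generator_forward <- function(state, X) {
  stopifnot(inherits(state, "boldcast_model"))
  X <- as_batch_array(X, state$gen_spec)
  tp <- ag_tape()
  P <- param_nodes(tp, state$gen_params)
  g <- gen_forward_graph(tp, P, state$gen_spec, X)
  out <- g$yhat$value
  attr(out, "region_attention") <- g$region_attention
  attr(out, "temporal_weights") <- g$temporal_weights
  out
}

#' Discriminator forward pass
#'
#' Scores each H-length window with the 3-layer GRU discriminator; outputs
#' are sigmoid scores, strictly in (0, 1).
#'
#' @param state a [model_state()].
#' @param W numeric vector (one window) or batch x H matrix.
#' @return Numeric vector of per-window scores.
#' @export
discriminator_forward <- function(state, W) {
  stopifnot(inherits(state, "boldcast_model"))
  W <- rbind_window(W)
  if (ncol(W) != state$disc_spec$H)
    stop("window length ", ncol(W), " does not match discriminator H = ",
         state$disc_spec$H)
  if (!all(is.finite(W))) stop("windows must be finite")
  tp <- ag_tape()
  P <- param_nodes(tp, state$disc_params)
  logits <- disc_forward_graph(tp, P, state$disc_spec, ag_const(tp, W))
  as.vector(1 / (1 + exp(-logits$value)))
}

#' Convolutional block attention on a feature block
#'
#' Standalone CBAM: channel attention (average- and max-pooled channel
#' vectors through a shared two-layer MLP, summed, sigmoid) gates the
#' channels, then spatial attention (channel-wise mean/max maps through a
#' width-`spatial_kernel` convolution, sigmoid) gates the positions. Output
#' shape equals input shape; gating is multiplicative, so a zero block maps
#' to zero. Weights are seeded draws — this entry point exists to expose the
#' attention computation itself (the trained pipeline owns its weights
#' inside the generator).
#'
#' @param F numeric C x L matrix (channels x positions) or batch x C x L
#'   array.
#' @param reduction channel bottleneck ratio (must be < C).
#' @param spatial_kernel odd convolution width.
#' @param seed seed for the CBAM weights.
#' @return Attended block, same shape as `F`, with attributes
#'   `channel_attention` and `spatial_attention` (values in (0, 1)).
#' @export
cbam_attention <- function(F, reduction = 8L, spatial_kernel = 7L, seed = 1L) {
  was_mat <- is.matrix(F)
  if (was_mat) {
    A <- array(0, dim = c(1L, nrow(F), ncol(F)))
    A[1L, , ] <- F
    F <- A
  }
  if (length(dim(F)) != 3L) stop("F must be C x L or batch x C x L")
  C <- dim(F)[2L]
  L <- dim(F)[3L]
  if (reduction >= C)
    stop("reduction (", reduction, ") must be smaller than the channel count (",
         C, ")")
  if (!all(is.finite(F))) stop("F must be finite")
  set.seed(seed)
  P0 <- cbam_params("cbam", C, as.integer(reduction),
                    as.integer(spatial_kernel))
  tp <- ag_tape()
  P <- param_nodes(tp, P0)
  feats <- lapply(seq_len(L), function(l) ag_const(tp, slice_t(F, l)))
  cb <- cbam_graph(tp, P, "cbam", feats, as.integer(spatial_kernel))
  out <- array(0, dim = dim(F))
  for (l in seq_len(L)) out[, , l] <- cb$out[[l]]$value
  sp <- do.call(cbind, lapply(cb$gates, `[[`, "value"))
  if (was_mat) out <- matrix(out[1L, , ], C, L)
  attr(out, "channel_attention") <- cb$channel_gate$value
  attr(out, "spatial_attention") <- sp
  out
}

#' Temporal attention layer (standalone)
#'
#' The generator's first stage in isolation: a 1 x m convolution mixes the
#' regions at each time step into `attn_channels` features, a CBAM block
#' gates them, and the per-time-step sigmoid gates reweight the input
#' window. Output shape equals input shape.
#'
#' @param X m x D matrix or batch x m x D array (regions x time).
#' @param attn_channels,reduction,spatial_kernel,seed architecture knobs as
#'   in [generator_spec()].
#' @return Weighted block, same shape as `X`, with attribute
#'   `temporal_weights` (per-time-step gates in (0, 1)).
#' @export
temporal_attention_layer <- function(X, attn_channels = 16L, reduction = 8L,
                                     spatial_kernel = 7L, seed = 1L) {
  was_mat <- is.matrix(X)
  if (was_mat) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  m <- dim(X)[2L]
  D <- dim(X)[3L]
  set.seed(seed)
  P0 <- c(list(`ta.conv.W` = glorot(m, attn_channels),
               `ta.conv.b` = matrix(0, 1L, attn_channels)),
          cbam_params("ta.cbam", attn_channels, as.integer(reduction),
                      as.integer(spatial_kernel)))
  tp <- ag_tape()
  P <- param_nodes(tp, P0)
  Xt <- lapply(seq_len(D), function(t) ag_const(tp, slice_t(X, t)))
  feats <- lapply(Xt, function(x) {
    ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, x, P$ta.conv.W), P$ta.conv.b))
  })
  cb <- cbam_graph(tp, P, "ta.cbam", feats, as.integer(spatial_kernel))
  out <- array(0, dim = dim(X))
  for (t in seq_len(D))
    out[, , t] <- ag_scale_rows(tp, Xt[[t]], cb$gates[[t]])$value
  w <- do.call(cbind, lapply(cb$gates, `[[`, "value"))
  if (was_mat) out <- matrix(out[1L, , ], m, D)
  attr(out, "temporal_weights") <- w
  out
}

#' Spatial attention layer (standalone)
#'
#' The generator's second stage in isolation: a D x 1 convolution mixes time
#' per region, a CBAM block gates the region features, and the per-region
#' sigmoid gates — the region attention vector, interpretable as each
#' region's contribution to the prediction — reweight the input window.
#'
#' @param X m x D matrix or batch x m x D array.
#' @inheritParams temporal_attention_layer
#' @return Weighted block, same shape as `X`, with attribute
#'   `region_attention` (per-region gates in (0, 1)).
#' @export
spatial_attention_layer <- function(X, attn_channels = 16L, reduction = 8L,
                                    spatial_kernel = 7L, seed = 1L) {
  was_mat <- is.matrix(X)
  if (was_mat) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  m <- dim(X)[2L]
  D <- dim(X)[3L]
  set.seed(seed)
  P0 <- c(list(`sa.conv.W` = glorot(D, attn_channels),
               `sa.conv.b` = matrix(0, 1L, attn_channels)),
          cbam_params("sa.cbam", attn_channels, as.integer(reduction),
                      as.integer(spatial_kernel)))
  tp <- ag_tape()
  P <- param_nodes(tp, P0)
  Xt <- lapply(seq_len(D), function(t) ag_const(tp, slice_t(X, t)))
  feats <- lapply(seq_len(m), function(r) {
    xr <- ag_cbind(tp, lapply(Xt, function(x) ag_col(tp, x, r)))
    ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, xr, P$sa.conv.W), P$sa.conv.b))
  })
  cb <- cbam_graph(tp, P, "sa.cbam", feats, as.integer(spatial_kernel))
  A <- do.call(cbind, lapply(cb$gates, `[[`, "value"))  # batch x m
  out <- array(0, dim = dim(X))
  for (t in seq_len(D)) out[, , t] <- slice_t(X, t) * A
  if (was_mat) out <- matrix(out[1L, , ], m, D)
  attr(out, "region_attention") <- A
  out
}
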