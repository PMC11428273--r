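# shared fixtures built in code

# exhaustive DTW oracle: enumerate all monotone paths (lengths <= ~7)
dtw_bruteforce <- function(y, yhat) {
  n <- length(y)
  m <- length(yhat)
  rec <- function(i, j) {
    cost <- abs(y[i] - yhat[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(n, m)
}

# FFT peak frequency in cycles/sample
fft_peak <- function(x) {
  T <- length(x)
  sp <- Mod(stats::fft(x))[2:(T %/% 2)]
  which.max(sp) / T
}

# a small, smooth multivariate forecasting task (normalized block + splits)
tiny_task <- function(T = 160L, m = 3L, D = 12L, H = 6L, seed = 5L,
                      noise = 0) {
  set.seed(seed)
  tt <- seq_len(T)
  blk <- matrix(0, m, T)
  for (r in seq_len(m)) {
    blk[r, ] <- sin(2 * pi * 0.015 * tt + r) +
      0.4 * sin(2 * pi * 0.04 * tt + 2 * r) +
      if (noise > 0) rnorm(T, 0, noise) else 0
  }
  nb <- t(apply(blk, 1, function(y) normalize_minmax(y)$values))
  ws <- make_windows(nb, 1L, window_spec(D, H))
  split_windows(ws)
}

tiny_gen_spec <- function(m = 3L, D = 12L, H = 6L, target = 1L) {
  generator_spec(m = m, D = D, H = H, target_region = target,
                 gru_hidden = 12L, fc_nodes = 12L, attn_channels = 8L,
                 cbam_reduction = 4L, spatial_kernel = 3L,
                 enc_conv_channels = 4L)
}

tiny_train_config <- function(supervised = 2L, joint = 0L, seed = 9L) {
  train_config(batch_size = 32L, supervised_epochs = supervised,
               joint_epochs = joint, seed = seed)
}
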