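test_that("spec constructors validate architecture constraints", {
  expect_error(generator_spec(m = 4, D = 8, H = 2, cbam_reduction = 16,
                              attn_channels = 16), "smaller than")
  expect_error(generator_spec(m = 4, D = 2, H = 2), "D >= 4")
  expect_error(generator_spec(m = 4, D = 8, H = 2, target_region = 5),
               "out of range")
  expect_error(discriminator_spec(0), "H")
  s <- generator_spec(m = 4, D = 8, H = 2)
  expect_identical(s$gru_layers, 2L)
  expect_identical(discriminator_spec(2)$gru_layers, 3L)
})

test_that("generator shape contract holds across (m, D, H) corners", {
  for (dims in list(c(1, 4, 1), c(3, 6, 2), c(5, 10, 7))) {
    spec <- generator_spec(m = dims[1], D = dims[2], H = dims[3],
                           gru_hidden = 8L, fc_nodes = 8L, attn_channels = 8L,
                           cbam_reduction = 4L, spatial_kernel = 3L,
                           enc_conv_channels = 4L)
    st <- model_state(spec, seed = 3)
    X <- array(runif(2 * dims[1] * dims[2]), c(2, dims[1], dims[2]))
    y <- generator_forward(st, X)
    expect_equal(dim(y), c(2L, dims[3]))
    expect_true(all(is.finite(y)))
    ra <- attr(y, "region_attention")
    expect_length(ra, dims[1])
    expect_true(all(ra > 0 & ra < 1))
  }
})

test_that("inference is deterministic and batch-consistent", {
  spec <- tiny_gen_spec()
  st <- model_state(spec, seed = 11)
  X1 <- matrix(runif(3 * 12), 3, 12)
  Xb <- array(0, c(4, 3, 12))
  for (i in 1:4) Xb[i, , ] <- X1  # identical windows
  out <- generator_forward(st, Xb)
  for (i in 2:4) expect_equal(out[i, ], out[1, ], tolerance = 1e-12)
  expect_equal(as.vector(generator_forward(st, X1)), out[1, ],
               tolerance = 1e-12)
  expect_error(generator_forward(st, matrix(0, 2, 12)), "m x D")
})

test_that("discriminator scores are strictly inside (0, 1) and repeatable", {
  st <- model_state(tiny_gen_spec(), seed = 5)
  W <- matrix(runif(6 * 6), 6, 6)
  s1 <- discriminator_forward(st, W)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, discriminator_forward(st, W))
  expect_equal(discriminator_forward(st, rbind(W[2, ], W[2, ]))[1],
               s1[2], tolerance = 1e-12)
  expect_error(discriminator_forward(st, matrix(0, 2, 5)), "does not match")
})

test_that("model states serialize and reload bit-exactly", {
  st <- model_state(tiny_gen_spec(), seed = 21)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(st, path)
  expect_identical(load_model(path), st)
})

test_that("cbam attention gates multiplicatively with sigmoid maps", {
  F0 <- matrix(0, 8, 10)
  out0 <- cbam_attention(F0, reduction = 4, spatial_kernel = 3)
  expect_equal(matrix(out0, 8, 10), F0)  # zero in, zero out

  F1 <- matrix(rnorm(80), 8, 10)
  out1 <- cbam_attention(F1, reduction = 4, spatial_kernel = 3)
  expect_equal(dim(out1), dim(F1))
  ca <- attr(out1, "channel_attention")
  sa <- attr(out1, "spatial_attention")
  expect_true(all(ca > 0 & ca < 1))
  expect_true(all(sa > 0 & sa < 1))
  expect_error(cbam_attention(F1, reduction = 8), "smaller than")
})

test_that("temporal attention preserves shape and reports time weights", {
  X <- matrix(rnorm(4 * 10), 4, 10)
  out <- temporal_attention_layer(X, attn_channels = 8, reduction = 4,
                                  spatial_kernel = 3)
  expect_equal(dim(out), dim(X))
  w <- attr(out, "temporal_weights")
  expect_length(as.vector(w), 10L)
  expect_true(all(w > 0 & w < 1))
  z <- temporal_attention_layer(matrix(0, 4, 10), attn_channels = 8,
                                reduction = 4, spatial_kernel = 3)
  expect_equal(matrix(z, 4, 10), matrix(0, 4, 10))
})

test_that("spatial attention exposes a per-region attention vector", {
  X <- matrix(rnorm(5 * 8), 5, 8)
  out <- spatial_attention_layer(X, attn_channels = 8, reduction = 4,
                                 spatial_kernel = 3)
  expect_equal(dim(out), dim(X))
  a <- as.vector(attr(out, "region_attention"))
  expect_length(a, 5L)
  expect_true(all(a > 0 & a < 1))
})

test_that("a trained model attends to the informative auxiliary region", {
  # region 2 duplicates the target's signal; regions 3-4 are pure noise
  set.seed(42)
  T <- 200
  base <- sin(2 * pi * 0.02 * seq_len(T))
  blk <- rbind(base + rnorm(T, 0, 0.05),
               base + rnorm(T, 0, 0.05),
               rnorm(T), rnorm(T))
  nb <- t(apply(blk, 1, function(y) normalize_minmax(y)$values))
  sp <- split_windows(make_windows(nb, 1, window_spec(12, 6)))
  st <- fit_forecaster(sp, tiny_gen_spec(m = 4),
                       config = tiny_train_config(6, 0, seed = 9))
  y <- generator_forward(st, sp$test$inputs)
  att <- attr(y, "region_attention")
  expect_gte(att[2], median(att[3:4]))
})
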