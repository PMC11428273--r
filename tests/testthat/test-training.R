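test_that("the learning-rate schedule is inverse-time and non-increasing", {
  cfg <- train_config(lr_init = 0.01, decay_rate = 1, decay_steps = 100)
  expect_equal(lr_schedule(0, cfg), 0.01)
  expect_equal(lr_schedule(100, cfg), 0.005)
  lrs <- vapply(0:50, lr_schedule, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(train_config(lr_init = 0), "schedule")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("zero epochs return the seeded initial state unchanged", {
  sp <- tiny_task()
  spec <- tiny_gen_spec()
  st <- fit_forecaster(sp, spec, config = tiny_train_config(0L, 0L, seed = 7))
  expect_identical(st$gen_params, model_state(spec, seed = 7L)$gen_params)
  expect_null(st$history)
})

test_that("a short supervised run reduces validation RMSE and logs finely", {
  sp <- tiny_task()
  st <- fit_forecaster(sp, tiny_gen_spec(),
                       config = tiny_train_config(3L, 1L, seed = 9))
  expect_true(all(is.finite(st$history$total)))
  expect_true(all(is.finite(st$history$ae)))
  expect_lte(min(st$val_rmse), st$val_rmse[1])
  expect_identical(unique(st$history$phase), c("supervised", "joint"))
  # joint-phase rows carry adversarial and discriminator losses
  joint <- st$history[st$history$phase == "joint", ]
  expect_true(all(is.finite(joint$adv)))
  expect_true(all(is.finite(joint$d_loss)))
  sup <- st$history[st$history$phase == "supervised", ]
  expect_true(all(is.na(sup$adv)))
})

test_that("training is seed-deterministic end to end", {
  sp <- tiny_task()
  a <- fit_forecaster(sp, tiny_gen_spec(), config = tiny_train_config(2L, 1L))
  b <- fit_forecaster(sp, tiny_gen_spec(), config = tiny_train_config(2L, 1L))
  expect_identical(a$val_rmse, b$val_rmse)
  expect_identical(a$gen_params, b$gen_params)
  expect_equal(predict(a, sp$test$inputs[1, , ]),
               predict(b, sp$test$inputs[1, , ]), tolerance = 1e-15)
})

test_that("forecasts have horizon length and beat persistence on a clean tone", {
  sp <- tiny_task(T = 200, noise = 0)
  st <- fit_forecaster(sp, tiny_gen_spec(),
                       config = tiny_train_config(4L, 0L, seed = 3))
  one <- predict(st, sp$test$inputs[1, , ])
  expect_length(one, 6L)
  yhat <- boldcast:::predict_batched(st, sp$test$inputs)
  expect_lt(rmse(sp$test$targets, yhat),
            rmse(sp$test$targets, persistence_forecast(sp$test)))
})

test_that("after joint training the discriminator separates real from fake", {
  # purely adversarial objective: the generator stays imperfect, so the
  # discriminator's learned real/fake margin is visible on held-out windows
  sp <- tiny_task(T = 220, noise = 0.15, seed = 5)
  st <- fit_forecaster(sp, tiny_gen_spec(),
                       weights = loss_weights(lambda_ae = 0, lambda_t = 0,
                                              lambda_dis = 0, lambda_g = 1),
                       config = train_config(batch_size = 32L,
                                             supervised_epochs = 0L,
                                             joint_epochs = 5L,
                                             d_steps_per_g_step = 3L,
                                             seed = 13L))
  fake <- boldcast:::predict_batched(st, sp$test$inputs)
  expect_gt(mean(discriminator_forward(st, sp$test$targets)),
            mean(discriminator_forward(st, fake)))
})

test_that("per-subject models cover every (region, low-mode) pair", {
  cfg <- synthetic_config(n_subjects = 1, m = 3, T = 220, noise_sigma = 0.1,
                          coupling = coupling_matrix(3, 0.4), seed = 31)
  sub <- generate_subject(cfg, 1)
  sm <- train_subject_models(
    sub, window_spec(12L, 6L), vmd_cfg = vmd_config(K = 2),
    config = tiny_train_config(1L, 0L),
    gen_args = list(gru_hidden = 8L, fc_nodes = 8L, attn_channels = 8L,
                    cbam_reduction = 4L, spatial_kernel = 3L,
                    enc_conv_channels = 4L))
  expect_s3_class(sm, "subject_models")
  expect_length(sm$models, 3L * sm$n_sel)
  expect_gte(sm$n_sel, 1L)

  ext <- extend_series(sm, sub, 9L)
  expect_equal(ncol(ext$data), 220L + 9L)
  expect_equal(ext$data[, 1:220], sub$data)
  # superposition: the appended block is exactly the sum of per-mode forecasts
  imf <- attr(ext, "imf_forecasts")
  expect_equal(Reduce(`+`, imf), ext$data[, 221:229, drop = FALSE])
  expect_error(extend_series(sm, sub, 0), "positive")

  partial <- train_subject_models(
    sub, window_spec(12L, 6L), targets = 1L, vmd_cfg = vmd_config(K = 2),
    config = tiny_train_config(0L, 0L),
    gen_args = list(gru_hidden = 8L, fc_nodes = 8L, attn_channels = 8L,
                    cbam_reduction = 4L, spatial_kernel = 3L,
                    enc_conv_channels = 4L))
  expect_error(extend_series(partial, sub, 6L), "every region")
})
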