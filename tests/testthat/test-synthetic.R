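test_that("config validation enforces bands, coupling and noise bounds", {
  expect_error(synthetic_config(band_freqs_hz = list(c(0.05, 0.01)),
                                amplitudes = 1), "low < high")
  expect_error(synthetic_config(tr_seconds = 2,
                                band_freqs_hz = list(c(0.1, 0.3)),
                                amplitudes = 1), "Nyquist")
  expect_error(synthetic_config(coupling = diag(3), m = 4), "m x m")
  expect_error(synthetic_config(ar_coeff = 1), "ar_coeff")
  expect_error(coupling_matrix(4, 1), "strength")
  expect_equal(rowSums(coupling_matrix(5, 0.4)), rep(1, 5))
})

test_that("a noiseless single component peaks at its configured frequency", {
  cfg <- synthetic_config(n_subjects = 1, m = 4, T = 1024, tr_seconds = 1,
                          band_freqs_hz = list(c(0.0199, 0.0201)),
                          amplitudes = 1, noise_sigma = 0, seed = 6)
  sub <- generate_subject(cfg, 1)
  for (r in 1:4) {
    pk <- fft_peak(sub$data[r, ])  # cycles/sample = Hz at TR 1
    expect_lt(abs(pk - 0.02), 1.5 / 1024)  # within one FFT bin
  }
})

test_that("generation is a pure function of (config, subject_index)", {
  cfg <- synthetic_config(n_subjects = 3, m = 3, T = 150, seed = 11)
  expect_identical(generate_subject(cfg, 2)$data, generate_subject(cfg, 2)$data)
  expect_false(identical(generate_subject(cfg, 1)$data,
                         generate_subject(cfg, 2)$data))
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
})

test_that("ground-truth components plus noise rebuild the series exactly", {
  cfg <- synthetic_config(n_subjects = 1, m = 5, T = 300,
                          coupling = coupling_matrix(5, 0.4), seed = 13)
  gt <- ground_truth_components(cfg, 1)
  sub <- generate_subject(cfg, 1)
  expect_identical(Reduce(`+`, gt$components) + gt$noise, sub$data)

  # each component is band-limited: >= 95% of spectral energy in its band
  comp1 <- gt$components[[1]][1, ]
  T <- length(comp1)
  freqs_hz <- (seq_len(T %/% 2) - 1) / (T * cfg$tr_seconds)
  sp <- Mod(stats::fft(comp1))[seq_len(T %/% 2)]^2
  band <- cfg$band_freqs_hz[[1]]
  inband <- freqs_hz >= band[1] * 0.7 & freqs_hz <= band[2] * 1.3
  expect_gt(sum(sp[inband]) / sum(sp), 0.95)

  # zero-amplitude component is identically zero
  cfg0 <- synthetic_config(n_subjects = 1, m = 2, T = 100,
                           band_freqs_hz = list(c(0.01, 0.02), c(0.03, 0.05)),
                           amplitudes = c(1, 0), seed = 3)
  expect_true(all(ground_truth_components(cfg0, 1)$components[[2]] == 0))
})

test_that("cohort generation yields valid subjects of the requested size", {
  cfg <- synthetic_config(n_subjects = 10, m = 6, T = 600, seed = 17)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 10L)
  for (s in co$subjects) {
    expect_s3_class(s, "roi_series")
    expect_equal(dim(s$data), c(6L, 600L))
  }
  # series of >= 250 points (the regime where prediction is acceptable)
  expect_gte(ncol(co$subjects[[1]]$data), 250L)
})

test_that("VMD recovers the two configured bands from generated data", {
  cfg <- synthetic_config(n_subjects = 1, m = 2, T = 600, noise_sigma = 0.05,
                          seed = 19)
  sub <- generate_subject(cfg, 1)
  set.seed(19)
  for (r in 1:2) {
    res <- vmd_decompose(sub$data[r, ], vmd_config(K = 2))
    hz <- center_freqs_hz(res, cfg$tr_seconds)
    # centers fall in (or within 15% of) the generating bands
    expect_gt(hz[1], cfg$band_freqs_hz[[1]][1] * 0.85)
    expect_lt(hz[1], cfg$band_freqs_hz[[1]][2] * 1.15)
    expect_gt(hz[2], cfg$band_freqs_hz[[2]][1] * 0.85)
    expect_lt(hz[2], cfg$band_freqs_hz[[2]][2] * 1.15)
  }
})

test_that("coupling induces the functional connectivity it promises", {
  cfg <- synthetic_config(n_subjects = 8, m = 4, T = 400, noise_sigma = 0.1,
                          coupling = coupling_matrix(4, 0.6), seed = 23)
  co <- generate_cohort(cfg)
  r12 <- vapply(co$subjects,
                function(s) fc_matrix(s)$values[1, 2], numeric(1))
  expect_gt(mean(abs(r12)), 0.5)

  # identity coupling: regions near-uncorrelated on average
  cfg0 <- synthetic_config(n_subjects = 8, m = 4, T = 400, noise_sigma = 0.1,
                           seed = 23)
  r12_0 <- vapply(generate_cohort(cfg0)$subjects,
                  function(s) fc_matrix(s)$values[1, 2], numeric(1))
  expect_lt(mean(abs(r12_0)), mean(abs(r12)))
})
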