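test_that("FC matrices are symmetric with unit diagonal and exact extremes", {
  base <- rnorm(50)
  s <- roi_series("s", rbind(base, base, -base + 0.5, rnorm(50)),
                  c("a", "b", "c", "d"), 1)
  fc <- fc_matrix(s)
  expect_equal(fc$values, t(fc$values))
  expect_equal(diag(fc$values), rep(1, 4), ignore_attr = TRUE)
  expect_equal(fc$values["a", "b"], 1)
  expect_equal(fc$values["a", "c"], -1)

  cs <- roi_series("s", rbind(rnorm(10), rep(1, 10)), c("a", "b"), 1)
  expect_error(fc_matrix(cs), "constant series for region 'b'")
})

test_that("independent white noise gives near-zero FC at large T", {
  set.seed(21)
  s <- roi_series("s", matrix(rnorm(5 * 2000), 5, 2000),
                  sprintf("r%d", 1:5), 1)
  fc <- fc_matrix(s)
  off <- fc$values[upper.tri(fc$values)]
  expect_true(all(abs(off) < 0.08))  # 99% bound at T = 2000
})

test_that("FC is invariant under per-region affine rescaling", {
  set.seed(4)
  d <- matrix(rnorm(4 * 100), 4, 100)
  s1 <- roi_series("s", d, letters[1:4], 1)
  s2 <- roi_series("s", d * c(2, 0.5, 3, 10) + c(1, -2, 0, 5),
                   letters[1:4], 1)
  expect_equal(fc_matrix(s1)$values, fc_matrix(s2)$values, tolerance = 1e-12)
})

test_that("icc21 reproduces the two-way random absolute-agreement ICC", {
  # frozen from an independent implementation of ICC(A,1) on this fixture
  truth <- c(0.838105, 0.406813, 0.506564, 0.581503, 0.342215, 0.500413,
             0.499822, 0.149055)
  pred <- c(0.888988, 0.436838, 0.475293, 0.572926, 0.36748, 0.487345,
            0.487685, 0.076393)
  expect_equal(boldcast:::icc21(cbind(pred, truth)), 0.9849312042054369,
               tolerance = 1e-9)
})

test_that("identical sessions give ICC 1 on every varying edge", {
  set.seed(9)
  fcs <- lapply(1:6, function(i) {
    fc_matrix(roi_series(paste0("s", i), matrix(rnorm(4 * 80), 4, 80),
                         letters[1:4], 1))
  })
  edges <- icc_edges(fcs, fcs)
  expect_equal(edges$icc, rep(1, 6), tolerance = 1e-9)
  expect_true(all(edges$grade == "excellent"))
})

test_that("icc_edges is symmetric in the two session lists", {
  set.seed(10)
  mk <- function(i) fc_matrix(roi_series(paste0("s", i),
                                         matrix(rnorm(3 * 60), 3, 60),
                                         letters[1:3], 1))
  a <- lapply(1:5, mk)
  b <- lapply(6:10, mk)
  expect_equal(icc_edges(a, b)$icc, icc_edges(b, a)$icc, tolerance = 1e-12)
})

test_that("degenerate edges are reported missing with a warning", {
  mk_const <- function(i) {
    v <- matrix(c(1, 0.5, 0.5, 1), 2)
    dimnames(v) <- list(c("a", "b"), c("a", "b"))
    structure(list(values = v, region_labels = c("a", "b")),
              class = "fc_matrix")
  }
  fcs <- lapply(1:4, mk_const)
  expect_warning(edges <- icc_edges(fcs, fcs), "zero variance")
  expect_true(is.na(edges$icc))
  expect_error(icc_edges(fcs[1:2], fcs[1:2]), ">= 3 subjects")
})

test_that("grading follows the published thresholds and boundary rules", {
  expect_identical(grade_icc(c(0.39, 0.70, 0.80)),
                   c("poor", "good", "excellent"))
  expect_identical(grade_icc(c(0.40, 0.60, 0.75)), c("fair", "good", "good"))
  expect_identical(grade_icc(-0.2), "poor")
  # monotone step function
  x <- seq(-1, 1, by = 0.01)
  g <- factor(grade_icc(x), levels = c("poor", "fair", "good", "excellent"),
              ordered = TRUE)
  expect_true(all(diff(as.integer(g)) >= 0))
})

test_that("per-region Pearson agreement behaves like correlation", {
  set.seed(5)
  d <- matrix(rnorm(3 * 100), 3, 100)
  truth <- roi_series("s", d, letters[1:3], 1)
  expect_equal(subject_pearson(truth, truth), c(a = 1, b = 1, c = 1))
  neg <- roi_series("s", -d, letters[1:3], 1)
  expect_equal(subject_pearson(neg, truth), c(a = -1, b = -1, c = -1))
  # attenuation: r ~ 1/sqrt(1 + sigma^2/var) for additive noise
  noisy <- roi_series("s", d + matrix(rnorm(300, 0, 0.1), 3), letters[1:3], 1)
  expect_true(all(subject_pearson(noisy, truth) > 0.98))
  expect_error(subject_pearson(truth,
    roi_series("s", d, c("x", "y", "z"), 1)), "labels differ")
})

test_that("the assembled reliability report summarizes all pieces", {
  set.seed(6)
  truth <- lapply(1:5, function(i)
    roi_series(paste0("s", i), matrix(rnorm(3 * 60), 3, 60), letters[1:3], 1))
  pred <- lapply(truth, function(s)
    roi_series(s$subject_id, s$data + matrix(rnorm(180, 0, 0.2), 3),
               s$region_labels, 1))
  rep <- reliability_report(pred, truth)
  expect_equal(nrow(rep$edges), 3L)
  expect_equal(dim(rep$per_subject_pearson), c(5L, 3L))
  expect_true(all(rep$per_subject_pearson > 0.9))
  expect_equal(sum(rep$grade_counts), 3L, ignore_attr = TRUE)
})
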