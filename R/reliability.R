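#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation between all region time series of one
#' subject: symmetric, unit diagonal, entries in `[-1, 1]`. Because Pearson
#' correlation is invariant to per-region affine rescaling, FC computed on
#' normalized series equals FC on the raw series.
#'
#' @param series a [roi_series()] with T >= 3 and no constant rows.
#' @return An `fc_matrix`: `values` (m x m), `region_labels`.
#' @export
fc_matrix <- function(series) {
  validate_roi_series(series)
  if (ncol(series$data) < 3L) stop("need T >= 3 for correlations")
  sds <- apply(series$data, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant series for region '",
         series$region_labels[which(sds == 0)[1L]],
         "': correlation undefined")
  v <- stats::cor(t(series$data))
  diag(v) <- 1
  dimnames(v) <- list(series$region_labels, series$region_labels)
  structure(list(values = v, region_labels = series$region_labels),
            class = "fc_matrix")
}

# ICC(2,1): two-way random effects, absolute agreement, single measures,
# from the ANOVA mean squares of an n x k ratings matrix.
icc21 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  mu <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - mu)^2)
  ssc <- n * sum((col_m - mu)^2)
  sst <- sum((ratings - mu)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-12) return(NA_real_)
  (msr - mse) / denom
}

#' Per-edge ICC between predicted and true FC
#'
#' Treats the predicted and ground-truth sessions as two raters of each
#' functional-connectivity edge: for every upper-triangle edge, the
#' intraclass correlation ICC(2,1) — two-way random effects, absolute
#' agreement, single measures — is computed across subjects. Edges with
#' (near-)zero variance across subjects and sessions have no defined ICC
#' and are reported as `NA` with a warning. Values are clipped to
#' `[-1, 1]` for reporting.
#'
#' @param fc_predicted,fc_true lists of [fc_matrix()] objects, one per
#'   subject, in matching order (>= 3 subjects).
#' @return Data frame with one row per edge: `region_a`, `region_b`,
#'   `icc`, `grade`.
#' @export
icc_edges <- function(fc_predicted, fc_true) {
  if (length(fc_predicted) != length(fc_true))
    stop("session lists have different numbers of subjects")
  n <- length(fc_predicted)
  if (n < 3L) stop("need >= 3 subjects for ICC, got ", n)
  labels <- fc_predicted[[1L]]$region_labels
  for (f in c(fc_predicted, fc_true))
    if (!identical(f$region_labels, labels))
      stop("region labels differ across FC matrices")
  m <- length(labels)
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  icc <- numeric(nrow(ut))
  for (e in seq_len(nrow(ut))) {
    i <- ut[e, 1L]; j <- ut[e, 2L]
    ratings <- cbind(
      vapply(fc_predicted, function(f) f$values[i, j], numeric(1)),
      vapply(fc_true, function(f) f$values[i, j], numeric(1)))
    if (stats::var(as.vector(ratings)) < 1e-24) {
      icc[e] <- NA_real_
    } else {
      icc[e] <- icc21(ratings)
    }
  }
  n_na <- sum(is.na(icc))
  if (n_na)
    warning(n_na, " edge(s) had zero variance; ICC reported as NA")
  icc <- pmin(pmax(icc, -1), 1)
  data.frame(region_a = labels[ut[, 1L]], region_b = labels[ut[, 2L]],
             icc = icc, grade = grade_icc(icc), stringsAsFactors = FALSE)
}

#' Grade an ICC value
#'
#' Cicchetti's qualitative bands: poor (< 0.40), fair (0.40-0.60),
#' good (0.60-0.75), excellent (> 0.75). Values exactly at 0.40 or 0.60 take
#' the higher grade; exactly 0.75 is "good".
#'
#' @param icc numeric vector (NAs pass through).
#' @return Character vector of grades.
#' @examples
#' grade_icc(c(0.39, 0.70, 0.80))
#' @export
grade_icc <- function(icc) {
  out <- rep(NA_character_, length(icc))
  ok <- !is.na(icc)
  out[ok & icc < 0.40] <- "poor"
  out[ok & icc >= 0.40 & icc < 0.60] <- "fair"
  out[ok & icc >= 0.60 & icc <= 0.75] <- "good"
  out[ok & icc > 0.75] <- "excellent"
  out
}

#' Per-region Pearson correlation between prediction and truth
#'
#' Individual-level agreement: for each region, the Pearson correlation
#' between the predicted segment and the matching true segment.
#'
#' @param predicted,truth [roi_series()] objects with identical shape and
#'   region labels.
#' @return Named numeric vector, one correlation per region.
#' @export
subject_pearson <- function(predicted, truth) {
  validate_roi_series(predicted)
  validate_roi_series(truth)
  if (!identical(predicted$region_labels, truth$region_labels))
    stop("region labels differ between predicted and truth")
  if (!all(dim(predicted$data) == dim(truth$data)))
    stop("shape mismatch between predicted and truth")
  out <- numeric(nrow(truth$data))
  for (r in seq_len(nrow(truth$data))) {
    if (stats::sd(predicted$data[r, ]) == 0 || stats::sd(truth$data[r, ]) == 0)
      stop("constant segment for region '", truth$region_labels[r],
           "': correlation undefined")
    out[r] <- stats::cor(predicted$data[r, ], truth$data[r, ])
  }
  names(out) <- truth$region_labels
  out
}

#' Test-retest reliability report
#'
#' Convenience wrapper assembling the full reliability stage: FC matrices
#' per subject for both sessions, per-edge ICC with grades, the grade
#' histogram, and per-subject per-region Pearson correlations.
#'
#' @param predicted,truth lists of [roi_series()] (same subjects, same
#'   order): the predicted and ground-truth sessions.
#' @return A `reliability_report`: `edges` (data frame from [icc_edges()]),
#'   `grade_counts`, `per_subject_pearson` (subjects x regions matrix),
#'   `n_undefined_edges`.
#' @export
reliability_report <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("session lists differ in length")
  fc_p <- lapply(predicted, fc_matrix)
  fc_t <- lapply(truth, fc_matrix)
  edges <- withCallingHandlers(
    icc_edges(fc_p, fc_t),
    warning = function(w) invokeRestart("muffleWarning"))
  pearson <- t(vapply(seq_along(predicted),
                      function(i) subject_pearson(predicted[[i]], truth[[i]]),
                      numeric(length(predicted[[1L]]$region_labels))))
  rownames(pearson) <- vapply(predicted, `[[`, character(1), "subject_id")
  grades <- factor(edges$grade, levels = c("poor", "fair", "good", "excellent"))
  structure(list(edges = edges,
                 grade_counts = table(grades),
                 per_subject_pearson = pearson,
                 n_undefined_edges = sum(is.na(edges$icc))),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d edges (mean ICC %.3f, %d undefined)\n",
              nrow(x$edges), mean(x$edges$icc, na.rm = TRUE),
              x$n_undefined_edges))
  print(x$grade_counts)
  invisible(x)
}
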