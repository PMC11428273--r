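#' Synthetic cohort configuration
#'
#' Generates multivariate series with the statistical structure resting-state
#' BOLD forecasting assumes: per-region band-limited low-frequency
#' oscillations (defaults emulate the two lowest empirical IMF bands,
#' 0.008-0.016 Hz and 0.03-0.05 Hz, so the < 0.05 Hz selection rule keeps
#' both), cross-region coupling (a target region partially driven by
#' auxiliary regions), and additive AR(1) noise emulating BOLD temporal
#' autocorrelation. Frequencies and phases are jittered per subject, which
#' creates the between-subject variance a meaningful ICC needs.
#'
#' @param n_subjects number of subjects.
#' @param m number of regions.
#' @param T number of timepoints (>= 2).
#' @param tr_seconds sampling interval in seconds.
#' @param band_freqs_hz list of `(low, high)` frequency bands in Hz, one per
#'   oscillatory component; all below Nyquist `1/(2 * tr_seconds)`.
#' @param amplitudes per-component amplitudes.
#' @param coupling m x m mixing matrix applied to the per-region component
#'   signals (`NULL` = identity, i.e. uncoupled regions); see
#'   [coupling_matrix()].
#' @param noise_sigma marginal standard deviation of the additive noise.
#' @param ar_coeff AR(1) coefficient of the noise in `[0, 1)`; 0.3 by
#'   default.
#' @param seed integer master seed; every subject is a pure function of
#'   `(config, seed, subject_index)`.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 10L, m = 6L, T = 600L,
                             tr_seconds = 0.72,
                             band_freqs_hz = list(c(0.008, 0.016),
                                                  c(0.03, 0.05)),
                             amplitudes = c(1, 0.7),
                             coupling = NULL,
                             noise_sigma = 0.2, ar_coeff = 0.3,
                             seed = 1L) {
  if (n_subjects < 1L || m < 1L || T < 2L) stop("invalid cohort dimensions")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (length(amplitudes) != length(band_freqs_hz))
    stop("need one amplitude per frequency band")
  nyq <- 1 / (2 * tr_seconds)
  for (b in band_freqs_hz) {
    if (length(b) != 2L || b[1L] <= 0 || b[2L] <= b[1L])
      stop("each band must be (low, high) with 0 < low < high")
    if (b[2L] >= nyq)
      stop("band upper edge ", b[2L], " Hz is at or above Nyquist ", nyq, " Hz")
  }
  if (is.null(coupling)) coupling <- diag(m)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(m, m))) stop("coupling must be m x m")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects), m = as.integer(m),
                 T = as.integer(T), tr_seconds = tr_seconds,
                 band_freqs_hz = band_freqs_hz, amplitudes = amplitudes,
                 coupling = coupling, noise_sigma = noise_sigma,
                 ar_coeff = ar_coeff, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Uniform cross-region coupling matrix
#'
#' `(1 - strength) * I + strength / (m - 1) * (J - I)`: each region keeps
#' `1 - strength` of its own signal and receives the rest as the average of
#' all other regions, so every region is partially predictable from the
#' auxiliary regions.
#'
#' @param m number of regions (>= 2).
#' @param strength mixing strength in `[0, 1)`.
#' @return m x m numeric matrix.
#' @export
coupling_matrix <- function(m, strength = 0.5) {
  if (m < 2L) stop("coupling needs m >= 2")
  if (strength < 0 || strength >= 1) stop("strength must be in [0, 1)")
  (1 - strength) * diag(m) + strength / (m - 1) * (matrix(1, m, m) - diag(m))
}

# deterministic per-subject draw of everything random
synth_draw <- function(config, subject_index) {
  set.seed(config$seed + 104729L * as.integer(subject_index))
  m <- config$m
  T <- config$T
  tt <- (seq_len(T) - 1L) * config$tr_seconds
  n_comp <- length(config$band_freqs_hz)
  components <- vector("list", n_comp)
  for (c in seq_len(n_comp)) {
    band <- config$band_freqs_hz[[c]]
    raw <- matrix(0, m, T)
    for (r in seq_len(m)) {
      f <- stats::runif(1, band[1L], band[2L])
      phi <- stats::runif(1, 0, 2 * pi)
      raw[r, ] <- config$amplitudes[c] * sin(2 * pi * f * tt + phi)
    }
    components[[c]] <- config$coupling %*% raw
  }
  noise <- matrix(0, m, T)
  if (config$noise_sigma > 0) {
    innov_sd <- config$noise_sigma * sqrt(1 - config$ar_coeff^2)
    for (r in seq_len(m)) {
      e <- stats::rnorm(T, 0, innov_sd)
      z <- numeric(T)
      z[1L] <- stats::rnorm(1, 0, config$noise_sigma)
      for (i in 2:T) z[i] <- config$ar_coeff * z[i - 1L] + e[i]
      noise[r, ] <- z
    }
  }
  list(components = components, noise = noise)
}

#' Generate one synthetic subject
#'
#' Each region is the coupled sum of the configured band-limited sinusoidal
#' components plus AR(1) noise; deterministic given `(config, subject_index)`.
#'
#' @param config a [synthetic_config()].
#' @param subject_index positive integer.
#' @return A [roi_series()] with labels `ROI01..ROIm` and id `sub-<index>`.
#' @export
generate_subject <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  d <- synth_draw(config, subject_index)
  data <- Reduce(`+`, d$components) + d$noise
  roi_series(sprintf("sub-%03d", as.integer(subject_index)), data,
             sprintf("ROI%02d", seq_len(config$m)), config$tr_seconds)
}

#' Generate a synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @return A [roi_cohort()] of `n_subjects` independent subjects sharing
#'   region labels and TR.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  roi_cohort(lapply(seq_len(config$n_subjects),
                    function(i) generate_subject(config, i)))
}

#' Ground-truth components of a synthetic subject
#'
#' The noiseless band-limited components (after coupling) and the noise used
#' to generate a subject, for oracle tests: their sum reproduces the
#' generated series exactly.
#'
#' @param config a [synthetic_config()].
#' @param subject_index positive integer.
#' @return List with `components` (list of m x T matrices, one per band) and
#'   `noise` (m x T matrix).
#' @export
ground_truth_components <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  synth_draw(config, subject_index)
}
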