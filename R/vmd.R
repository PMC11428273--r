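#' Variational mode decomposition configuration
#'
#' VMD decomposes a 1-D signal into `K` band-limited modes ("intrinsic mode
#' functions", IMFs), each concentrated around a center frequency, by
#' minimising the summed bandwidth of the analytic mode signals subject to
#' the modes reconstructing the input. The augmented-Lagrangian saddle point
#' is found by ADMM: a Wiener-filter-like mode update in the frequency
#' domain alternates with a center-of-mass update of each center frequency,
#' plus optional dual ascent of the reconstruction multiplier.
#'
#' @param K number of modes to extract (>= 1).
#' @param alpha quadratic bandwidth penalty; larger values give narrower
#'   modes. Default 2000, a common choice for slowly oscillating signals.
#' @param tau dual-ascent step for the reconstruction multiplier. `tau = 0`
#'   relaxes the exact-reconstruction constraint (robust to noise);
#'   `tau > 0` enforces reconstruction progressively.
#' @param tol relative convergence tolerance on the summed mode change.
#' @param max_iter iteration cap.
#' @param init_mode center-frequency initialisation: `"uniform"` spacing
#'   over the positive band, `"zero"`, or seeded `"random"`.
#' @param seed integer seed used by `init_mode = "random"`.
#' @return A `vmd_config` list.
#' @export
vmd_config <- function(K = 4L, alpha = 2000, tau = 0, tol = 1e-7,
                       max_iter = 500L, init_mode = c("uniform", "zero", "random"),
                       seed = 1L) {
  init_mode <- match.arg(init_mode)
  if (K < 1L) stop("K must be >= 1")
  if (alpha <= 0) stop("alpha must be positive")
  if (tau < 0) stop("tau must be non-negative")
  if (tol <= 0) stop("tol must be positive")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(K = as.integer(K), alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter), init_mode = init_mode,
                 seed = as.integer(seed)),
            class = "vmd_config")
}

#' Decompose a series into band-limited modes
#'
#' Runs the ADMM iteration for variational mode decomposition on a single
#' series. The series is mirror-extended by half its length at each end
#' before decomposition and trimmed afterwards, which suppresses edge
#' ringing. Modes are returned in the time domain, sorted by ascending
#' center frequency (mode 1 = lowest band).
#'
#' @param x numeric vector, length >= 8, all finite.
#' @param config a [vmd_config()].
#' @return A `vmd_result` with elements `modes` (K x T matrix),
#'   `center_freqs` (cycles/sample, non-decreasing, in `[0, 0.5]`),
#'   `n_iter`, and `converged`.
#' @examples
#' t <- 0:511
#' res <- vmd_decompose(sin(2 * pi * 0.05 * t), vmd_config(K = 1))
#' res$center_freqs
#' @export
vmd_decompose <- function(x, config = vmd_config()) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("input contains non-finite values")
  T <- length(x)
  if (T < 8L) stop("series too short for decomposition: need T >= 8, got ", T)
  K <- config$K

  # mirror extension by floor(T/2) on each side
  hl <- T %/% 2L
  f <- c(rev(x[seq_len(hl)]), x, rev(x[(T - hl + 1L):T]))
  Tm <- length(f)

  fr <- (seq_len(Tm) - 1L) / Tm            # FFT bin frequencies in [0, 1)
  pos <- fr <= 0.5 + .Machine$double.eps   # analytic (kept) half
  fhat <- stats::fft(f)
  fhat_plus <- fhat
  fhat_plus[!pos] <- 0

  omega <- switch(config$init_mode,
    uniform = (0.5 / K) * (seq_len(K) - 0.5),
    zero = rep(0, K),
    random = {
      set.seed(config$seed)
      sort(stats::runif(K, 0, 0.5))
    })

  u <- matrix(complex(real = 0), K, Tm)
  lam <- complex(real = rep(0, Tm))
  eps <- .Machine$double.eps
  converged <- FALSE
  n_iter <- config$max_iter

  s_all <- colSums(u)
  for (it in seq_len(config$max_iter)) {
    u_prev <- u
    for (k in seq_len(K)) {
      s_others <- s_all - u[k, ]
      u_new <- (fhat_plus - s_others + lam / 2) /
        (1 + 2 * config$alpha * (fr - omega[k])^2)
      s_all <- s_others + u_new
      u[k, ] <- u_new
      pw <- Mod(u_new[pos])^2
      e <- sum(pw)
      if (e > eps) omega[k] <- sum(fr[pos] * pw) / e
    }
    if (config$tau > 0) lam <- lam + config$tau * (fhat_plus - s_all)
    udiff <- 0
    for (k in seq_len(K)) {
      num <- sum(Mod(u[k, ] - u_prev[k, ])^2)
      den <- sum(Mod(u_prev[k, ])^2)
      udiff <- udiff + num / (den + eps)
    }
    if (udiff < config$tol) {
      converged <- TRUE
      n_iter <- it
      break
    }
  }

  # back to time domain via Hermitian completion, then trim the mirrors
  modes <- matrix(0, K, T)
  neg <- which(fr > 0.5 + .Machine$double.eps)
  for (k in seq_len(K)) {
    U <- u[k, ]
    U[1L] <- complex(real = Re(U[1L]))
    if (Tm %% 2L == 0L) {
      ny <- Tm %/% 2L + 1L
      U[ny] <- complex(real = Re(U[ny]))
    }
    U[neg] <- Conj(U[Tm - neg + 2L])
    full <- Re(stats::fft(U, inverse = TRUE)) / Tm
    modes[k, ] <- full[(hl + 1L):(hl + T)]
  }

  ord <- order(omega)
  structure(list(modes = modes[ord, , drop = FALSE],
                 center_freqs = pmin(pmax(omega[ord], 0), 0.5),
                 n_iter = n_iter, converged = converged),
            class = "vmd_result")
}

#' @export
print.vmd_result <- function(x, ...) {
  cat(sprintf("<vmd_result> %d modes x %d samples; center freqs (cyc/sample): %s; %s in %d iter\n",
              nrow(x$modes), ncol(x$modes),
              paste(signif(x$center_freqs, 3), collapse = ", "),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Reconstruct a signal from its modes
#'
#' Element-wise sum of all modes. With `tau > 0` in the decomposition the
#' sum approaches the original signal; with `tau = 0` the reconstruction
#' constraint is relaxed and broadband noise is discarded.
#'
#' @param result a `vmd_result`.
#' @return Numeric vector of length T.
#' @export
vmd_reconstruct <- function(result) {
  stopifnot(inherits(result, "vmd_result"))
  colSums(result$modes)
}

#' Convert mode center frequencies to Hz
#'
#' @param result a `vmd_result`.
#' @param tr_seconds sampling interval in seconds.
#' @return Numeric vector of center frequencies in Hz.
#' @export
center_freqs_hz <- function(result, tr_seconds) {
  stopifnot(inherits(result, "vmd_result"), tr_seconds > 0)
  result$center_freqs / tr_seconds
}

#' Select low-frequency modes
#'
#' Returns the indices of modes whose center frequency in Hz lies strictly
#' below `f_max_hz`, in ascending frequency order. Resting-state functional
#' connectivity is most stable below about 0.05 Hz, so that is the default
#' cutoff used throughout the pipeline.
#'
#' @param result a `vmd_result`.
#' @param tr_seconds sampling interval in seconds.
#' @param f_max_hz frequency cutoff in Hz (> 0).
#' @return Integer vector of mode indices (possibly empty).
#' @export
select_low_modes <- function(result, tr_seconds, f_max_hz = 0.05) {
  if (f_max_hz <= 0) stop("f_max_hz must be positive")
  hz <- center_freqs_hz(result, tr_seconds)
  which(hz < f_max_hz)
}

#' Decompose every region of every subject in a cohort
#'
#' Applies [vmd_decompose()] independently to each region series of each
#' subject and records which modes fall below the low-frequency cutoff.
#'
#' @param cohort a [roi_cohort()].
#' @param config a [vmd_config()].
#' @param f_max_hz low-frequency cutoff in Hz.
#' @return A `cohort_decomposition`: per subject, per region, the
#'   `vmd_result` and the selected low-mode indices.
#' @export
decompose_cohort <- function(cohort, config = vmd_config(), f_max_hz = 0.05) {
  stopifnot(inherits(cohort, "roi_cohort"))
  tr <- cohort$subjects[[1L]]$tr_seconds
  out <- lapply(cohort$subjects, function(s) {
    per_region <- lapply(seq_len(nrow(s$data)), function(r) {
      res <- tryCatch(vmd_decompose(s$data[r, ], config),
                      error = function(e) {
                        stop("decomposition failed for subject '", s$subject_id,
                             "', region '", s$region_labels[r], "': ",
                             conditionMessage(e))
                      })
      list(result = res, selected = select_low_modes(res, tr, f_max_hz))
    })
    names(per_region) <- s$region_labels
    per_region
  })
  names(out) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  structure(list(decompositions = out, tr_seconds = tr,
                 f_max_hz = f_max_hz, config = config),
            class = "cohort_decomposition")
}

#' Extract one selected-IMF block from a cohort decomposition
#'
#' For a given subject and selected-mode rank (1 = lowest retained band),
#' returns the m x T matrix of that mode across all regions — the
#' multivariate series a frequency-specific forecasting task trains on.
#'
#' @param dec a `cohort_decomposition`.
#' @param subject_id subject identifier.
#' @param imf_rank which selected mode (1-based rank among selected).
#' @return m x T numeric matrix with region labels as rownames.
#' @export
imf_block <- function(dec, subject_id, imf_rank = 1L) {
  stopifnot(inherits(dec, "cohort_decomposition"))
  sub <- dec$decompositions[[subject_id]]
  if (is.null(sub)) stop("unknown subject: ", subject_id)
  rows <- lapply(sub, function(rr) {
    if (length(rr$selected) < imf_rank)
      stop("region has only ", length(rr$selected),
           " selected modes, requested rank ", imf_rank)
    rr$result$modes[rr$selected[imf_rank], ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(sub)
  out
}
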