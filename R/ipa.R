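#' Parameters of the Index of Pupillary Activity
#'
#' The IPA counts transient pupil-dilation events per second: detail
#' coefficients of a two-level Symlet-16 wavelet decomposition are reduced to
#' their modulus maxima, a universal threshold \eqn{\lambda =
#' f \cdot \hat\sigma \sqrt{2 \log n}} is applied, and surviving maxima are
#' counted.  `threshold_factor` is the multiplicative adaptation of the
#' universal threshold (default 0.8, the calibration that best tracks the
#' commercial ICA indicator).
#'
#' @param wavelet wavelet name; only `"sym16"` is implemented.
#' @param levels decomposition depth (default 2; the detail band analysed is
#'   the coarsest one).
#' @param boundary boundary extension; only `"periodic"` is implemented.
#' @param threshold_factor positive multiplier on the universal threshold.
#' @param log_base `"natural"` (Donoho's formula) or `"base2"` (strict
#'   reference-code compatibility) for the `log n` term.
#' @param sigma_estimator `"sd_of_maxima"`: population standard deviation of
#'   the sparse modulus-maxima sequence (reference behaviour);
#'   `"mad_of_detail"`: median absolute deviation of the detail coefficients
#'   divided by 0.6745 (textbook noise scale).
#' @param normalize divide level-`j` detail coefficients by `sqrt(2^j)`
#'   (reference arithmetic); set `FALSE` for raw filter-bank output.
#' @return a validated list of class `ipa_params`.
#' @export
ipa_params <- function(wavelet = "sym16",
                       levels = 2L,
                       boundary = "periodic",
                       threshold_factor = 0.8,
                       log_base = c("natural", "base2"),
                       sigma_estimator = c("sd_of_maxima", "mad_of_detail"),
                       normalize = TRUE) {
  log_base <- match.arg(log_base)
  sigma_estimator <- match.arg(sigma_estimator)
  if (!identical(wavelet, "sym16")) {
    abort("only the sym16 wavelet is implemented", class = "pupilload_param")
  }
  if (!identical(boundary, "periodic")) {
    abort("only periodic boundary handling is implemented",
          class = "pupilload_param")
  }
  levels <- as.integer(levels)
  if (levels < 1L) abort("levels must be >= 1", class = "pupilload_param")
  if (!is.numeric(threshold_factor) || threshold_factor <= 0) {
    abort("threshold_factor must be > 0", class = "pupilload_param")
  }
  structure(list(wavelet = wavelet, levels = levels, boundary = boundary,
                 threshold_factor = threshold_factor, log_base = log_base,
                 sigma_estimator = sigma_estimator,
                 normalize = isTRUE(normalize)),
            class = "ipa_params")
}

#' Modulus maxima of a coefficient sequence
#'
#' Keeps `c[i]` iff `|c[i]|` is a local maximum of the absolute sequence:
#' strictly greater than the left neighbour and at least the right neighbour
#' (first index of a two-sample plateau wins; boundaries are compared
#' one-sided).  Zero values are never maxima.  All other positions are set
#' to 0, so the output has the same length as the input.
#'
#' @param coeffs numeric vector, length >= 3.
#' @return numeric vector of the same length, nonzero only at maxima.
#' @export
modulus_maxima <- function(coeffs) {
  n <- length(coeffs)
  if (n < 3L) {
    abort("modulus_maxima needs at least 3 coefficients",
          class = "pupilload_too_short")
  }
  m <- abs(coeffs)
  left_ok <- c(TRUE, m[-1L] > m[-n])          # strict against left neighbour
  right_ok <- c(m[-n] >= m[-1L], TRUE)        # non-strict against right
  keep <- left_ok & right_ok & m > 0
  out <- numeric(n)
  out[keep] <- coeffs[keep]
  out
}

#' Universal threshold for modulus-maxima denoising
#'
#' \eqn{\lambda = f \cdot \hat\sigma \sqrt{2 \log n}} where `n` is the number
#' of coefficient positions, `f` the threshold factor, and \eqn{\hat\sigma}
#' the noise-scale estimate chosen in `params` (default: population standard
#' deviation of the sparse maxima sequence).
#'
#' @param maxima output of [modulus_maxima()] (sparse sequence, zeros at
#'   non-maxima positions).
#' @param params an [ipa_params()] list.
#' @param detail optional raw detail coefficients, required for the
#'   `mad_of_detail` estimator.
#' @return threshold `lambda >= 0`.
#' @export
universal_threshold <- function(maxima, params = ipa_params(), detail = NULL) {
  n <- length(maxima)
  if (n < 2L) {
    abort("universal threshold undefined for fewer than 2 positions",
          class = "pupilload_too_short")
  }
  sigma <- switch(params$sigma_estimator,
    sd_of_maxima = {
      mu <- mean(maxima)
      sqrt(mean((maxima - mu)^2))             # population sd, ddof = 0
    },
    mad_of_detail = {
      if (is.null(detail)) {
        abort("mad_of_detail estimator needs the detail coefficients",
              class = "pupilload_param")
      }
      median(abs(detail - median(detail))) / 0.6745
    })
  logn <- if (params$log_base == "natural") log(n) else log2(n)
  params$threshold_factor * sigma * sqrt(2 * logn)
}

#' Index of Pupillary Activity of one prepared pupil series
#'
#' Full chain: mean-centering -> wavelet detail -> modulus maxima ->
#' universal threshold -> hard thresholding -> event count per second.  The
#' series is centered first because the IPA measures diameter *changes*: the
#' DC level carries no information, and centering makes the result exactly
#' invariant to constant offsets (a constant series maps to the exact zero
#' vector).  The rate is normalized by the nominal span of the series
#' (`n / sampling rate`).
#'
#' @param series a `pupil_series` (see [extract_segment_series()]) or a plain
#'   numeric vector together with `fs`.
#' @param params an [ipa_params()] list.
#' @param fs sampling rate in Hz, required when `series` is a bare vector.
#' @return list of class `ipa_result`: `event_count`, `duration` (s), `ipa`
#'   (events/s), `degraded` (logical).
#' @export
compute_ipa <- function(series, params = ipa_params(), fs = NULL) {
  if (inherits(series, "pupil_series")) {
    d <- series$d
    fs <- series$fs
    degraded <- isTRUE(series$degraded)
  } else {
    d <- as.numeric(series)
    if (is.null(fs)) abort("fs is required for a bare numeric series",
                           class = "pupilload_param")
    degraded <- FALSE
  }
  detail <- wavelet_detail(d - mean(d), params)
  maxima <- modulus_maxima(detail)
  lambda <- universal_threshold(maxima, params, detail = detail)
  surviving <- maxima[abs(maxima) >= lambda & maxima != 0]
  duration <- length(d) / fs
  count <- length(surviving)
  structure(list(event_count = count,
                 duration = duration,
                 ipa = count / duration,
                 degraded = degraded),
            class = "ipa_result")
}

#' @export
print.ipa_result <- function(x, ...) {
  cat(sprintf("IPA: %.4f events/s (%d events over %.2f s)%s\n",
              x$ipa, x$event_count, x$duration,
              if (x$degraded) " [degraded]" else ""))
  invisible(x)
}
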