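#' Symlet-16 decomposition filter bank
#'
#' Published Daubechies least-asymmetric ("Symlet") filter with 16 vanishing
#' moments: 32 low-pass decomposition coefficients.  The high-pass filter is
#' derived by the quadrature-mirror relation `hi[k] = (-1)^(k+1) *
#' lo[L - 1 - k]` (1-based k).
#'
#' @return list with numeric vectors `lo` and `hi`, each of length 32.
#' @keywords internal
sym16_filters <- function() {
  lo <- c(
    6.230006701220761e-06, -3.113556407621969e-06,
    -0.00010943147929529757, 2.8078582128442894e-05,
    0.0008523547108047095, -0.0001084456223089688,
    -0.0038809122526038786, 0.0007182119788317892,
    0.012666731659857348, -0.0031265171722710075,
    -0.031051202843553064, 0.004869274404904607,
    0.032333091610663785, -0.06698304907021778,
    -0.034574228416972504, 0.39712293362064416,
    0.7565249878756971, 0.47534280601152273,
    -0.054040601387606135, -0.15959219218520598,
    0.03072113906330156, 0.07803785290341991,
    -0.003510275068374009, -0.024952758046290123,
    0.001359844742484172, 0.0069377611308027096,
    -0.00022211647621176323, -0.0013387206066921965,
    3.656592483348223e-05, 0.00016545679579108483,
    -5.396483179315242e-06, -1.0797982104319795e-05
  )
  L <- length(lo)
  hi <- (-1)^(seq_len(L)) * rev(lo)
  list(lo = lo, hi = hi)
}

#' One level of the periodized discrete wavelet transform
#'
#' Circular-convolution DWT: the signal is treated as one period of a
#' periodic sequence, so each output band has exactly `floor(n/2)`
#' coefficients.  Odd-length inputs are truncated by their final sample
#' before decimation (documented convention of this package).
#'
#' Indexing convention (0-based): `a[k] = sum_j lo[j] * x[(2k - j) mod n]`,
#' which matches the standard periodization convention of common wavelet
#' toolboxes for even `n`.
#'
#' @param x numeric vector, length >= filter length.
#' @param filters list with `lo` and `hi` (see [sym16_filters()]).
#' @return list with numeric vectors `approx` and `detail`.
#' @keywords internal
dwt_periodized_step <- function(x, filters = sym16_filters()) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- x[-n]
    n <- n - 1L
  }
  L <- length(filters$lo)
  if (n < 2L) {
    abort("series too short for DWT step", class = "pupilload_too_short")
  }
  half <- n %/% 2L
  # periodic extension (prepend the last L-1 samples), then one matrix
  # multiply evaluates both decimated convolutions
  # y[k] = sum_j h[j] * x[(2k - j) mod n] without any modulo arithmetic
  xe <- c(tail(rep(x, ceiling((L - 1L) / n)), L - 1L), x)
  idx <- outer(2L * (seq_len(half) - 1L) + L, seq_len(L) - 1L, `-`)
  bands <- matrix(xe[idx], nrow = half, ncol = L) %*%
    cbind(filters$lo, filters$hi)
  list(approx = bands[, 1L], detail = bands[, 2L])
}

#' Detail coefficients of a pupil series at the coarsest requested level
#'
#' Runs `levels` cascaded periodized DWT steps and returns the detail band of
#' the final step, optionally divided by `sqrt(2^levels)` (per-level
#' orthonormal rescaling used by the reference IPA arithmetic; with the
#' default two levels this divides by 2).
#'
#' @param d numeric vector of pupil diameters (mm), no missing values.
#' @param params an [ipa_params()] list.
#' @return numeric vector of detail coefficients, length about
#'   `length(d) / 2^levels`.
#' @export
wavelet_detail <- function(d, params = ipa_params()) {
  stopifnot(is.numeric(d))
  if (anyNA(d) || any(!is.finite(d))) {
    abort("wavelet_detail: series contains missing or non-finite values",
          class = "pupilload_invalid_series")
  }
  filters <- sym16_filters()
  min_n <- ipa_min_length(params)
  if (length(d) < min_n) {
    abort(sprintf(
      "series too short for a %d-level decomposition: %d samples, minimum %d",
      params$levels, length(d), min_n), class = "pupilload_too_short")
  }
  x <- d
  detail <- NULL
  for (lev in seq_len(params$levels)) {
    step <- dwt_periodized_step(x, filters)
    detail <- step$detail
    x <- step$approx
  }
  if (isTRUE(params$normalize)) detail <- detail / sqrt(2^params$levels)
  detail
}

#' Minimum usable series length for the IPA decomposition
#'
#' Four filter lengths: below this, periodic boundary artifacts dominate the
#' detail band.
#'
#' @param params an [ipa_params()] list.
#' @return integer sample count.
#' @export
ipa_min_length <- function(params = ipa_params()) {
  4L * length(sym16_filters()$lo)
}
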