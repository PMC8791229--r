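#' ROI-level preprocessing configuration
#'
#' Settings for the fixed preprocessing chain applied to each subject's ROI
#' time series: discard initial volumes, detrend, nuisance regression
#' (optionally including the global signal, defined as the per-timepoint
#' mean over the ROI columns), then ideal band-pass filtering.
#'
#' @param n_discard Initial time points to drop (default 10).
#' @param detrend `"linear"` or `"none"`.
#' @param band_low_hz,band_high_hz Pass-band edges in Hz (defaults
#'   0.01-0.08); must satisfy `0 <= low < high < 1/(2 TR)` at use time.
#' @param gsr Include global-signal regression (logical).
#' @param extra_confounds Optional T x K numeric matrix of additional
#'   nuisance regressors (e.g. motion parameters), aligned to the series
#'   *after* volume discard.
#' @return Object of class `prep_config`.
#' @export
prep_config <- function(n_discard = 10, detrend = c("linear", "none"),
                        band_low_hz = 0.01, band_high_hz = 0.08,
                        gsr = TRUE, extra_confounds = NULL) {
  detrend <- match.arg(detrend)
  if (!is_count(n_discard)) stopf("n_discard must be a non-negative count")
  if (band_low_hz < 0 || band_low_hz >= band_high_hz)
    stopf("band edges must satisfy 0 <= low < high")
  if (!is.null(extra_confounds) && !is.matrix(extra_confounds))
    stopf("extra_confounds must be a matrix")
  structure(list(n_discard = n_discard, detrend = detrend,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 gsr = isTRUE(gsr), extra_confounds = extra_confounds),
            class = "prep_config")
}

#' Discard initial volumes and detrend
#'
#' Drops the first `n_discard` rows, then (for `detrend = "linear"`) removes
#' each column's least-squares intercept and linear slope. After linear
#' detrending every column has zero mean and zero fitted slope.
#'
#' @param series A [roi_time_series()].
#' @param config A [prep_config()].
#' @return The processed `roi_ts`.
#' @export
discard_and_detrend <- function(series, config = prep_config()) {
  x <- series$data
  nd <- config$n_discard
  if (nrow(x) <= nd + 2)
    stopf("series too short: %d time points with %d to discard", nrow(x), nd)
  x <- x[(nd + 1):nrow(x), , drop = FALSE]
  if (config$detrend == "linear") {
    tt <- seq_len(nrow(x))
    X <- cbind(1, tt)
    x <- qr.resid(qr(X), x)
  }
  series$data <- x
  series
}

#' Regress nuisance signals out of every column
#'
#' Replaces each ROI column by its least-squares residual on an intercept,
#' the supplied confound columns, and (optionally) the global signal (the
#' row mean over ROI columns, computed before regression). Residuals are
#' orthogonal to every regressor by construction.
#'
#' @param series A [roi_time_series()].
#' @param confounds Optional T x K numeric matrix.
#' @param include_global Add the global mean signal as a regressor.
#' @return The processed `roi_ts`.
#' @export
regress_confounds <- function(series, confounds = NULL, include_global = FALSE) {
  x <- series$data
  X <- matrix(1, nrow(x), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(confounds)) {
    if (!is.matrix(confounds) || nrow(confounds) != nrow(x))
      stopf("confounds must be a matrix with %d rows", nrow(x))
    cn <- colnames(confounds)
    if (is.null(cn)) cn <- sprintf("confound%d", seq_len(ncol(confounds)))
    colnames(confounds) <- cn
    X <- cbind(X, confounds)
  }
  if (include_global)
    X <- cbind(X, global = rowMeans(x))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stopf("confound design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  series$data <- qr.resid(qr_x, x)
  series
}

#' Ideal frequency-domain band-pass filter
#'
#' Zeroes every discrete-Fourier component whose frequency falls strictly
#' outside `[band_low_hz, band_high_hz]` (bins exactly at the band edges are
#' retained, as are their conjugate mirrors), then inverse-transforms. The
#' output is real and the same length as the input; applying the filter
#' twice equals applying it once.
#'
#' @param series A [roi_time_series()].
#' @param config A [prep_config()]; the band must lie below the Nyquist
#'   frequency `1 / (2 TR)`.
#' @return The filtered `roi_ts`.
#' @export
bandpass <- function(series, config = prep_config()) {
  x <- series$data
  tr <- series$tr_seconds
  nyquist <- 1 / (2 * tr)
  if (config$band_high_hz > nyquist + 1e-12)
    stopf("band_high_hz (%g Hz) exceeds the Nyquist frequency (%g Hz) at TR = %g s",
          config$band_high_hz, nyquist, tr)
  t_len <- nrow(x)
  freq <- (seq_len(t_len) - 1) / (t_len * tr)
  freq <- pmin(freq, 1 / tr - freq)  # fold to [0, Nyquist]
  keep <- freq >= config$band_low_hz - 1e-12 &
    freq <= config$band_high_hz + 1e-12
  fx <- mvfft(x)
  fx[!keep, ] <- 0
  series$data <- Re(mvfft(fx, inverse = TRUE)) / t_len
  series
}

#' Run the full preprocessing chain
#'
#' Fixed order: discard initial volumes, detrend, nuisance regression
#' (extra confounds from the config plus optional global signal), band-pass.
#'
#' @param series A [roi_time_series()].
#' @param config A [prep_config()].
#' @return The preprocessed `roi_ts`.
#' @export
preprocess <- function(series, config = prep_config()) {
  series <- discard_and_detrend(series, config)
  series <- regress_confounds(series, config$extra_confounds, config$gsr)
  bandpass(series, config)
}
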