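#' Canonical haemodynamic response function parameters
#'
#' The standard double-gamma parameterization: response gamma density with
#' peak delay 6 s, undershoot gamma density with delay 16 s, unit
#' dispersions, undershoot weighted 1/6.  These are the published defaults
#' of the canonical HRF used by common fMRI analysis software.
#'
#' @param peak_delay,undershoot_delay gamma means in seconds.
#' @param peak_dispersion,undershoot_dispersion gamma scales in seconds.
#' @param peak_undershoot_ratio ratio of peak to undershoot amplitude.
#' @param kernel_length kernel support in seconds.
#' @return an object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, peak_undershoot_ratio, kernel_length)
  if (any(vals <= 0)) stop("all HRF parameters must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length = kernel_length), class = "hrf_params")
}

#' Canonical haemodynamic response kernel
#'
#' Difference of two gamma densities sampled at resolution `dt`, rescaled
#' so the kernel maximum is exactly 1.
#'
#' @param dt sampling step in seconds, `0 < dt <= 1`.
#' @param params an [hrf_params()] object.
#' @return numeric kernel vector covering `[0, kernel_length)`.
#' @export
canonical_hrf <- function(dt = 0.1, params = hrf_params()) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 1)
    stop("dt must be a single value in (0, 1]")
  t <- seq(0, params$kernel_length - dt, by = dt)
  h <- dgamma(t, shape = params$peak_delay / params$peak_dispersion,
              scale = params$peak_dispersion) -
    dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
           scale = params$undershoot_dispersion) / params$peak_undershoot_ratio
  h / max(h)
}

#' Canonical skin conductance response function parameters
#'
#' A gamma-density kernel standing in for the canonical sudomotor response
#' shape: sharp rise, peak a few seconds after burst onset, slow decay.
#' Defaults (`shape = 3`, `scale = 1.75`) put the peak at
#' `(shape - 1) * scale = 3.5` s.  Downstream statistics depend only on
#' relative amplitudes, so the exact parametric family is configurable.
#'
#' @param shape,scale gamma shape/scale of the kernel.
#' @param kernel_length kernel support in seconds.
#' @param latency_window onset-latency search window after stimulus onset,
#'   in seconds (default `c(0, 3.5)`).
#' @return an object of class `scrf_params`.
#' @export
scrf_params <- function(shape = 3, scale = 1.75, kernel_length = 25,
                        latency_window = c(0, 3.5)) {
  if (shape <= 1 || scale <= 0 || kernel_length <= 0)
    stop("scrf parameters must be positive (shape > 1 for a peaked kernel)")
  if (length(latency_window) != 2 || latency_window[1] >= latency_window[2])
    stop("latency_window must be an increasing pair of seconds")
  structure(list(shape = shape, scale = scale, kernel_length = kernel_length,
                 latency_window = latency_window), class = "scrf_params")
}

#' Canonical skin conductance response kernel
#'
#' @param sample_rate sampling rate in Hz.
#' @param params an [scrf_params()] object.
#' @return numeric kernel vector with maximum 1.
#' @export
canonical_scrf <- function(sample_rate = 10, params = scrf_params()) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive value")
  t <- seq(0, params$kernel_length - 1 / sample_rate, by = 1 / sample_rate)
  k <- dgamma(t, shape = params$shape, scale = params$scale)
  k / max(k)
}
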