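# Internal: HRF-convolved event regressors on a microtime grid, sampled at
# scan acquisition times (mid-volume reference).  Onsets are rounded to the
# microtime grid; with the default dt = 0.1 s and integer-second designs the
# rounding is exact.

convolved_regressors <- function(onsets, durations, n_scans, tr,
                                 hrf_par = hrf_params(), dt = 0.1) {
  stopifnot(length(durations) %in% c(1L, length(onsets)))
  durations <- rep(durations, length.out = length(onsets))
  h <- canonical_hrf(dt, hrf_par)
  t_end <- n_scans * tr
  n_fine <- ceiling(t_end / dt) + length(h) + 1L
  scan_times <- (seq_len(n_scans) - 0.5) * tr   # mid-volume reference
  scan_idx <- floor(scan_times / dt + 1e-9) + 1L  # snap down onto the microtime grid
  out <- matrix(0, n_scans, length(onsets))
  for (i in seq_along(onsets)) {
    u <- numeric(n_fine)
    a <- round(onsets[i] / dt) + 1L
    b <- min(a + max(1L, round(durations[i] / dt)) - 1L, n_fine)
    if (a > n_fine) stop("event onset beyond the sampled run")
    u[a:b] <- 1
    x <- stats::convolve(u, rev(h), type = "open")[seq_len(n_fine)]
    out[, i] <- x[scan_idx] * dt   # dt-scaled: regressor approximates the continuous convolution
  }
  out
}

# Discrete cosine high-pass basis: K = floor(2 * T / cutoff) columns of the
# orthonormal DCT-II basis (frequencies below 1/cutoff Hz), excluding the
# constant term, which is carried by an explicit intercept column.
dct_highpass_basis <- function(n_scans, tr, cutoff = 128) {
  T_run <- n_scans * tr
  K <- floor(2 * T_run / cutoff)
  if (K < 1) return(matrix(0, n_scans, 0))
  s <- seq_len(n_scans) - 0.5
  X <- vapply(seq_len(K),
              function(k) sqrt(2 / n_scans) * cos(pi * k * s / n_scans),
              numeric(n_scans))
  X
}
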