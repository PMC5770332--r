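#' Simulate a skin conductance trace with per-trial sudomotor bursts
#'
#' The trace is a sum over trials of a canonical skin conductance response
#' kernel scaled by that trial's true burst amplitude, placed at a latency
#' inside the anticipatory window after stimulus onset, plus Gaussian
#' measurement noise.  Reinforced trials additionally receive an
#' unconditioned-response burst at US onset (stimulus offset).
#'
#' Per-trial amplitudes are drawn as `max(0, rnorm(mean, trial_sd))` around
#' the condition mean; latencies are drawn from the estimator's 0.25 s
#' grid by default so that noise-free recovery is exact (set
#' `latency_grid = NULL` for continuous latencies).
#'
#' @param design an `experiment_design`.
#' @param amp_by_role named vector of mean burst amplitudes (microsiemens)
#'   per role; default `c("CS+" = 1, "CS-" = 0.5, NS1 = 0.5, NS2 = 0.5)`,
#'   i.e. acquired fear raises anticipatory arousal on `CS+` trials.
#' @param noise_sd SD of additive white measurement noise.
#' @param trial_sd SD of trial-to-trial amplitude variability around the
#'   condition mean (truncated at 0).
#' @param amp_us mean amplitude of the unconditioned response on
#'   reinforced trials (default 2).
#' @param sample_rate sampling rate in Hz (default 10; the estimator is
#'   rate-agnostic).
#' @param params an [scrf_params()] object.
#' @param latency_grid candidate latencies (s after onset) from which each
#'   trial's true latency is drawn; `NULL` draws uniformly in the window.
#' @param seed RNG seed.
#' @return an object of class `scr_trace` with elements `signal`, `time`,
#'   `sample_rate` and `ground_truth` (per-trial amplitudes and latencies).
#' @export
simulate_scr <- function(design,
                         amp_by_role = c("CS+" = 1, "CS-" = 0.5,
                                         "NS1" = 0.5, "NS2" = 0.5),
                         noise_sd = 0.1, trial_sd = 0.2, amp_us = 2,
                         sample_rate = 10, params = scrf_params(),
                         latency_grid = seq(0, 3.5, by = 0.25), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  if (any(amp_by_role < 0) || amp_us < 0) stop("amplitudes must be >= 0")
  roles <- unique(design$trials$role)
  missing <- setdiff(roles, names(amp_by_role))
  if (length(missing))
    stop("amp_by_role lacks roles: ", paste(missing, collapse = ", "))
  itis <- diff(design$trials$onset) - design$trials$duration[-nrow(design$trials)]
  if (any(itis < 1))
    stop("inter-trial interval below 1 s: kernel placement undefined")
  tr <- design$trials
  n_samp <- ceiling((max(tr$onset) + 30) * sample_rate)
  kern <- canonical_scrf(sample_rate, params)
  with_seed(seed, {
    amps <- pmax(0, rnorm(nrow(tr), amp_by_role[tr$role], trial_sd))
    lat <- if (is.null(latency_grid)) {
      runif(nrow(tr), params$latency_window[1], params$latency_window[2])
    } else {
      latency_grid[sample.int(length(latency_grid), nrow(tr), replace = TRUE)]
    }
    sig <- numeric(n_samp)
    add_burst <- function(sig, t0, a) {
      i0 <- round(t0 * sample_rate) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, n_samp)
      sig[idx] <- sig[idx] + a * kern[seq_along(idx)]
      sig
    }
    for (i in seq_len(nrow(tr)))
      sig <- add_burst(sig, tr$onset[i] + lat[i], amps[i])
    us_amps <- rep(NA_real_, nrow(tr))
    for (i in which(tr$reinforced)) {
      us_amps[i] <- max(0, rnorm(1, amp_us, trial_sd))
      sig <- add_burst(sig, tr$onset[i] + tr$duration[i], us_amps[i])
    }
    if (noise_sd > 0) sig <- sig + rnorm(n_samp, sd = noise_sd)
  })
  structure(list(signal = sig, time = (seq_len(n_samp) - 1L) / sample_rate,
                 sample_rate = sample_rate,
                 ground_truth = list(amplitudes = amps, latencies = lat,
                                     us_amplitudes = us_amps)),
            class = "scr_trace")
}

#' Write / read a skin conductance trace as two-column TSV
#'
#' @param trace an `scr_trace` (or any list with `time` and `signal`).
#' @param path file path.
#' @return `write_scr_tsv` returns `path` invisibly; `read_scr_tsv`
#'   returns an `scr_trace` (without ground truth).
#' @export
write_scr_tsv <- function(trace, path) {
  write.table(data.frame(time = trace$time, conductance = trace$signal),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scr_tsv
#' @export
read_scr_tsv <- function(path) {
  d <- read.delim(path)
  if (!all(c("time", "conductance") %in% names(d)))
    stop("trace file must have columns 'time' and 'conductance'")
  dt <- diff(d$time)
  if (any(abs(dt - dt[1]) > 1e-6)) stop("trace must be uniformly sampled")
  structure(list(signal = d$conductance, time = d$time,
                 sample_rate = 1 / dt[1], ground_truth = NULL),
            class = "scr_trace")
}
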