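#' Generative specification for synthetic BOLD data
#'
#' Encodes the three competing hypotheses about threat coding as generative
#' regimes.  Every stimulus carries a stimulus-identity multivoxel pattern
#' over the whole grid; `CS+` trials may additionally carry a threat
#' pattern confined to a designated ROI, either shared across sound
#' complexities (`amp_threat_shared`), complexity-specific with orthogonal
#' patterns (`amp_threat_specific`), or absent (both zero).
#'
#' All pattern vectors have unit Euclidean norm, so amplitudes are in
#' noise-SD units when `noise_sd = 1`.
#'
#' @param grid_dim integer 3-vector of grid dimensions (default `c(12,12,12)`).
#' @param voxel_size voxel edge length in mm (default 1.5, isotropic).
#' @param roi_labels optional integer 3-D label array on the grid; by
#'   default three disjoint cuboid ROIs (1 = HG-like, 2 = higher-ACX-like,
#'   3 = amygdala-like) are placed by [make_roi_labels()].
#' @param threat_roi label of the ROI carrying threat patterns (default 1).
#' @param amp_stimulus amplitude of the per-stimulus identity patterns.
#' @param amp_threat_shared amplitude of the complexity-invariant threat
#'   pattern added to all `CS+` trials.
#' @param amp_threat_specific amplitude of the per-complexity (mutually
#'   orthogonal) threat patterns added to `CS+` trials.
#' @param noise_sd SD of additive Gaussian voxel noise.
#' @param ar_rho lag-1 autocorrelation of the noise (0 = white).
#' @param drift_amplitude,drift_period sinusoidal low-frequency drift
#'   (amplitude in signal units; period in seconds, default 300 s, i.e.
#'   below the 1/128 Hz high-pass edge).
#' @param boxcar_duration duration in seconds of the generative neural
#'   boxcar (default 3.5, matching the estimation model).
#' @param baseline constant signal offset.
#' @param pattern_seed seed for drawing the unit-norm patterns, so the same
#'   patterns can be planted across subjects or regimes.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(grid_dim = c(12L, 12L, 12L), voxel_size = 1.5,
                        roi_labels = NULL, threat_roi = 1L,
                        amp_stimulus = 1, amp_threat_shared = 0,
                        amp_threat_specific = 0, noise_sd = 1, ar_rho = 0,
                        drift_amplitude = 1, drift_period = 300,
                        boxcar_duration = 3.5, baseline = 100,
                        pattern_seed = 1L) {
  if (any(c(noise_sd, drift_amplitude) < 0)) stop("sds/amplitudes must be >= 0")
  if (abs(ar_rho) >= 1) stop("ar_rho must lie in (-1, 1)")
  if (is.null(roi_labels)) roi_labels <- make_roi_labels(grid_dim)
  stopifnot(all(dim(roi_labels) == grid_dim))
  n_vox <- prod(grid_dim)
  unit <- function(v) v / sqrt(sum(v^2))
  with_seed(pattern_seed, {
    stim_pat <- t(vapply(1:8, function(i) unit(rnorm(n_vox)), numeric(n_vox)))
    roi_idx <- which(as.vector(roi_labels) == threat_roi)
    if (!length(roi_idx)) stop("threat_roi label absent from roi_labels")
    mk_roi_pattern <- function() {
      v <- numeric(n_vox); v[roi_idx] <- rnorm(length(roi_idx)); unit(v)
    }
    threat_shared <- mk_roi_pattern()
    sp1 <- mk_roi_pattern()
    sp2v <- rnorm(length(roi_idx))
    # orthogonalize the two complexity-specific patterns
    sp2 <- numeric(n_vox); sp2[roi_idx] <- sp2v
    sp2 <- unit(sp2 - sum(sp2 * sp1) * sp1)
    threat_specific <- rbind(simple = sp1, complex = sp2)
  })
  structure(list(grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
                 roi_labels = roi_labels, threat_roi = as.integer(threat_roi),
                 stimulus_patterns = stim_pat,
                 threat_pattern_shared = threat_shared,
                 threat_pattern_specific = threat_specific,
                 amp_stimulus = amp_stimulus,
                 amp_threat_shared = amp_threat_shared,
                 amp_threat_specific = amp_threat_specific,
                 noise_sd = noise_sd, ar_rho = ar_rho,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 boxcar_duration = boxcar_duration, baseline = baseline),
            class = "effect_spec")
}

#' Effect specification for one of the three threat-coding hypotheses
#'
#' Hypothesis 1: no threat pattern beyond stimulus identity.  Hypothesis 2:
#' a threat pattern shared between simple and complex sounds.  Hypothesis
#' 3: complexity-specific (orthogonal) threat patterns.
#'
#' @param hypothesis 1, 2 or 3.
#' @param amp_threat threat-pattern amplitude used for the active regime.
#'   The default (4 voxel-noise-SD units along a unit-norm pattern) is
#'   deliberately strong so that desk-scale simulations with tens of
#'   subjects distinguish the regimes reliably; see the methods vignette.
#' @param ... passed to [effect_spec()].
#' @export
effect_spec_for_hypothesis <- function(hypothesis, amp_threat = 4, ...) {
  switch(as.character(hypothesis),
    "1" = effect_spec(amp_threat_shared = 0, amp_threat_specific = 0, ...),
    "2" = effect_spec(amp_threat_shared = amp_threat,
                      amp_threat_specific = 0, ...),
    "3" = effect_spec(amp_threat_shared = 0,
                      amp_threat_specific = amp_threat, ...),
    stop("hypothesis must be 1, 2 or 3"))
}

#' Default cuboid ROI label image
#'
#' Three disjoint cuboid ROIs (labels 1 = HG-like, 2 = higher-ACX-like,
#' 3 = amygdala-like) inside the grid, each of edge length about a third
#' of the grid (4x4x4 = 64 voxels on the default 12-cube); all other
#' voxels are labelled 0.
#'
#' @param grid_dim integer 3-vector (minimum 6 per axis).
#' @return integer 3-D array of labels.
#' @export
make_roi_labels <- function(grid_dim = c(12L, 12L, 12L)) {
  if (any(grid_dim < 6)) stop("grid_dim must be at least 6 in each axis")
  s <- max(2L, min(grid_dim) %/% 3L)
  lab <- array(0L, grid_dim)
  lo <- 2L:(1L + s)
  hi <- (grid_dim[1] - s):(grid_dim[1] - 1L)
  lab[lo, lo, lo] <- 1L
  lab[hi, lo, lo] <- 2L
  mid <- (grid_dim[2] - s):(grid_dim[2] - 1L)
  lab[lo, mid, mid] <- 3L
  lab
}

# per-trial ground-truth amplitude matrix [n_trials x n_voxels]
trial_amplitudes <- function(design, spec) {
  tr <- design$trials
  A <- spec$amp_stimulus * spec$stimulus_patterns[tr$stimulus_id, , drop = FALSE]
  is_csp <- tr$role == "CS+"
  if (any(is_csp)) {
    A[is_csp, ] <- A[is_csp, , drop = FALSE] +
      spec$amp_threat_shared *
        matrix(spec$threat_pattern_shared, sum(is_csp),
               ncol(A), byrow = TRUE)
    for (cpx in c("simple", "complex")) {
      sel <- is_csp & tr$complexity == cpx
      if (any(sel))
        A[sel, ] <- A[sel, , drop = FALSE] +
          spec$amp_threat_specific *
            matrix(spec$threat_pattern_specific[cpx, ], sum(sel),
                   ncol(A), byrow = TRUE)
    }
  }
  A
}

#' Simulate a 4-D BOLD series with planted multivoxel patterns
#'
#' Each voxel's time course is the sum over trials of an HRF-convolved
#' boxcar scaled by that trial's planted amplitude at that voxel, plus a
#' sinusoidal low-frequency drift with voxel-specific phase, plus (optionally
#' AR(1)) Gaussian noise and a constant baseline.
#'
#' @param design an `experiment_design`.
#' @param spec an [effect_spec()].
#' @param tr repetition time in seconds (default 2.5).
#' @param seed RNG seed for noise and drift phases.
#' @param n_scans optional number of volumes; must cover the last trial
#'   onset plus a 30 s response window (the default does).
#' @return an object of class `bold_series` with elements `data`
#'   (4-D array x,y,z,time), `tr`, `roi_labels` and `ground_truth`.
#' @export
simulate_bold <- function(design, spec = effect_spec(), tr = 2.5, seed = 1L,
                          n_scans = NULL) {
  stopifnot(inherits(design, "experiment_design"), inherits(spec, "effect_spec"))
  run_len <- design_run_length(design)
  last_onset <- max(design$trials$onset)
  n_scans <- n_scans %||% ceiling(max(run_len, last_onset + 30) / tr)
  if (n_scans * tr < last_onset + 30)
    stop("run length would truncate the final trial's response window")
  R <- convolved_regressors(design$trials$onset,
                            spec$boxcar_duration, n_scans, tr)
  A <- trial_amplitudes(design, spec)
  n_vox <- prod(spec$grid_dim)
  signal <- R %*% A
  scan_times <- (seq_len(n_scans) - 0.5) * tr
  with_seed(seed, {
    if (spec$drift_amplitude > 0) {
      phase <- runif(n_vox, 0, 2 * pi)
      drift <- spec$drift_amplitude *
        sin(outer(2 * pi * scan_times / spec$drift_period, phase, "+"))
      signal <- signal + drift
    }
    if (spec$noise_sd > 0) {
      eps <- matrix(rnorm(n_scans * n_vox, sd = spec$noise_sd), n_scans, n_vox)
      if (spec$ar_rho != 0) {
        eps <- apply(eps, 2, function(e)
          as.numeric(stats::filter(e, spec$ar_rho, method = "recursive"))) *
          sqrt(1 - spec$ar_rho^2)
      }
      signal <- signal + eps
    }
  })
  signal <- signal + spec$baseline
  structure(list(
    data = array(t(signal), c(spec$grid_dim, n_scans)),
    tr = tr, roi_labels = spec$roi_labels, voxel_size = spec$voxel_size,
    ground_truth = list(spec = spec, amplitudes = A, design = design)
  ), class = "bold_series")
}

#' Simulate a beta series directly (bypassing the BOLD forward model)
#'
#' Draws per-trial, per-voxel response amplitudes as planted patterns plus
#' i.i.d. Gaussian noise — the asymptotic output of the single-trial GLM on
#' data from [simulate_bold()].  Used where decoding behaviour, not GLM
#' estimation, is under study; orders of magnitude faster.
#'
#' @inheritParams simulate_bold
#' @param beta_noise_sd trial-level noise SD on the betas (default
#'   `spec$noise_sd`).
#' @return a `beta_series` object (see [estimate_betas()]).
#' @export
simulate_betas <- function(design, spec = effect_spec(), seed = 1L,
                           beta_noise_sd = NULL) {
  stopifnot(inherits(design, "experiment_design"), inherits(spec, "effect_spec"))
  beta_noise_sd <- beta_noise_sd %||% spec$noise_sd
  A <- trial_amplitudes(design, spec)
  B <- with_seed(seed, A + matrix(rnorm(length(A), sd = beta_noise_sd),
                                  nrow(A), ncol(A)))
  new_beta_series(B, design$trials, spec$grid_dim, spec$voxel_size,
                  roi_labels = spec$roi_labels)
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels, %d scans, TR %.2g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}
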