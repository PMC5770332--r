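#' Build the single-trial (least-squares-all) design matrix
#'
#' One regressor per trial — a 3.5 s boxcar at trial onset convolved with
#' the canonical HRF on a 0.1 s microtime grid and sampled at mid-volume
#' scan times — plus a single US regressor pooling all reinforced-trial
#' electric stimulations (0.5 s boxcars at stimulus offset), a discrete
#' cosine high-pass basis with 128 s cutoff, an explicit intercept, and
#' any supplied nuisance columns (e.g. motion parameters).
#'
#' @param design an `experiment_design` or a trial data frame as returned
#'   by [read_events_tsv()].
#' @param n_scans number of volumes.
#' @param tr repetition time in seconds.
#' @param hrf_par an [hrf_params()] object.
#' @param nuisance optional numeric matrix `n_scans x j` of nuisance
#'   regressors.
#' @param boxcar_duration event boxcar duration in seconds (default 3.5).
#' @param highpass_cutoff high-pass period in seconds (default 128).
#' @param us_duration US boxcar duration in seconds (default 0.5).
#' @param microtime_dt microtime resolution in seconds (default 0.1).
#' @return an object of class `trial_design_matrix` with elements `matrix`
#'   and `column_roles` (`"trial:i"`, `"US"`, `"dct:k"`, `"intercept"`,
#'   `"nuisance:j"`).
#' @export
build_design_matrix <- function(design, n_scans, tr = 2.5,
                                hrf_par = hrf_params(), nuisance = NULL,
                                boxcar_duration = 3.5, highpass_cutoff = 128,
                                us_duration = 0.5, microtime_dt = 0.1) {
  trials <- if (inherits(design, "experiment_design")) design$trials else design
  stopifnot(is.data.frame(trials), all(c("onset", "reinforced") %in% names(trials)))
  if (n_scans * tr < max(trials$onset) + boxcar_duration)
    stop("n_scans x tr must cover the last onset plus the boxcar duration")
  X_tr <- convolved_regressors(trials$onset, boxcar_duration, n_scans, tr,
                               hrf_par, microtime_dt)
  roles <- paste0("trial:", seq_len(nrow(trials)))
  # pooled US regressor at CS+ offsets of reinforced trials
  reinf <- which(trials$reinforced)
  if (length(reinf)) {
    us_onsets <- trials$onset[reinf] +
      (if ("duration" %in% names(trials)) trials$duration[reinf] else 4)
    X_us <- rowSums(convolved_regressors(us_onsets, us_duration, n_scans, tr,
                                         hrf_par, microtime_dt))
    X_tr <- cbind(X_tr, X_us)
    roles <- c(roles, "US")
  } else {
    warning("no reinforced trials: empty US regressor dropped")
  }
  X_dct <- dct_highpass_basis(n_scans, tr, highpass_cutoff)
  if (ncol(X_dct)) {
    X_tr <- cbind(X_tr, X_dct)
    roles <- c(roles, paste0("dct:", seq_len(ncol(X_dct))))
  }
  X_tr <- cbind(X_tr, 1)
  roles <- c(roles, "intercept")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance must have n_scans rows")
    X_tr <- cbind(X_tr, nuisance)
    roles <- c(roles, paste0("nuisance:", seq_len(ncol(nuisance))))
  }
  colnames(X_tr) <- roles
  trial_cols <- grep("^trial:", roles)
  # exact collinearity among trial columns is a degenerate design
  qr_tr <- qr(X_tr[, trial_cols, drop = FALSE])
  if (qr_tr$rank < length(trial_cols))
    stop("degenerate design: exactly collinear trial regressors")
  structure(list(matrix = X_tr, column_roles = roles,
                 boxcar_duration = boxcar_duration,
                 highpass_cutoff = highpass_cutoff, tr = tr,
                 trials = trials),
            class = "trial_design_matrix")
}

new_beta_series <- function(betas, trial_metadata, grid_dim = NULL,
                            voxel_size = NULL, voxel_index = NULL,
                            roi_labels = NULL) {
  stopifnot(nrow(betas) == nrow(trial_metadata))
  if (is.null(voxel_index) && !is.null(grid_dim)) {
    stopifnot(ncol(betas) == prod(grid_dim))
    voxel_index <- arrayInd(seq_len(prod(grid_dim)), grid_dim)
  }
  structure(list(betas = betas, trial_metadata = trial_metadata,
                 usable_mask = !trial_metadata$reinforced,
                 grid_dim = grid_dim, voxel_size = voxel_size,
                 voxel_index = voxel_index, roi_labels = roi_labels),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series> %d trials x %d voxels (%d usable trials)\n",
              nrow(x$betas), ncol(x$betas), sum(x$usable_mask)))
  invisible(x)
}

#' Estimate single-trial BOLD amplitudes (least-squares-all)
#'
#' Ordinary least squares per voxel, all regressors fit simultaneously;
#' only the trial-column coefficients are returned.  Reinforced trials are
#' flagged unusable in `usable_mask` (their conditioned response overlaps
#' the US response) and excluded by downstream decoding.
#'
#' @param bold a `bold_series` from [simulate_bold()], or a plain numeric
#'   matrix `n_scans x n_voxels`.
#' @param X a `trial_design_matrix` from [build_design_matrix()].
#' @param mask optional logical/0-1 3-D array selecting voxels (only for
#'   `bold_series` input).
#' @return an object of class `beta_series`: `betas`
#'   (`n_trials x n_voxels`), `trial_metadata`, `usable_mask`, and voxel
#'   grid information when available.
#' @export
estimate_betas <- function(bold, X, mask = NULL) {
  stopifnot(inherits(X, "trial_design_matrix"))
  grid_dim <- voxel_size <- voxel_index <- roi_labels <- NULL
  if (inherits(bold, "bold_series")) {
    d <- dim(bold$data)
    grid_dim <- d[1:3]
    voxel_size <- bold$voxel_size
    roi_labels <- bold$roi_labels
    Y <- matrix(bold$data, prod(grid_dim), d[4])
    keep <- if (is.null(mask)) seq_len(nrow(Y)) else {
      stopifnot(all(dim(mask) == grid_dim))
      which(as.vector(mask) != 0)
    }
    if (!length(keep)) stop("mask selects no voxels")
    Y <- t(Y[keep, , drop = FALSE])
    voxel_index <- arrayInd(keep, grid_dim)
  } else {
    Y <- as.matrix(bold)
  }
  M <- X$matrix
  if (nrow(M) != nrow(Y))
    stop("design matrix rows (", nrow(M), ") != time points (", nrow(Y), ")")
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) {
    bad <- X$column_roles[qrX$pivot[(qrX$rank + 1):ncol(M)]]
    stop("rank-deficient design matrix; offending columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, Y)
  trial_cols <- grep("^trial:", X$column_roles)
  new_beta_series(B[trial_cols, , drop = FALSE], X$trials,
                  grid_dim = grid_dim, voxel_size = voxel_size,
                  voxel_index = voxel_index, roi_labels = roi_labels)
}
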