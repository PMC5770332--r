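#' Linear SVM configuration
#'
#' Linear-kernel C-support-vector classification with the cited library's
#' default cost `C = 1`; features are pre-z-scored, so no internal scaling
#' is applied.  Decision values of exactly zero predict the majority
#' training class (the imbalance-induced prior).
#'
#' @param C soft-margin cost.
#' @param tol SMO stopping tolerance on the KKT violation.
#' @param max_iter maximum SMO iterations.
#' @export
svm_config <- function(C = 1, tol = 1e-4, max_iter = 100000L) {
  stopifnot(C > 0, tol > 0, max_iter > 0)
  structure(list(C = C, tol = tol, max_iter = as.integer(max_iter)),
            class = "svm_config")
}

#' Construct a feature matrix with class labels
#'
#' @param values numeric matrix `n_trials x n_voxels`.
#' @param labels per-trial class labels (2 levels).
#' @param trial_order original sequence positions of the trials (used for
#'   chronological fold assignment); defaults to row order.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, trial_order = seq_len(nrow(values))) {
  values <- as.matrix(values)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly 2 classes")
  if (length(labels) != nrow(values) || length(trial_order) != nrow(values))
    stop("labels/trial_order length must match rows of values")
  if (anyNA(values)) stop("feature matrix contains missing values")
  structure(list(values = values, labels = labels, trial_order = trial_order),
            class = "feature_matrix")
}

#' Z-score features per voxel across trials
#'
#' Each voxel is independently standardized across the selected trials
#' (population-SD convention, i.e. dividing by the root mean squared
#' deviation).  Constant voxels are dropped with a warning.
#'
#' @param betas a `beta_series`, a `feature_matrix`, or a numeric matrix.
#' @param trial_subset optional row indices selecting the trials to use
#'   (for a `beta_series`, indices into its trials).
#' @param labels class labels for the selected trials; for a
#'   `beta_series`, defaults to the trial `role`.
#' @return a `feature_matrix` with standardized `values`.
#' @export
zscore_features <- function(betas, trial_subset = NULL, labels = NULL) {
  if (inherits(betas, "beta_series")) {
    trial_subset <- trial_subset %||% which(betas$usable_mask)
    vals <- betas$betas[trial_subset, , drop = FALSE]
    labels <- labels %||% betas$trial_metadata$role[trial_subset]
    ord <- betas$trial_metadata$trial_index[trial_subset]
  } else {
    vals <- if (inherits(betas, "feature_matrix")) betas$values else as.matrix(betas)
    if (inherits(betas, "feature_matrix")) labels <- labels %||% betas$labels
    if (!is.null(trial_subset)) {
      vals <- vals[trial_subset, , drop = FALSE]
      if (!is.null(labels) && length(labels) > nrow(vals))
        labels <- labels[trial_subset]
    }
    ord <- seq_len(nrow(vals))
  }
  if (nrow(vals) < 2) stop("need at least 2 trials to z-score")
  mu <- colMeans(vals)
  sdev <- sqrt(colMeans(sweep(vals, 2, mu)^2))  # population SD
  keep <- sdev > 0
  if (!any(keep)) stop("all features are constant; cannot z-score")
  if (!all(keep))
    warning(sum(!keep), " constant feature(s) dropped before z-scoring")
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  if (is.null(labels)) labels <- rep(c("A", "B"), length.out = nrow(z))
  feature_matrix(z, labels, ord)
}

#' Interleaved three-fold cross-validation scheme
#'
#' Every third trial (by sequence position) serves as test data: fold
#' index of position `p` is `(p - 1) mod n_folds`.  With 36 trials this
#' gives training sets of 24 and test sets of 12.
#'
#' @param n_trials number of trials.
#' @param n_folds number of folds (default 3).
#' @return an object of class `fold_scheme` (integer fold assignment,
#'   0-based, in position order).
#' @export
make_folds <- function(n_trials, n_folds = 3L) {
  stopifnot_scalar_count(n_trials, "n_trials")
  if (n_trials < n_folds) stop("need at least n_folds trials")
  structure(list(n_folds = as.integer(n_folds),
                 assignment = as.integer((seq_len(n_trials) - 1L) %% n_folds)),
            class = "fold_scheme")
}

labels_pm1 <- function(labels) {
  ifelse(as.integer(labels) == 1L, 1L, -1L)
}

# count-preserving label permutations as an n x n_perm matrix of +/-1
permute_labels <- function(y_pm1, n_perm) {
  vapply(seq_len(n_perm), function(i) sample(y_pm1), integer(length(y_pm1)))
}

#' Cross-validated decoding accuracy for one condition
#'
#' Trains a linear SVM per fold on the training trials and pools accuracy
#' over all test trials.
#'
#' @param fm a `feature_matrix`.
#' @param folds a `fold_scheme` (defaults to interleaved three-fold on the
#'   trials of `fm`).
#' @param svm an [svm_config()].
#' @return raw accuracy (fraction of correctly classified test trials).
#' @export
decode_condition <- function(fm, folds = make_folds(nrow(fm$values)),
                             svm = svm_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(folds, "fold_scheme"))
  .svc_cv_accuracy(fm$values, labels_pm1(fm$labels), folds$assignment,
                   folds$n_folds, svm$C, svm$tol, svm$max_iter)
}

#' Permutation-based chance accuracy
#'
#' Reruns the full cross-validation under `n_perm` uniform label
#' permutations (class counts preserved) and returns the mean permuted
#' accuracy — the empirical chance level of the classifier, which under
#' class imbalance exceeds the naive 50%.
#'
#' @inheritParams decode_condition
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with `chance_accuracy` (mean) and `accuracies` (per
#'   permutation).
#' @export
permutation_chance <- function(fm, folds = make_folds(nrow(fm$values)),
                               n_perm = 1000L, seed = 1L,
                               svm = svm_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- labels_pm1(fm$labels)
  perms <- with_seed(seed, permute_labels(y, n_perm))
  acc <- .svc_cv_perm_accuracies(fm$values, perms, folds$assignment,
                                 folds$n_folds, svm$C, svm$tol, svm$max_iter)
  list(chance_accuracy = mean(acc), accuracies = acc)
}

new_decoding_outcome <- function(raw, chance, condition = NULL,
                                 n_permutations = NA_integer_,
                                 n_subsample_reps = NA_integer_, seed = NA) {
  structure(list(raw_accuracy = raw, chance_accuracy = chance,
                 corrected_accuracy = raw - chance, condition = condition,
                 n_permutations = n_permutations,
                 n_subsample_reps = n_subsample_reps, seed = seed),
            class = "decoding_outcome")
}

#' @export
print.decoding_outcome <- function(x, ...) {
  cat(sprintf("<decoding_outcome>%s raw %.3f, chance %.3f, corrected %+.3f\n",
              if (is.null(x$condition)) "" else
                paste0(" [", paste(x$condition, collapse = ", "), "]"),
              x$raw_accuracy, x$chance_accuracy, x$corrected_accuracy))
  invisible(x)
}

#' Decode one condition with permutation chance correction
#'
#' Convenience wrapper: raw accuracy via [decode_condition()], chance via
#' [permutation_chance()], corrected = raw - chance.
#'
#' @inheritParams permutation_chance
#' @param condition optional label (e.g. `c("reinforced", "simple")`).
#' @return a `decoding_outcome`.
#' @export
decode_roi <- function(fm, folds = make_folds(nrow(fm$values)),
                       n_perm = 1000L, seed = 1L, svm = svm_config(),
                       condition = NULL) {
  raw <- decode_condition(fm, folds, svm)
  ch <- permutation_chance(fm, folds, n_perm, seed, svm)
  new_decoding_outcome(raw, ch$chance_accuracy, condition, n_perm, seed = seed)
}

#' Bias-matched decoding of the neutral conditions by subsampling
#'
#' The neutral context has 24 + 24 usable trials, whereas the reinforced
#' context has 12 `CS+` vs 24 `CS-`.  To match bias and power, one neutral
#' class is randomly halved to 12 before decoding; the halved class
#' alternates deterministically across repetitions so both classes are
#' halved equally often.  Raw and permutation-chance accuracies are both
#' averaged over repetitions; corrected = mean raw - mean chance.
#'
#' @param fm_ns `feature_matrix` of the 48 neutral trials (24 per class),
#'   in chronological order.
#' @param n_rep number of subsampling repetitions (default 100).
#' @param n_perm permutations per repetition (default 1000).
#' @param seed RNG seed.
#' @param svm an [svm_config()].
#' @param condition optional condition label.
#' @return a `decoding_outcome` with `n_subsample_reps` set.
#' @export
subsampled_ns_decoding <- function(fm_ns, n_rep = 100L, n_perm = 1000L,
                                   seed = 1L, svm = svm_config(),
                                   condition = NULL) {
  stopifnot(inherits(fm_ns, "feature_matrix"))
  tab <- table(fm_ns$labels)
  if (length(tab) != 2 || tab[1] != tab[2])
    stop("subsampled decoding expects two equally sized neutral classes (24 + 24)")
  y <- labels_pm1(fm_ns$labels)
  half <- unname(tab[1]) %/% 2L
  seeds <- derive_seeds(seed, n_rep)
  raws <- chances <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    with_seed(seeds[r], {
      cls <- if (r %% 2L == 1L) 1L else -1L  # alternate which class is halved
      keep_cls <- sort(sample(which(y == cls), half))
      keep <- sort(c(keep_cls, which(y != cls)))
      vals <- fm_ns$values[keep, , drop = FALSE]
      yk <- y[keep]
      folds <- make_folds(length(keep))
      raws[r] <- .svc_cv_accuracy(vals, yk, folds$assignment, folds$n_folds,
                                  svm$C, svm$tol, svm$max_iter)
      perms <- permute_labels(yk, n_perm)
      chances[r] <- mean(.svc_cv_perm_accuracies(vals, perms, folds$assignment,
                                                 folds$n_folds, svm$C,
                                                 svm$tol, svm$max_iter))
    })
  }
  out <- new_decoding_outcome(mean(raws), mean(chances), condition,
                              n_perm, n_rep, seed)
  out$rep_raw <- raws
  out$rep_chance <- chances
  out
}

#' Cross-classification between stimulus sets
#'
#' Trains a single SVM on all training trials (no cross-validation) and
#' evaluates it on all test trials, e.g. training on the `CS+`/`CS-`
#' distinction for simple sounds and testing on complex sounds.  Chance is
#' estimated by permuting the training labels and re-evaluating on the
#' (unpermuted) test set.
#'
#' @param fm_train,fm_test `feature_matrix` objects sharing the voxel
#'   space and label scheme.
#' @param n_perm number of training-label permutations (default 1000).
#' @param seed RNG seed.
#' @param svm an [svm_config()].
#' @param direction,stimulus_set optional annotations (e.g.
#'   `"simple->complex"`, `"CS"`).
#' @return a `cross_decoding_outcome` (inherits `decoding_outcome`).
#' @export
cross_classify <- function(fm_train, fm_test, n_perm = 1000L, seed = 1L,
                           svm = svm_config(), direction = NULL,
                           stimulus_set = NULL) {
  stopifnot(inherits(fm_train, "feature_matrix"),
            inherits(fm_test, "feature_matrix"))
  if (ncol(fm_train$values) != ncol(fm_test$values))
    stop("train and test feature matrices differ in voxel space")
  if (!identical(levels(fm_train$labels), levels(fm_test$labels)))
    stop("train and test label schemes differ")
  ytr <- labels_pm1(fm_train$labels)
  yte <- labels_pm1(fm_test$labels)
  perms <- with_seed(seed, permute_labels(ytr, n_perm))
  acc <- .svc_transfer_accuracies(fm_train$values, cbind(ytr, perms),
                                  fm_test$values, yte,
                                  svm$C, svm$tol, svm$max_iter)
  out <- new_decoding_outcome(acc[1], mean(acc[-1]),
                              condition = stimulus_set, n_perm, seed = seed)
  out$direction <- direction
  out$stimulus_set <- stimulus_set
  class(out) <- c("cross_decoding_outcome", class(out))
  out
}
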