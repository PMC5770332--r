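# Subject-level decoding pipelines tying the beta series to the
# condition-wise and cross-classification analyses.

# usable trials of one (context, complexity) cell, in chronological order
condition_trials <- function(meta, usable, context, complexity) {
  idx <- which(meta$context == context & meta$complexity == complexity & usable)
  idx[order(meta$onset[idx])]
}

#' Condition-wise ROI decoding for one subject
#'
#' For each complexity, decodes `CS+` vs `CS-` on the usable (non
#' reinforced) trials of the reinforced context (12:24 imbalance) with
#' permutation chance correction, and `NS1` vs `NS2` in the neutral
#' context via the bias-matched subsampling procedure
#' ([subsampled_ns_decoding()]).  Features are z-scored per voxel across
#' the trials entering each analysis.
#'
#' @param betas a `beta_series`.
#' @param voxels optional column indices selecting the ROI voxels
#'   (default: all voxels in `betas`).
#' @param n_perm label permutations per chance estimate.
#' @param n_rep neutral-condition subsampling repetitions.
#' @param seed master RNG seed (sub-seeds are derived per condition).
#' @param svm an [svm_config()].
#' @return data frame with one row per (context, complexity):
#'   `raw_accuracy`, `chance_accuracy`, `corrected_accuracy`.
#' @export
roi_decoding_table <- function(betas, voxels = NULL, n_perm = 1000L,
                               n_rep = 100L, seed = 1L, svm = svm_config()) {
  stopifnot(inherits(betas, "beta_series"))
  meta <- betas$trial_metadata
  vals <- betas$betas
  if (!is.null(voxels)) vals <- vals[, voxels, drop = FALSE]
  seeds <- derive_seeds(seed, 4L)
  cells <- expand.grid(context = c("reinforced", "neutral"),
                       complexity = c("simple", "complex"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ctx <- cells$context[i]; cpx <- cells$complexity[i]
    idx <- condition_trials(meta, betas$usable_mask, ctx, cpx)
    fm <- zscore_features(vals[idx, , drop = FALSE],
                          labels = meta$role[idx])
    if (ctx == "reinforced") {
      out <- decode_roi(fm, make_folds(nrow(fm$values)), n_perm,
                        seed = seeds[i], svm = svm,
                        condition = c(ctx, cpx))
    } else {
      out <- subsampled_ns_decoding(fm, n_rep, n_perm, seed = seeds[i],
                                    svm = svm, condition = c(ctx, cpx))
    }
    data.frame(context = ctx, complexity = cpx,
               raw_accuracy = out$raw_accuracy,
               chance_accuracy = out$chance_accuracy,
               corrected_accuracy = out$corrected_accuracy)
  })
  do.call(rbind, rows)
}

#' Cross-classification between simple and complex sounds for one subject
#'
#' Trains on the `CS+`/`CS-` distinction for all 36 usable trials of one
#' complexity in the reinforced context and tests on the other complexity
#' (both directions).  As a control matched for motor response, the same
#' transfer is computed for neutral sounds labelled by required key press;
#' to match the 12:24 class imbalance of the CS analysis, the
#' key-matched training set is subsampled (one key class halved,
#' alternating across `n_rep` repetitions) and results averaged.
#'
#' @inheritParams roi_decoding_table
#' @return data frame with one row per (stimulus_set, direction).
#' @export
cross_decoding_table <- function(betas, voxels = NULL, n_perm = 1000L,
                                 n_rep = 100L, seed = 1L, svm = svm_config()) {
  stopifnot(inherits(betas, "beta_series"))
  meta <- betas$trial_metadata
  vals <- betas$betas
  if (!is.null(voxels)) vals <- vals[, voxels, drop = FALSE]
  seeds <- derive_seeds(seed, 4L)

  fm_cs <- lapply(c(simple = "simple", complex = "complex"), function(cpx) {
    idx <- condition_trials(meta, betas$usable_mask, "reinforced", cpx)
    zscore_features(vals[idx, , drop = FALSE],
                    labels = factor(meta$role[idx], c("CS+", "CS-")))
  })
  fm_ns <- lapply(c(simple = "simple", complex = "complex"), function(cpx) {
    idx <- condition_trials(meta, betas$usable_mask, "neutral", cpx)
    zscore_features(vals[idx, , drop = FALSE],
                    labels = factor(meta$response_key[idx], c("left", "right")))
  })

  dirs <- data.frame(train = c("simple", "complex"),
                     test = c("complex", "simple"),
                     stringsAsFactors = FALSE)
  rows <- list()
  for (d in seq_len(nrow(dirs))) {
    lab <- paste0(dirs$train[d], "->", dirs$test[d])
    cs <- cross_classify(fm_cs[[dirs$train[d]]], fm_cs[[dirs$test[d]]],
                         n_perm, seed = seeds[d], direction = lab,
                         stimulus_set = "CS")
    rows[[length(rows) + 1L]] <- data.frame(
      stimulus_set = "CS", direction = lab,
      raw_accuracy = cs$raw_accuracy, chance_accuracy = cs$chance_accuracy,
      corrected_accuracy = cs$corrected_accuracy)
    ns <- subsampled_cross(fm_ns[[dirs$train[d]]], fm_ns[[dirs$test[d]]],
                           n_perm, n_rep, seeds[2L + d], svm)
    rows[[length(rows) + 1L]] <- data.frame(
      stimulus_set = "NS", direction = lab,
      raw_accuracy = ns$raw, chance_accuracy = ns$chance,
      corrected_accuracy = ns$raw - ns$chance)
  }
  do.call(rbind, rows)
}

# key-matched neutral transfer with imbalance-matched subsampled training
subsampled_cross <- function(fm_train, fm_test, n_perm, n_rep, seed,
                             svm = svm_config()) {
  y <- labels_pm1(fm_train$labels)
  yte <- labels_pm1(fm_test$labels)
  tab <- table(y)
  if (length(tab) != 2 || tab[1] != tab[2])
    stop("key-matched transfer expects two equally sized training classes")
  half <- unname(tab[1]) %/% 2L
  seeds <- derive_seeds(seed, n_rep)
  raws <- chances <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    with_seed(seeds[r], {
      cls <- if (r %% 2L == 1L) 1L else -1L
      keep <- sort(c(sample(which(y == cls), half), which(y != cls)))
      Xtr <- fm_train$values[keep, , drop = FALSE]
      yk <- y[keep]
      perms <- permute_labels(yk, n_perm)
      acc <- .svc_transfer_accuracies(Xtr, cbind(yk, perms), fm_test$values,
                                      yte, svm$C, svm$tol, svm$max_iter)
      raws[r] <- acc[1]
      chances[r] <- mean(acc[-1])
    })
  }
  list(raw = mean(raws), chance = mean(chances))
}
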