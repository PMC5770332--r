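test_that("z-scoring satisfies its contract", {
  set.seed(1)
  fm <- zscore_features(matrix(rnorm(40 * 7) * 5 + 2, 40, 7))
  expect_lt(max(abs(colMeans(fm$values))), 1e-10)
  psd <- apply(fm$values, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(psd - 1)), 1e-10)
})

test_that("z-scoring uses the population-SD convention", {
  fm <- zscore_features(matrix(c(1, 3, 3, 1), 2, 2), labels = c("A", "B"))
  expect_equal(unname(fm$values), matrix(c(-1, 1, 1, -1), 2, 2))
})

test_that("constant voxels are dropped; all-constant input fails", {
  X <- cbind(rnorm(10), rep(2, 10), rnorm(10))
  expect_warning(fm <- zscore_features(X), "1 constant feature")
  expect_equal(ncol(fm$values), 2)
  expect_error(suppressWarnings(zscore_features(matrix(1, 10, 3))),
               "all features are constant")
  expect_error(zscore_features(matrix(1, 1, 3)), "at least 2 trials")
})

test_that("fold scheme is the interleaved partition", {
  f <- make_folds(36)
  expect_equal(as.integer(table(f$assignment)), rep(12L, 3))
  for (k in 0:2) {
    test_k <- which(f$assignment == k)
    expect_equal(length(test_k), 12)
    expect_equal(36 - length(test_k), 24)
    expect_equal(test_k, seq(k + 1, 36, by = 3))
  }
  expect_equal(sort(unlist(lapply(0:2, function(k) which(f$assignment == k)))),
               1:36)
  expect_equal(make_folds(3)$assignment, c(0L, 1L, 2L))
  expect_error(make_folds(2), "at least")
})

test_that("a single permutation is reproducible under a fixed seed", {
  f <- null_condition_features(12, 24, p = 10, seed = 3)
  fm <- feature_matrix(f$values, f$labels)
  a <- permutation_chance(fm, n_perm = 1, seed = 42)
  b <- permutation_chance(fm, n_perm = 1, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$accuracies,
                         permutation_chance(fm, n_perm = 1, seed = 43)$accuracies))
})

test_that("balanced-label chance sits at 50%", {
  ch <- vapply(1:20, function(s) {
    f <- null_condition_features(18, 18, p = 40, seed = 600 + s)
    permutation_chance(feature_matrix(f$values, f$labels),
                       n_perm = 120, seed = s)$chance_accuracy
  }, numeric(1))
  expect_gte(mean(ch), 0.48)
  expect_lte(mean(ch), 0.52)
})

test_that("permutation distribution covers the observed accuracy under the null", {
  # exchangeable labels: raw accuracy should fall in the central 95% of
  # the permutation distribution about 95% of the time
  inside <- vapply(1:150, function(s) {
    f <- null_condition_features(12, 24, p = 15, seed = 4000 + s)
    fm <- feature_matrix(f$values, f$labels)
    raw <- decode_condition(fm)
    perm <- permutation_chance(fm, n_perm = 99, seed = s)$accuracies
    lo <- quantile(perm, 0.025, type = 1)
    hi <- quantile(perm, 0.975, type = 1)
    raw >= lo && raw <= hi
  }, logical(1))
  expect_gte(mean(inside), 0.92)
  expect_lte(mean(inside), 1.0)
})

test_that("NS subsampling enforces and requires the 24+24 structure", {
  f <- null_condition_features(24, 24, p = 12, seed = 9)
  fm <- feature_matrix(f$values, f$labels)
  out <- subsampled_ns_decoding(fm, n_rep = 4, n_perm = 10, seed = 5)
  expect_equal(out$n_subsample_reps, 4)
  expect_length(out$rep_raw, 4)
  expect_identical(out$corrected_accuracy,
                   mean(out$rep_raw) - mean(out$rep_chance))
  expect_identical(out,
                   subsampled_ns_decoding(fm, n_rep = 4, n_perm = 10, seed = 5))
  bad <- feature_matrix(f$values[1:47, ], f$labels[1:47])
  expect_error(subsampled_ns_decoding(bad), "equally sized")
})

test_that("subsampling matches the bias of the imbalanced CS analysis", {
  # same planted amplitude and noise model in both contexts: corrected
  # accuracies should agree (the procedure's stated purpose)
  cs <- ns <- numeric(30)
  for (s in 1:30) {
    csf <- planted_condition_features(2, 12, 24, p = 32, seed = 100 + s)
    nsf <- planted_condition_features(2, 24, 24, p = 32, seed = 500 + s)
    cs[s] <- decode_roi(feature_matrix(csf$values, csf$labels),
                        n_perm = 120, seed = s)$corrected_accuracy
    ns[s] <- subsampled_ns_decoding(feature_matrix(nsf$values, nsf$labels),
                                    n_rep = 10, n_perm = 120,
                                    seed = s)$corrected_accuracy
  }
  expect_gt(t.test(cs, ns, paired = TRUE)$p.value, 0.05)
  expect_lt(abs(mean(cs) - mean(ns)), 0.05)
})

test_that("cross-classification validates its inputs", {
  f <- null_condition_features(12, 24, p = 10, seed = 2)
  fm <- feature_matrix(f$values, f$labels)
  g <- null_condition_features(12, 24, p = 11, seed = 3)
  expect_error(cross_classify(fm, feature_matrix(g$values, g$labels)),
               "voxel space")
  h <- null_condition_features(12, 24, p = 10, seed = 4)
  fm_h <- feature_matrix(h$values, factor(h$labels, levels = c("B", "A")))
  expect_error(cross_classify(fm, fm_h), "label schemes")
})

test_that("shared patterns transfer across sets; chance permutation is seeded", {
  set.seed(8)
  p <- 24
  u <- rnorm(p); u <- u / sqrt(sum(u^2))
  mk <- function(seed) {
    f <- null_condition_features(12, 24, p = p, seed = seed)
    sel <- f$labels == "A"
    f$values[sel, ] <- f$values[sel, ] + matrix(5 * u, sum(sel), p, byrow = TRUE)
    feature_matrix(f$values, f$labels)
  }
  out <- cross_classify(mk(21), mk(22), n_perm = 60, seed = 7)
  expect_gt(out$corrected_accuracy, 0.15)
  expect_identical(out$chance_accuracy,
                   cross_classify(mk(21), mk(22), n_perm = 60,
                                  seed = 7)$chance_accuracy)
})
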