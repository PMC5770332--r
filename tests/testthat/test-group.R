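make_balanced_table <- function(n_subj, factors, seed = 1, n_per_cell = 1) {
  with_seed2(seed, {
    cells <- do.call(expand.grid, c(stats::setNames(
      rep(list(c("lo", "hi")), length(factors)), factors),
      list(stringsAsFactors = FALSE)))
    tbl <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
      d <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), , drop = FALSE]
      d$subject <- s
      d
    }))
    tbl$response <- rnorm(nrow(tbl))
    tbl
  })
}

test_that("containment df reproduce the published denominators", {
  # decoding model: 18 subjects, 2x2x2, one observation per cell -> df 119
  t3 <- make_balanced_table(18, c("context", "complexity", "hemisphere"))
  f3 <- mixed_anova(t3, c("context", "complexity", "hemisphere"))
  expect_equal(nrow(f3), 7)
  expect_true(all(f3$df_den == 119))
  expect_true(all(f3$df_num == 1))
  # amygdala model: 18 subjects, 2x2 -> df 51
  t2 <- make_balanced_table(18, c("context", "complexity"))
  expect_true(all(mixed_anova(t2, c("context", "complexity"))$df_den == 51))
  # trial-level arousal model: 16 subjects x 168 usable trials, 2x2x2 -> 2665
  t_scr <- do.call(rbind, lapply(1:16, function(s) {
    cells <- expand.grid(cs = c("plus", "minus"), context = c("rf", "nt"),
                         complexity = c("si", "co"), stringsAsFactors = FALSE)
    n_per <- ifelse(cells$cs == "plus" & cells$context == "rf", 12, 24)
    d <- cells[rep(seq_len(8), n_per), ]
    d$subject <- s
    d
  }))
  set.seed(2)
  t_scr$response <- rnorm(nrow(t_scr))
  expect_equal(nrow(t_scr), 16 * 168)
  f_scr <- suppressWarnings(mixed_anova(t_scr, c("cs", "context", "complexity")))
  expect_true(all(f_scr$df_den == 2665))
  expect_true(all(is.finite(f_scr$F)))
})

test_that("one-obs-per-cell F values match an independent sums-of-squares oracle", {
  tbl <- make_balanced_table(6, c("A", "B"), seed = 8)
  tbl$response <- tbl$response +
    ifelse(tbl$A == "hi", 0.8, 0) + ifelse(tbl$B == "hi", -0.4, 0)
  got <- mixed_anova(tbl, c("A", "B"))
  # oracle: classical repeated-measures ANOVA from cell means
  y <- tbl$response
  g <- mean(y)
  ss <- function(means, n_each) n_each * sum((means - g)^2)
  m_subj <- tapply(y, tbl$subject, mean)
  m_a <- tapply(y, tbl$A, mean); m_b <- tapply(y, tbl$B, mean)
  m_ab <- tapply(y, paste(tbl$A, tbl$B), mean)
  ss_a <- ss(m_a, 12); ss_b <- ss(m_b, 12)
  ss_ab <- ss(m_ab, 6) - ss_a - ss_b
  ss_subj <- ss(m_subj, 4)
  sse <- sum((y - g)^2) - ss_subj - ss_a - ss_b - ss_ab
  df_den <- 24 - 6 - 3
  oracle_F <- c(A = ss_a, B = ss_b, `A x B` = ss_ab) / (sse / df_den)
  expect_equal(got$F[match(c("A", "B", "A x B"), got$effect)],
               unname(oracle_F), tolerance = 1e-6)
  expect_true(all(got$df_den == df_den))
})

test_that("df identity holds for arbitrary balanced designs", {
  for (k in 1:3) {
    for (n_subj in c(5, 9)) {
      factors <- paste0("f", seq_len(k))
      tbl <- make_balanced_table(n_subj, factors, seed = k * 10 + n_subj)
      ft <- mixed_anova(tbl, factors)
      expect_true(all(ft$df_den == n_subj * 2^k - n_subj - (2^k - 1)))
      expect_equal(nrow(ft), 2^k - 1)
    }
  }
})

test_that("mixed_anova is invariant to subject and level relabelling", {
  tbl <- make_balanced_table(8, c("A", "B"), seed = 3)
  base <- mixed_anova(tbl, c("A", "B"))
  perm <- tbl
  perm$subject <- match(perm$subject, sample(unique(perm$subject)))
  expect_equal(mixed_anova(perm, c("A", "B"))$F, base$F, tolerance = 1e-10)
  flip <- tbl
  flip$A <- ifelse(flip$A == "hi", "zlo", "ahi")
  expect_equal(mixed_anova(flip, c("A", "B"))$F, base$F, tolerance = 1e-10)
})

test_that("unbalanced or malformed tables are rejected", {
  tbl <- make_balanced_table(6, c("A", "B"), seed = 1)
  expect_error(mixed_anova(tbl[-1, ], c("A", "B")), "unbalanced")
  tbl3 <- tbl; tbl3$A[tbl3$A == "hi"][1:3] <- "mid"
  expect_error(mixed_anova(tbl3, "A"), "exactly 2 levels")
  tblN <- tbl; tblN$response[1] <- NA
  expect_error(mixed_anova(tblN, c("A", "B")), "finite")
})

test_that("wilcoxon post-hoc matches exact enumeration and handles errors", {
  # n = 6, all differences positive: one-sided exact p = 1/2^6
  a <- c(2.0, 3.1, 1.7, 4.2, 2.8, 3.3)
  b <- a - c(0.5, 0.2, 0.9, 0.1, 0.6, 0.3)
  expect_equal(wilcoxon_posthoc(a, b, alternative = "greater"), 1 / 64)
  expect_error(wilcoxon_posthoc(a, a), "all paired differences are zero")
  expect_error(wilcoxon_posthoc(1:3, 3:1), "length")
})

test_that("wilcoxon type-I error is calibrated", {
  set.seed(14)
  rej <- vapply(1:1000, function(i) {
    d <- rnorm(12)
    wilcoxon_posthoc(d, rep(0, 12)) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("volume-learning correlation recovers a planted partial correlation", {
  rs <- oracle <- numeric(300)
  for (i in 1:300) {
    rec <- simulate_volume_records(18, partial_r = 0.6, seed = i)
    out <- volume_learning_correlation(rec)
    rs[i] <- out$r[out$complexity == "complex"]
    # brute-force partial correlation oracle: residualize both variables
    rh <- resid(lm(hg_voxels ~ total_gm_voxels, rec))
    rl <- resid(lm(learning_complex ~ total_gm_voxels, rec))
    oracle[i] <- cor(rh, rl)
  }
  expect_lt(abs(mean(rs) - mean(oracle)), 0.1)
  expect_lt(abs(mean(rs) - 0.6), 0.1)
})

test_that("independent learning indices give near-zero mean correlation", {
  rs <- vapply(1:300, function(i) {
    rec <- simulate_volume_records(18, partial_r = 0.6, seed = 5000 + i)
    out <- volume_learning_correlation(rec)
    out$r[out$complexity == "simple"]   # simple index is independent
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("degenerate volume records fail loudly", {
  rec <- simulate_volume_records(10, seed = 1)
  rec$hg_voxels <- 0.01 * rec$total_gm_voxels   # exactly proportional
  expect_error(volume_learning_correlation(rec), "collinear")
  rec2 <- simulate_volume_records(10, seed = 2)
  rec2$total_gm_voxels <- 100
  expect_error(volume_learning_correlation(rec2), "constant")
  expect_error(volume_learning_correlation(simulate_volume_records(3)),
               "at least 4")
})
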