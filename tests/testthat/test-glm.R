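test_that("design matrix column count follows the stated construction", {
  d <- full_design(seed = 1)
  n_scans <- ceiling(threatmvpa:::design_run_length(d) / 2.5)
  nuis <- matrix(rnorm(n_scans * 2), ncol = 2)
  X <- build_design_matrix(d, n_scans, tr = 2.5, nuisance = nuis)
  n_dct <- floor(2 * n_scans * 2.5 / 128)
  expect_equal(ncol(X$matrix), 192 + 1 + n_dct + 1 + 2)
  expect_equal(sum(grepl("^trial:", X$column_roles)), 192)
  expect_equal(sum(X$column_roles == "US"), 1)
  expect_equal(sum(grepl("^dct:", X$column_roles)), n_dct)
  expect_equal(sum(grepl("^nuisance:", X$column_roles)), 2)
  # DCT columns are mutually orthogonal
  D <- X$matrix[, grepl("^dct:", X$column_roles)]
  G <- crossprod(D)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("an empty US regressor is dropped with a warning", {
  d <- generate_design(design_params(n_blocks = 2L, reinforcement_rate = 0),
                       seed = 1)
  n_scans <- ceiling(threatmvpa:::design_run_length(d) / 2.5)
  expect_warning(X <- build_design_matrix(d, n_scans), "US regressor dropped")
  expect_false("US" %in% X$column_roles)
})

test_that("small-instance betas equal the normal-equations oracle", {
  d <- manual_design(onsets = c(5, 15, 28))
  suppressWarnings(X <- build_design_matrix(d, n_scans = 20, tr = 2.5))
  set.seed(31)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  bs <- estimate_betas(Y, X)
  M <- X$matrix
  oracle <- solve(crossprod(M), crossprod(M, Y))   # brute-force normal equations
  expect_lt(max(abs(bs$betas - oracle[1:3, ])), 1e-6)
})

test_that("noise-free planted amplitudes 0,1,2 are recovered", {
  d <- manual_design(onsets = c(10, 26, 40))
  suppressWarnings(X <- build_design_matrix(d, n_scans = 40, tr = 2.5))
  R <- X$matrix[, 1:3]
  Y <- cbind(R %*% c(0, 1, 2), R %*% c(2, 1, 0)) + 5   # intercept absorbs 5
  bs <- estimate_betas(Y, X)
  expect_equal(bs$betas, cbind(c(0, 1, 2), c(2, 1, 0)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a constant regressor on a constant signal returns the constant", {
  d <- manual_design(onsets = 5)
  suppressWarnings(X <- build_design_matrix(d, n_scans = 16, tr = 2.5))
  # overwrite the trial column with ones and drop the intercept collision by
  # using a plain matrix fit instead: beta for a ones regressor on signal c
  M <- matrix(1, 16, 1)
  qrM <- qr(M)
  expect_equal(drop(qr.coef(qrM, rep(4.2, 16))), 4.2)
  # and through the public path: constant signal has zero trial response
  bs <- estimate_betas(matrix(4.2, 16, 1), X)
  expect_lt(abs(bs$betas[1, 1]), 1e-10)
})

test_that("OLS residuals are orthogonal to all design columns", {
  d <- small_design(seed = 8)
  n_scans <- ceiling(threatmvpa:::design_run_length(d) / 2.5)
  X <- build_design_matrix(d, n_scans)
  set.seed(77)
  Y <- scale(matrix(rnorm(n_scans * 3), n_scans, 3))
  bs <- estimate_betas(Y, X)
  M <- X$matrix
  full <- qr.coef(qr(M), Y)
  r <- Y - M %*% full
  expect_lt(max(abs(crossprod(M, r))), 1e-6)
})

test_that("betas are equivariant to voxel scaling", {
  d <- manual_design(onsets = c(8, 22))
  suppressWarnings(X <- build_design_matrix(d, n_scans = 24, tr = 2.5))
  set.seed(5)
  y <- rnorm(24)
  b1 <- estimate_betas(cbind(y), X)$betas
  b2 <- estimate_betas(cbind(3.7 * y), X)$betas
  expect_equal(b2, 3.7 * b1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the high-pass basis is inert without drift and removes drift bias", {
  d <- small_design(seed = 3)
  n_scans <- ceiling(threatmvpa:::design_run_length(d) / 2.5)
  X_hp <- build_design_matrix(d, n_scans, highpass_cutoff = 128)
  X_no <- build_design_matrix(d, n_scans, highpass_cutoff = Inf)
  expect_equal(sum(grepl("^dct:", X_no$column_roles)), 0)
  tcols <- 1:48
  amps <- rep(1, 48)
  sig <- X_hp$matrix[, tcols] %*% amps
  # drift-free, noise-free: adding DCT columns leaves trial betas unchanged
  b_hp <- estimate_betas(cbind(sig), X_hp)$betas
  b_no <- estimate_betas(cbind(sig), X_no)$betas
  expect_lt(max(abs(b_hp - b_no)), 1e-6)
  # planted slow sinusoidal drift: filtered bias < 10% of unfiltered bias
  t_scan <- (seq_len(n_scans) - 0.5) * 2.5
  set.seed(12)
  bias_hp <- bias_no <- numeric(50)
  for (s in 1:50) {
    drift <- 2 * sin(2 * pi * t_scan / 300 + runif(1, 0, 2 * pi))
    y <- sig + drift
    bias_hp[s] <- mean(abs(estimate_betas(cbind(y), X_hp)$betas - amps))
    bias_no[s] <- mean(abs(estimate_betas(cbind(y), X_no)$betas - amps))
  }
  expect_lt(mean(bias_hp), 0.1 * mean(bias_no))
})

test_that("degenerate designs are rejected with named columns", {
  d <- manual_design(onsets = c(10, 10))  # exactly collinear trial columns
  expect_error(suppressWarnings(build_design_matrix(d, n_scans = 20)),
               "degenerate design")
  d2 <- manual_design(onsets = c(5, 18))
  suppressWarnings(X <- build_design_matrix(d2, n_scans = 20))
  X$matrix <- cbind(X$matrix, X$matrix[, "intercept"])
  X$column_roles <- c(X$column_roles, "nuisance:dup")
  expect_error(estimate_betas(matrix(rnorm(20), 20, 1), X), "nuisance:dup")
})

test_that("dimension mismatches and empty masks fail loudly", {
  d <- manual_design(onsets = 5)
  suppressWarnings(X <- build_design_matrix(d, n_scans = 16, tr = 2.5))
  expect_error(estimate_betas(matrix(0, 10, 1), X), "time points")
  expect_error(build_design_matrix(d, n_scans = 2, tr = 2.5), "cover")
  sp <- effect_spec(grid_dim = c(8, 8, 8))
  b <- simulate_bold(manual_design(onsets = 5), sp, seed = 1)
  X2 <- suppressWarnings(build_design_matrix(manual_design(onsets = 5),
                                             dim(b$data)[4]))
  expect_error(estimate_betas(b, X2, mask = array(0, c(8, 8, 8))),
               "no voxels")
})
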