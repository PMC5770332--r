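#' Factorial mixed-effects ANOVA with containment degrees of freedom
#'
#' Fits `response ~ full factorial fixed effects + (1 | subject)` on a
#' long-format table of 2-level within-subject factors and returns an F
#' table with containment denominator degrees of freedom
#' `df_den = N_obs - n_subjects - p_within`, where `p_within` is the
#' number of non-intercept fixed-effect parameters (`2^k - 1` for `k`
#' two-level factors).  With one observation per cell this equals the
#' classical pooled-error repeated-measures ANOVA and is computed in
#' closed form; with several observations per cell the model is fit by
#' maximum likelihood (lme4) and each single-df effect is tested by a
#' Wald F with the same containment rule.  For the published designs this
#' reproduces the printed denominators exactly: 119 for the 2x2x2 decoding
#' model with 18 subjects, 51 for the 2x2 model, and 2665 for the
#' trial-level arousal model (16 subjects x 168 trials).
#'
#' @param tbl long-format data frame.
#' @param factors character vector of factor column names (each with
#'   exactly 2 levels).
#' @param subject name of the subject column (default `"subject"`).
#' @param response name of the response column (default `"response"`).
#' @return an `f_table` data frame: `effect`, `df_num`, `df_den`, `F`, `p`.
#' @export
mixed_anova <- function(tbl, factors, subject = "subject",
                        response = "response") {
  stopifnot(is.data.frame(tbl), all(c(factors, subject, response) %in% names(tbl)))
  if (anyNA(tbl[[response]]) || any(!is.finite(tbl[[response]])))
    stop("responses must be finite")
  tbl <- tbl[, c(subject, factors, response)]
  names(tbl) <- c(".subject", factors, ".y")
  tbl$.subject <- factor(tbl$.subject)
  for (f in factors) {
    tbl[[f]] <- factor(tbl[[f]])
    if (nlevels(tbl[[f]]) != 2)
      stop("factor '", f, "' must have exactly 2 levels")
  }
  # every subject must contribute every cell, with equal counts per cell
  counts <- table(tbl[c(".subject", factors)])
  if (any(counts == 0)) {
    rep_tab <- as.data.frame(counts)
    stop("unbalanced table: empty subject x cell combinations\n",
         paste(utils::capture.output(print(head(rep_tab[rep_tab$Freq == 0, ], 10))),
               collapse = "\n"))
  }
  n_subj <- nlevels(tbl$.subject)
  N <- nrow(tbl)
  k <- length(factors)
  p_within <- 2^k - 1L
  df_den <- N - n_subj - p_within
  fixed <- paste(factors, collapse = " * ")
  contr <- stats::setNames(rep(list("contr.sum"), k), factors)

  one_per_cell <- all(counts == 1)
  if (one_per_cell) {
    # closed form: pooled-error repeated-measures ANOVA (the random-
    # intercept mixed model coincides with this in the balanced case)
    fml <- as.formula(paste(".y ~ .subject +", fixed))
    fit <- lm(fml, data = tbl, contrasts = c(list(.subject = "contr.sum"), contr))
    av <- anova(fit)
    eff <- setdiff(rownames(av), c(".subject", "Residuals"))
    stopifnot(av["Residuals", "Df"] == df_den)
    out <- data.frame(effect = gsub(":", " x ", eff),
                      df_num = av[eff, "Df"],
                      df_den = df_den,
                      F = av[eff, "F value"],
                      p = av[eff, "Pr(>F)"])
  } else {
    if (!all(counts == counts[1]))
      warning("unequal cell counts; Wald F tests from the ML fit are approximate")
    fml <- as.formula(paste(".y ~", fixed, "+ (1 | .subject)"))
    fit <- lme4::lmer(fml, data = tbl, REML = FALSE,
                      contrasts = contr,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    b <- lme4::fixef(fit)[-1]
    V <- as.matrix(vcov(fit))[-1, -1, drop = FALSE]
    Fv <- b^2 / diag(V)
    eff <- names(b)
    # map coefficient names (factor1, with sum contrasts) back to effects
    for (f in factors) eff <- gsub(paste0(f, "1"), f, eff, fixed = TRUE)
    out <- data.frame(effect = gsub(":", " x ", eff),
                      df_num = 1L, df_den = df_den, F = unname(Fv),
                      p = unname(pf(Fv, 1, df_den, lower.tail = FALSE)))
  }
  rownames(out) <- NULL
  class(out) <- c("f_table", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank post-hoc test
#'
#' Exact null distribution for n (non-zero differences) up to 25, normal
#' approximation with tie correction otherwise.
#'
#' @param a,b paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (of `a - b`).
#' @return the p-value.
#' @export
wilcoxon_posthoc <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero: statistic undefined")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- wilcox.test(d, alternative = alternative, exact = exact,
                     correct = !exact)
  unname(res$p.value)
}

#' Anatomy-corrected volume/learning correlation
#'
#' Residualizes the Heschl's gyrus voxel count on the total gray matter
#' voxel count (least squares with intercept) and correlates the
#' residuals with the complexity-specific fear learning index (Pearson,
#' two-sided).
#'
#' @param records data frame with columns `hg_voxels`, `total_gm_voxels`
#'   and one learning-index column per complexity (default
#'   `learning_simple`, `learning_complex`).
#' @param learning_cols named character vector mapping complexity to
#'   column name.
#' @return data frame: `complexity`, `r`, `p`, `n`.
#' @export
volume_learning_correlation <- function(records,
                                        learning_cols = c(simple = "learning_simple",
                                                          complex = "learning_complex")) {
  stopifnot(is.data.frame(records),
            all(c("hg_voxels", "total_gm_voxels", learning_cols) %in% names(records)))
  if (nrow(records) < 4) stop("need at least 4 subjects")
  if (var(records$total_gm_voxels) == 0 || var(records$hg_voxels) == 0)
    stop("constant volume predictor")
  res <- resid(lm(hg_voxels ~ total_gm_voxels, data = records))
  if (sd(res) < 1e-8 * sd(records$hg_voxels))
    stop("HG volume is collinear with total gray matter volume; residual correlation undefined")
  rows <- lapply(names(learning_cols), function(cp) {
    ct <- cor.test(res, records[[learning_cols[[cp]]]])
    data.frame(complexity = cp, r = unname(ct$estimate),
               p = ct$p.value, n = nrow(records))
  })
  do.call(rbind, rows)
}

#' Simulate subject volume records with a planted partial correlation
#'
#' Generates native-space bilateral HG and total gray matter voxel
#' counts (HG scaling with total volume plus independent anatomical
#' variability) and learning indices correlated with the
#' volume-independent HG component at level `partial_r`.
#'
#' @param n_subjects number of subjects.
#' @param partial_r planted correlation between the residual HG volume
#'   and the complex-sound learning index.
#' @param seed RNG seed.
#' @return data frame usable by [volume_learning_correlation()].
#' @export
simulate_volume_records <- function(n_subjects = 18L, partial_r = 0.6,
                                    seed = 1L) {
  stopifnot(abs(partial_r) <= 1)
  with_seed(seed, {
    gm <- rnorm(n_subjects, 5e5, 5e4)        # total gray matter voxels
    hg_resid <- rnorm(n_subjects)            # volume-independent HG component
    hg <- round(3000 + 0.002 * gm + 300 * hg_resid)
    mk_learning <- function(r) {
      z <- scale(hg_resid)[, 1]
      r * z + sqrt(1 - r^2) * rnorm(n_subjects)
    }
    data.frame(subject = seq_len(n_subjects), hg_voxels = hg,
               total_gm_voxels = round(gm),
               learning_simple = mk_learning(0),
               learning_complex = mk_learning(partial_r))
  })
}
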