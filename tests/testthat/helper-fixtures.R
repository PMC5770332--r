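# Shared fixtures, all generated in code.

# the published design (192 trials)
full_design <- function(seed = 1) generate_design(design_params(), seed = seed)

# 2-block design (48 trials, 6 per stimulus) for fast GLM/SCR tests
small_design <- function(seed = 1) {
  generate_design(design_params(n_blocks = 2L), seed = seed)
}

# hand-built design object for single/few-trial oracles
manual_design <- function(onsets, role = "CS-", complexity = "simple",
                          context = "neutral", reinforced = FALSE,
                          duration = 4, params = design_params()) {
  n <- length(onsets)
  trials <- data.frame(
    trial_index = seq_len(n), onset = onsets, duration = duration,
    stimulus_id = rep_len(if (role[1] == "CS-") 2L else 1L, n),
    role = rep_len(role, n), complexity = rep_len(complexity, n),
    context = rep_len(context, n),
    reinforced = rep_len(reinforced, n),
    response_key = "left", block_index = 1L, miniblock_index = 1L,
    stringsAsFactors = FALSE)
  structure(list(params = params, trials = trials),
            class = "experiment_design")
}

# iid standard-normal features with a shuffled 12:24 label vector
null_condition_features <- function(n_minority = 12, n_majority = 24,
                                    p = 64, seed = 1) {
  with_seed2(seed, {
    lab <- sample(c(rep("A", n_minority), rep("B", n_majority)))
    list(values = matrix(rnorm((n_minority + n_majority) * p), ncol = p),
         labels = lab)
  })
}

# planted-pattern features: minority class shifted by amp * unit pattern
planted_condition_features <- function(amp, n_minority = 12, n_majority = 24,
                                       p = 64, seed = 1, pattern_seed = 99) {
  u <- with_seed2(pattern_seed, { v <- rnorm(p); v / sqrt(sum(v^2)) })
  f <- null_condition_features(n_minority, n_majority, p, seed)
  sel <- f$labels == "A"
  f$values[sel, ] <- f$values[sel, , drop = FALSE] +
    matrix(amp * u, sum(sel), p, byrow = TRUE)
  f
}

# local RNG scope for test fixtures (mirror of the package-internal helper)
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
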