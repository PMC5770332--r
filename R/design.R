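#' Parameters of the factorial threat-conditioning design
#'
#' The experiment crosses context (reinforced vs. neutral, signalled by a
#' background cue) with sound complexity (simple vs. complex), with two
#' stimuli per cell: `CS+`/`CS-` in the reinforced context and `NS1`/`NS2`
#' in the neutral context.  The run is organised into blocks of two
#' miniblocks; each miniblock presents one stimulus pair only.  Defaults
#' reproduce the published design: 8 blocks x 2 miniblocks x 12 trials,
#' 4 s sounds, inter-trial intervals drawn from \{7, 9, 11\} s, and 50% of
#' `CS+` trials reinforced by the aversive stimulation (US).
#'
#' @param n_blocks number of blocks (default 8).
#' @param miniblocks_per_block miniblocks per block (default 2).
#' @param trials_per_miniblock trials per miniblock (default 12); must be
#'   even so both members of the stimulus pair occur equally often.
#' @param n_stimuli number of distinct stimuli (default 8 = 2 contexts x
#'   2 complexities x 2 pair members).
#' @param stim_duration sound duration in seconds (default 4).
#' @param iti_set set of possible inter-trial intervals in seconds
#'   (default `c(7, 9, 11)`).
#' @param reinforcement_rate fraction of `CS+` trials that co-terminate
#'   with the US (default 0.5).
#' @param block_padding lead-in/lead-out padding per block in seconds
#'   (default 10 each); with the default trial timing this reproduces the
#'   published average block duration of ~332 s.
#' @return an object of class `design_params`.
#' @export
design_params <- function(n_blocks = 8L, miniblocks_per_block = 2L,
                          trials_per_miniblock = 12L, n_stimuli = 8L,
                          stim_duration = 4, iti_set = c(7, 9, 11),
                          reinforcement_rate = 0.5, block_padding = 10) {
  stopifnot_scalar_count(n_blocks, "n_blocks")
  stopifnot_scalar_count(miniblocks_per_block, "miniblocks_per_block")
  stopifnot_scalar_count(trials_per_miniblock, "trials_per_miniblock")
  stopifnot_scalar_count(n_stimuli, "n_stimuli")
  if (n_stimuli != 8L)
    stop("the factorial design requires n_stimuli = 8 (2 contexts x 2 complexities x 2 stimuli)")
  if (trials_per_miniblock %% 2L != 0L)
    stop("trials_per_miniblock must be even: both stimuli of a pair must appear equally often within a miniblock")
  if (length(iti_set) < 1) stop("iti_set must be non-empty")
  if (any(iti_set <= 0)) stop("inter-trial intervals must be positive")
  if (reinforcement_rate < 0 || reinforcement_rate > 1)
    stop("reinforcement_rate must lie in [0, 1]")
  if (stim_duration <= 0) stop("stim_duration must be positive")
  structure(list(
    n_blocks = as.integer(n_blocks),
    miniblocks_per_block = as.integer(miniblocks_per_block),
    trials_per_miniblock = as.integer(trials_per_miniblock),
    n_stimuli = as.integer(n_stimuli),
    stim_duration = stim_duration,
    iti_set = iti_set,
    reinforcement_rate = reinforcement_rate,
    block_padding = block_padding
  ), class = "design_params")
}

# Fixed stimulus table.  Pair members share the motor response across
# complexity ("left" for CS+/NS1-like members, "right" for the others), so
# the neutral key-matched cross-classification control is well defined.
stimulus_table <- function() {
  data.frame(
    stimulus_id = 1:8,
    context = rep(c("reinforced", "neutral"), each = 4),
    complexity = rep(rep(c("simple", "complex"), each = 2), 2),
    role = c("CS+", "CS-", "CS+", "CS-", "NS1", "NS2", "NS1", "NS2"),
    response_key = rep(c("left", "right"), 4),
    stringsAsFactors = FALSE
  )
}

#' Generate a randomized threat-conditioning experiment design
#'
#' Blocks alternate context; within each block the two miniblocks present
#' the simple and the complex pair of that context, in an order that
#' alternates across that context's blocks (starting order randomized).
#' Trial order within a miniblock is randomized with both pair members
#' appearing equally often.  Reinforced `CS+` trials (US delivery) are
#' selected uniformly at random among each `CS+` stimulus's trials.
#'
#' @param params a [design_params()] object.
#' @param seed integer RNG seed; the design is a pure function of
#'   `(params, seed)`.
#' @return an object of class `experiment_design` with elements `params`
#'   and `trials` (a data frame of ordered trial events with onsets in
#'   seconds from run start).
#' @examples
#' d <- generate_design(design_params(), seed = 1)
#' table(d$trials$stimulus_id)  # 24 each
#' @export
generate_design <- function(params = design_params(), seed = 1L) {
  stopifnot(inherits(params, "design_params"))
  with_seed(seed, {
    stab <- stimulus_table()
    n_mb <- params$n_blocks * params$miniblocks_per_block
    # context per block: alternating, random start
    ctx_levels <- c("reinforced", "neutral")
    start_ctx <- sample(ctx_levels, 1)
    block_ctx <- rep(c(start_ctx, setdiff(ctx_levels, start_ctx)),
                     length.out = params$n_blocks)
    # complexity order alternates across blocks of the same context
    start_cpx <- sample(c("simple", "complex"), 2)  # per-context start order
    names(start_cpx) <- ctx_levels
    ctx_block_counter <- c(reinforced = 0L, neutral = 0L)

    rows <- vector("list", n_mb)
    t_cur <- 0
    mb_global <- 0L
    for (b in seq_len(params$n_blocks)) {
      ctx <- block_ctx[b]
      ctx_block_counter[ctx] <- ctx_block_counter[ctx] + 1L
      first_cpx <- if (ctx_block_counter[ctx] %% 2L == 1L)
        start_cpx[ctx] else setdiff(c("simple", "complex"), start_cpx[ctx])
      cpx_order <- rep(c(first_cpx, setdiff(c("simple", "complex"), first_cpx)),
                       length.out = params$miniblocks_per_block)
      t_cur <- t_cur + params$block_padding  # lead-in
      for (m in seq_len(params$miniblocks_per_block)) {
        mb_global <- mb_global + 1L
        pair <- stab[stab$context == ctx & stab$complexity == cpx_order[m], ]
        ids <- sample(rep(pair$stimulus_id, params$trials_per_miniblock / 2L))
        onsets <- numeric(length(ids))
        for (k in seq_along(ids)) {
          onsets[k] <- t_cur
          t_cur <- t_cur + params$stim_duration +
            iti_draw(params$iti_set)
        }
        rows[[mb_global]] <- data.frame(
          onset = onsets,
          duration = params$stim_duration,
          stimulus_id = ids,
          block_index = b,
          miniblock_index = mb_global,
          stringsAsFactors = FALSE
        )
      }
      t_cur <- t_cur + params$block_padding  # lead-out
    }
    trials <- do.call(rbind, rows)
    trials <- merge(trials, stab, by = "stimulus_id", sort = FALSE)
    trials <- trials[order(trials$onset), ]
    trials$trial_index <- seq_len(nrow(trials))
    # reinforcement: uniform among each CS+ stimulus's trials
    trials$reinforced <- FALSE
    for (sid in stab$stimulus_id[stab$role == "CS+"]) {
      idx <- which(trials$stimulus_id == sid)
      n_reinf <- round(params$reinforcement_rate * length(idx))
      if (n_reinf > 0)
        trials$reinforced[sample(idx, n_reinf)] <- TRUE
    }
    rownames(trials) <- NULL
    cols <- c("trial_index", "onset", "duration", "stimulus_id", "role",
              "complexity", "context", "reinforced", "response_key",
              "block_index", "miniblock_index")
    structure(list(params = params, trials = trials[, cols]),
              class = "experiment_design")
  })
}

# single ITI draw; sample() misbehaves with length-1 numeric sets
iti_draw <- function(iti_set) {
  if (length(iti_set) == 1L) iti_set else sample(iti_set, 1)
}

#' @export
print.experiment_design <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<experiment_design> %d trials, %d blocks, run length %.1f s\n",
              nrow(tr), x$params$n_blocks, design_run_length(x)))
  cat(sprintf("  reinforced trials: %d/%d CS+\n",
              sum(tr$reinforced), sum(tr$role == "CS+")))
  invisible(x)
}

# run length in seconds: last trial offset + block lead-out
design_run_length <- function(design) {
  tr <- design$trials
  max(tr$onset + tr$duration) + design$params$block_padding
}

#' Write / read a BIDS-style events table
#'
#' Columns: `onset`, `duration`, `trial_type` (the role), `stimulus_id`,
#' `context`, `complexity`, `reinforced`, `response_key`.
#'
#' @param design an `experiment_design`.
#' @param path file path of the tab-separated events file.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a trial data frame in the package's internal layout.
#' @export
write_events_tsv <- function(design, path) {
  tr <- design$trials
  out <- data.frame(
    onset = tr$onset, duration = tr$duration, trial_type = tr$role,
    stimulus_id = tr$stimulus_id, context = tr$context,
    complexity = tr$complexity,
    reinforced = tolower(as.character(tr$reinforced)),
    response_key = tr$response_key
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "stimulus_id", "context",
            "complexity", "reinforced", "response_key")
  missing <- setdiff(need, names(ev))
  if (length(missing))
    stop("events file lacks columns: ", paste(missing, collapse = ", "))
  data.frame(
    trial_index = seq_len(nrow(ev)),
    onset = ev$onset, duration = ev$duration,
    stimulus_id = ev$stimulus_id, role = ev$trial_type,
    complexity = ev$complexity, context = ev$context,
    reinforced = as.logical(toupper(ev$reinforced)),
    response_key = ev$response_key,
    stringsAsFactors = FALSE
  )
}
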