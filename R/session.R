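#' Simulate one complete recording session
#'
#' Builds the trial schedule, draws behavioral choices and rewards, and
#' generates binned spike counts for every neuron, all from the current RNG
#' state (call `set.seed()` beforehand for reproducibility).
#'
#' @param cfg A [paradigm_config()].
#' @param behavior A [behavior_profile()].
#' @param neurons List of [neuron_profile()] objects (possibly empty).
#' @param profile A [stimulus_profile()].
#' @param grid A [time_grid()].
#' @param session_id,monkey_id Identifiers carried into result tables.
#' @return An object of class `recal_session`: a list with `trials` (trial
#'   table), `spikes` (named list of trials-x-bins count matrices), `grid`,
#'   `config`, and the generative `behavior` and `neurons` (ground truth,
#'   used by recovery tests).
#' @export
simulate_session <- function(cfg = paradigm_config(),
                             behavior = default_behavior(),
                             neurons = list(),
                             profile = stimulus_profile(),
                             grid = time_grid(),
                             session_id = "s01",
                             monkey_id = "m1") {
  trials <- build_trial_schedule(cfg)
  trials <- simulate_choices(trials, cfg, behavior)
  spikes <- lapply(neurons, simulate_spike_counts,
                   trials = trials, profile = profile, grid = grid)
  if (length(spikes)) {
    names(spikes) <- sprintf("n%02d", seq_along(spikes))
  }
  structure(list(session_id = session_id, monkey_id = monkey_id,
                 trials = trials, spikes = spikes, grid = grid,
                 config = cfg, behavior = behavior, neurons = neurons),
            class = "recal_session")
}

#' @export
print.recal_session <- function(x, ...) {
  cat(sprintf("Recalibration session %s (monkey %s): %d trials, %d neurons\n",
              x$session_id, x$monkey_id, nrow(x$trials), length(x$spikes)))
  print(table(block = x$trials$block, modality = x$trials$modality))
  invisible(x)
}

# single-cue trials of one cue in one block, with that cue's heading
single_cue_trials <- function(session, cue, block) {
  tr <- session$trials
  keep <- tr$block == block & tr$modality == cue
  tr[keep, , drop = FALSE]
}
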