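#' Behavioral analysis of one session
#'
#' Fits per-cue psychometric functions to the single-cue trials of the pre
#' and post blocks (combined-cue post trials are excluded: they exist to
#' maintain recalibration, not to measure it) and returns the PSE shifts.
#'
#' @param session A `recal_session`.
#' @param lapse,lapse_value Passed to [fit_psychometric()]; the same
#'   treatment is applied pre and post.
#' @return Data.frame, one row per cue: PSEs, thresholds, shift,
#'   convergence flags, session/monkey ids and the delta sign.
#' @export
analyze_behavior <- function(session, lapse = c("fixed", "free"),
                             lapse_value = 0) {
  lapse <- match.arg(lapse)
  delta_sign <- sign(session$config$delta_max_deg)
  out <- lapply(c("vestibular", "visual"), function(cue) {
    fits <- lapply(c("pre", "post"), function(blk) {
      tr <- single_cue_trials(session, cue, blk)
      fit_psychometric(tr$heading_deg, tr$choice, lapse = lapse,
                       lapse_value = lapse_value)
    })
    data.frame(session_id = session$session_id,
               monkey_id = session$monkey_id,
               cue = cue, delta_sign = delta_sign,
               pse_pre_deg = fits[[1]]$pse_deg,
               pse_post_deg = fits[[2]]$pse_deg,
               shift_deg = pse_shift(fits[[1]], fits[[2]]),
               threshold_pre_deg = fits[[1]]$threshold_deg,
               threshold_post_deg = fits[[2]]$threshold_deg,
               converged = fits[[1]]$converged && fits[[2]]$converged)
  })
  do.call(rbind, out)
}

#' Neuronal shift analysis of one session
#'
#' For every neuron and cue: tuning regressions (baseline-subtracted rates)
#' pre and post, reference-anchored neurometric fits (raw rates, pre-block
#' reference, preferred side fixed from the pre-block tuning slope),
#' bootstrap PSE reliability, the inclusion screen, and the neuronal PSE
#' shift for neurons that pass. Bootstrap SDs are only computed for neurons
#' that meet the tuning criterion (others cannot pass the screen).
#'
#' @param session A `recal_session`.
#' @param B Bootstrap resamples for the PSE reliability screen.
#' @param window Firing-rate window (s), default the stimulus interval.
#' @return Data.frame, one row per neuron x cue.
#' @export
analyze_neurons <- function(session, B = 200, window = c(0, 1)) {
  if (!length(session$spikes)) {
    return(data.frame())
  }
  tr <- session$trials
  delta_sign <- sign(session$config$delta_max_deg)
  out <- list()
  for (id in names(session$spikes)) {
    rates <- trial_firing_rates(session$spikes[[id]], session$grid,
                                tr$block, window = window)
    for (cue in c("vestibular", "visual")) {
      pre <- tr$block == "pre" & tr$modality == cue
      post <- tr$block == "post" & tr$modality == cue
      h <- if (cue == "vestibular") tr$vest_heading_deg else tr$vis_heading_deg
      tun_pre <- tuning_regression(rates$fr_bsub_hz[pre], h[pre])
      tun_post <- tuning_regression(rates$fr_bsub_hz[post], h[post])
      tuned <- tun_pre$p_value < 0.05 || tun_post$p_value < 0.05
      ref <- reference_stats(rates$fr_hz[pre])
      side <- tun_pre$preferred_side
      fit_pre <- fit_neurometric(rates$fr_hz[pre], h[pre], ref, side)
      fit_post <- fit_neurometric(rates$fr_hz[post], h[post], ref, side)
      if (tuned) {
        sd_pre <- bootstrap_pse_sd(rates$fr_hz[pre], h[pre], ref, side, B = B)
        sd_post <- if (is.finite(sd_pre) && sd_pre < 10) {
          bootstrap_pse_sd(rates$fr_hz[post], h[post], ref, side, B = B)
        } else Inf
      } else {
        sd_pre <- sd_post <- NA_real_
      }
      scr <- screen_neuron(tun_pre, tun_post, sd_pre, sd_post)
      out[[paste(id, cue)]] <- data.frame(
        session_id = session$session_id, monkey_id = session$monkey_id,
        neuron_id = id, cue = cue, delta_sign = delta_sign,
        slope_pre = tun_pre$slope_hz_per_deg, p_pre = tun_pre$p_value,
        slope_post = tun_post$slope_hz_per_deg, p_post = tun_post$p_value,
        preferred_side = side,
        pse_pre_deg = fit_pre$pse_deg, pse_post_deg = fit_post$pse_deg,
        bootstrap_sd_pre = sd_pre, bootstrap_sd_post = sd_post,
        passed = scr$passed,
        neuronal_shift_deg = if (scr$passed) {
          neuronal_shift(fit_pre, fit_post, scr)
        } else NA_real_,
        baseline_pre_hz = unname(rates$baseline_hz["pre"]),
        baseline_post_hz = unname(rates$baseline_hz["post"]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choice/heading decomposition of one session
#'
#' Partial correlations of stimulus-window firing rates with heading and
#' choice, per neuron, cue and block (raw rates; single-cue trials only).
#'
#' @param session A `recal_session`.
#' @return Data.frame, one row per neuron x cue x block.
#' @export
analyze_choice <- function(session) {
  if (!length(session$spikes)) return(data.frame())
  tr <- session$trials
  out <- list()
  for (id in names(session$spikes)) {
    rates <- trial_firing_rates(session$spikes[[id]], session$grid, tr$block)
    for (cue in c("vestibular", "visual")) {
      for (blk in c("pre", "post")) {
        i <- tr$block == blk & tr$modality == cue
        pc <- partial_correlations(rates$fr_hz[i], tr$heading_deg[i],
                                   tr$choice[i])
        out[[paste(id, cue, blk)]] <- data.frame(
          session_id = session$session_id, neuron_id = id,
          cue = cue, block = blk,
          r_h = pc$r_h, r_c = pc$r_c, p_h = pc$p_h, p_c = pc$p_c,
          r_h2 = pc$r_h2, r_c2 = pc$r_c2, n_trials = pc$n_trials,
          flag = pc$flag)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-level report
#'
#' Combines per-session behavioral shifts and per-neuron shift records into
#' the group statistics: per-cue neuronal-perceptual Pearson correlations
#' (screened neurons only), the pooled-versus-mixed-model comparison when
#' several monkeys contribute, and the pre/post comparison of partial
#' correlations and baseline rates when available.
#'
#' @param behavior Row-bound [analyze_behavior()] outputs.
#' @param neurons Row-bound [analyze_neurons()] outputs.
#' @param partials Optional row-bound [analyze_choice()] outputs.
#' @return List with `correlations` (data.frame per cue), `behavior`
#'   ([behavioral_summary()] output), `mixed_model` (per cue, or NULL),
#'   `partials_tests`, `baseline_test`, and `shift_records` (the merged
#'   per-neuron table).
#' @export
group_report <- function(behavior, neurons, partials = NULL) {
  if (is.null(neurons) || !nrow(neurons)) {
    neurons <- data.frame(session_id = character(), monkey_id = character(),
                          neuron_id = character(), cue = character(),
                          neuronal_shift_deg = numeric(), passed = logical())
  }
  records <- merge(
    neurons,
    behavior[, c("session_id", "cue", "shift_deg")],
    by = c("session_id", "cue"))
  names(records)[names(records) == "shift_deg"] <- "perceptual_shift_deg"

  correlations <- do.call(rbind, lapply(c("vestibular", "visual"),
    function(cue) {
      d <- records[records$cue == cue & records$passed, ]
      if (nrow(d) < 3) {
        return(data.frame(cue = cue, r = NA_real_, p = NA_real_,
                          n = nrow(d)))
      }
      ct <- neuronal_perceptual_correlation(d)
      data.frame(cue = cue, r = ct$r, p = ct$p, n = ct$n)
    }))

  beh_sum <- tryCatch(behavioral_summary(behavior), error = function(e) NULL)

  mm <- lapply(c(vestibular = "vestibular", visual = "visual"),
    function(cue) {
      d <- records[records$cue == cue & records$passed, ]
      tryCatch(mixed_model_comparison(d), error = function(e) NULL)
    })

  pt <- if (!is.null(partials) && nrow(partials)) {
    partials$neuron_id <- paste(partials$session_id, partials$neuron_id)
    tryCatch(compare_pre_post_partials(partials), error = function(e) NULL)
  } else NULL

  bt <- if (nrow(neurons) &&
            all(c("baseline_pre_hz", "baseline_post_hz") %in% names(neurons))) {
    per_neuron <- unique(neurons[, c("session_id", "neuron_id",
                                     "baseline_pre_hz", "baseline_post_hz")])
    tryCatch(baseline_fr_comparison(per_neuron$baseline_pre_hz,
                                    per_neuron$baseline_post_hz),
             error = function(e) NULL)
  } else NULL

  list(correlations = correlations, behavior = beh_sum, mixed_model = mm,
       partials_tests = pt, baseline_test = bt, shift_records = records)
}

#' Default experiment configuration
#'
#' Describes a batch of simulated sessions: the paradigm, the base behavior
#' (per discrepancy orientation), the area profile and population size, and
#' analysis settings. Sessions alternate between delta+ and delta- and are
#' assigned to monkeys round-robin.
#'
#' @param n_sessions Number of sessions.
#' @param area Area profile for [make_area_population()].
#' @param neurons_per_session Neurons recorded per session.
#' @param n_monkeys Number of (synthetic) monkeys.
#' @param delta_signs Discrepancy orientations cycled over sessions.
#' @param bootstrap_B Resamples for the reliability screen.
#' @param paradigm A [paradigm_config()] (its `delta_max_deg` magnitude is
#'   reused with the per-session sign).
#' @param shift_vest_deg,shift_vis_deg,sigma_vest_deg,sigma_vis_deg,lapse,w_vest
#'   Base behavior for a delta+ session (see [default_behavior()]).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_sessions = 10,
                              area = "MSTd-like",
                              neurons_per_session = 1,
                              n_monkeys = 2,
                              delta_signs = c(1, -1),
                              bootstrap_B = 100,
                              paradigm = paradigm_config(),
                              shift_vest_deg = 1.5,
                              shift_vis_deg = -0.9,
                              sigma_vest_deg = 4,
                              sigma_vis_deg = 3,
                              lapse = 0.01,
                              w_vest = 0.6) {
  structure(list(n_sessions = n_sessions, area = area,
                 neurons_per_session = neurons_per_session,
                 n_monkeys = n_monkeys, delta_signs = delta_signs,
                 bootstrap_B = bootstrap_B, paradigm = paradigm,
                 shift_vest_deg = shift_vest_deg,
                 shift_vis_deg = shift_vis_deg,
                 sigma_vest_deg = sigma_vest_deg,
                 sigma_vis_deg = sigma_vis_deg,
                 lapse = lapse, w_vest = w_vest),
            class = "experiment_config")
}

# simulate one session of an experiment batch (k = session index)
simulate_experiment_session <- function(config, k) {
  ds <- config$delta_signs[((k - 1) %% length(config$delta_signs)) + 1]
  cfg <- config$paradigm
  cfg$delta_max_deg <- ds * abs(cfg$delta_max_deg)
  base <- default_behavior(delta_sign = ds,
                           shift_vest_deg = config$shift_vest_deg,
                           shift_vis_deg = config$shift_vis_deg,
                           sigma_vest_deg = config$sigma_vest_deg,
                           sigma_vis_deg = config$sigma_vis_deg,
                           lapse = config$lapse, w_vest = config$w_vest)
  beh <- sample_session_behavior(base)
  neurons <- if (config$neurons_per_session > 0) {
    make_area_population(config$area, config$neurons_per_session, beh)
  } else list()
  simulate_session(cfg, beh, neurons,
                   session_id = sprintf("s%03d", k),
                   monkey_id = sprintf("m%d", ((k - 1) %% config$n_monkeys) + 1))
}

#' Run a full simulated experiment end to end
#'
#' Simulates `config$n_sessions` sessions, runs the behavioral, neuronal
#' and choice analyses on each, computes the group report, writes all
#' result tables (`behavior_shifts.csv`, `neuron_shifts.csv`,
#' `partials.csv`, `group_stats.csv`) plus a `manifest.json` to `out_dir`,
#' and returns the results invisibly. The root seed is fanned out to one
#' child seed per session plus one per analysis stage, so identical
#' (config, seed) pairs give byte-identical result tables.
#'
#' @param config An [experiment_config()].
#' @param seed Integer root seed.
#' @param out_dir Output directory.
#' @return (Invisibly) list with `behavior`, `neurons`, `partials`,
#'   `report`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1,
                           out_dir = tempfile("recalibr_run_")) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, config$n_sessions)
  message("simulate + analyze: ", config$n_sessions, " sessions (",
          config$area, ")")
  behavior <- list(); neurons <- list(); partials <- list()
  for (k in seq_len(config$n_sessions)) {
    set.seed(child[k])
    ses <- simulate_experiment_session(config, k)
    behavior[[k]] <- analyze_behavior(ses)
    neurons[[k]] <- analyze_neurons(ses, B = config$bootstrap_B)
    partials[[k]] <- analyze_choice(ses)
  }
  behavior <- do.call(rbind, behavior)
  neurons <- do.call(rbind, neurons)
  partials <- do.call(rbind, partials)
  n_pass <- sum(neurons$passed)
  message("screened neuron-cue records: ", n_pass, " passed / ",
          nrow(neurons), " total")
  report <- group_report(behavior, neurons, partials)

  group_stats <- report$correlations
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_results(list(behavior_shifts = behavior,
                              neuron_shifts = neurons,
                              partials = partials,
                              group_stats = group_stats), out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("recalibr")),
    seed = seed,
    config_hash = config_hash(config),
    files = lapply(as.list(files), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(behavior = behavior, neurons = neurons,
                 partials = partials, report = report,
                 manifest = manifest, out_dir = out_dir))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
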