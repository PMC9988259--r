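#' Write a session to delimited text files
#'
#' Persists a [simulate_session()] result as diff-able, language-neutral
#' files in `path`: `trials.csv` (one row per trial), `spikes.csv` (long
#' format: `neuron_id, trial_id, bin_start_s, count`) and `meta.json`
#' (schema version, time grid, paradigm configuration, and the generative
#' ground truth). Counts are written losslessly; floats at full precision.
#'
#' @param session A `recal_session`.
#' @param path Directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recal_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tf <- file.path(path, "trials.csv")
  utils::write.csv(session$trials[, trials_columns()], tf, row.names = FALSE)

  long <- do.call(rbind, lapply(names(session$spikes), function(id) {
    counts <- session$spikes[[id]]
    data.frame(neuron_id = id,
               trial_id = rep(session$trials$trial_id, ncol(counts)),
               bin_start_s = rep(session$grid$bin_start_s,
                                 each = nrow(counts)),
               count = as.vector(counts))
  }))
  sf <- file.path(path, "spikes.csv")
  if (is.null(long)) {
    long <- data.frame(neuron_id = character(), trial_id = integer(),
                       bin_start_s = numeric(), count = numeric())
  }
  utils::write.csv(long, sf, row.names = FALSE)

  meta <- list(schema_version = "1",
               session_id = session$session_id,
               monkey_id = session$monkey_id,
               grid = session$grid[c("start_s", "end_s", "bin_width_s")],
               config = to_jsonable(unclass(session$config)),
               behavior = to_jsonable(unclass(session$behavior)),
               neurons = lapply(session$neurons,
                                function(np) to_jsonable(unclass(np))))
  mf <- file.path(path, "meta.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tf, sf, mf))
}

trials_columns <- function() {
  c("trial_id", "block", "modality", "heading_deg", "vest_heading_deg",
    "vis_heading_deg", "delta_deg", "reward_rule", "choice", "rewarded")
}

#' Read a session written by [write_session()]
#'
#' Validates the schema strictly: required columns, closed vocabularies for
#' `block`/`modality`/`choice`, finite headings, and a complete identical
#' time grid for every (neuron, trial). Violations raise an error naming the
#' offending field.
#'
#' @param path Directory containing `trials.csv`, `spikes.csv`, `meta.json`.
#' @return A `recal_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("schema error: meta.json missing")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (is.null(meta$schema_version)) {
    stop("schema error: schema_version missing from meta.json")
  }

  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  missing <- setdiff(trials_columns(), names(trials))
  if (length(missing)) {
    stop("schema error: missing trial column(s): ",
         paste(missing, collapse = ", "))
  }
  check_vocab <- function(x, field, vocab, allow_na = FALSE) {
    bad <- !(x %in% vocab) & !(allow_na & is.na(x))
    if (any(bad)) stop("schema error: invalid value in ", field)
  }
  check_vocab(trials$block, "block", c("pre", "recal", "post"))
  check_vocab(trials$modality, "modality",
              c("vestibular", "visual", "combined"))
  check_vocab(trials$choice, "choice", c("left", "right", "none"))
  if (any(!is.finite(trials$heading_deg))) {
    stop("schema error: non-finite heading_deg")
  }
  for (col in c("heading_deg", "vest_heading_deg", "vis_heading_deg",
                "delta_deg")) {
    trials[[col]] <- as.numeric(trials[[col]])
  }
  trials$trial_id <- as.integer(trials$trial_id)

  grid <- time_grid(meta$grid$start_s, meta$grid$end_s, meta$grid$bin_width_s)
  spikes_long <- utils::read.csv(file.path(path, "spikes.csv"),
                                 stringsAsFactors = FALSE)
  for (col in c("neuron_id", "trial_id", "bin_start_s", "count")) {
    if (!col %in% names(spikes_long)) {
      stop("schema error: missing spike column: ", col)
    }
  }
  if (any(spikes_long$count < 0)) stop("schema error: negative count")
  nb <- length(grid$bin_start_s)
  nt <- nrow(trials)
  spikes <- lapply(split(spikes_long, spikes_long$neuron_id), function(d) {
    if (nrow(d) != nb * nt) {
      stop("schema error: ragged spike grid for neuron_id ", d$neuron_id[1])
    }
    d <- d[order(d$bin_start_s, d$trial_id), ]
    if (!isTRUE(all.equal(unique(d$bin_start_s), grid$bin_start_s,
                          tolerance = 1e-9))) {
      stop("schema error: bin_start_s grid mismatch for neuron_id ",
           d$neuron_id[1])
    }
    matrix(d$count, nrow = nt, ncol = nb)
  })
  spikes <- spikes[order(names(spikes))]

  cfg <- do.call(paradigm_config, meta$config)
  beh <- do.call(behavior_profile, restore_profile(meta$behavior))
  neurons <- lapply(meta$neurons, function(np) {
    do.call(neuron_profile, restore_profile(np))
  })
  structure(list(session_id = meta$session_id, monkey_id = meta$monkey_id,
                 trials = trials, spikes = spikes, grid = grid,
                 config = cfg, behavior = beh, neurons = neurons),
            class = "recal_session")
}

# JSON objects (not arrays) are needed to keep the pre/post and per-cue
# names of profile fields; named atomic vectors become named lists on write
to_jsonable <- function(x) {
  if (is.list(x)) return(lapply(x, to_jsonable))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

# jsonlite round-trips named vectors c(pre=, post=) as lists; restore them
restore_profile <- function(x) {
  lapply(x, function(el) {
    if (is.list(el) && all(c("pre", "post") %in% names(el)) &&
        all(vapply(el, is.numeric, logical(1)))) {
      return(unlist(el))
    }
    if (is.list(el) && length(el) &&
        all(vapply(el, function(e) is.list(e) || is.numeric(e), logical(1))) &&
        !is.null(names(el))) {
      inner <- lapply(el, function(e) if (is.list(e)) unlist(e) else e)
      if (all(vapply(inner, is.numeric, logical(1)))) {
        if (all(vapply(inner, length, integer(1)) == 1)) return(unlist(el))
        return(inner)
      }
    }
    el
  })
}

#' Write named result tables as CSV files
#'
#' One UTF-8, "."-decimal CSV per table, with headers and deterministic
#' column order.
#'
#' @param tables Named list of data.frames; names must be unique.
#' @param path Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_results <- function(tables, path) {
  if (is.null(names(tables)) || any(names(tables) == "") ||
      anyDuplicated(names(tables))) {
    stop("tables must have unique non-empty names")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(names(tables), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    f
  }, character(1))
  invisible(files)
}
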