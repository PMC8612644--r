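#' Face categories used throughout the package
#'
#' Four familiar-face subcategories plus unfamiliar faces.
#' @export
face_categories <- c("cinema", "music", "politics", "sport", "unfamiliar")

familiar_categories <- function() face_categories[face_categories != "unfamiliar"]

#' Generate event-related experimental designs
#'
#' Builds one design per functional run of a fast event-related experiment:
#' 40 stimulus trials per run (8 repetitions of each of 5 face categories,
#' random order), each trial consisting of a 1 s face event, 1 s blank, a 1 s
#' letter event, and 1 s blank (4 s total). Between 35 and 39 null trials of
#' 0-10 s (drawn on the 2 s repetition-time grid) are interleaved uniformly at
#' random; the first 10 s and the last 4 s of every run are null. Each
#' category's 8 trials in a run carry identity labels 1..8 in random order.
#'
#' @param n_runs Number of runs (>= 1).
#' @param seed Integer seed; identical seeds give identical designs.
#' @param trial_params Optional list overriding defaults:
#'   `trials_per_category` (8), `stimulus_duration` (4 s), `event_duration`
#'   (1 s), `null_range` (c(35, 39) trials), `null_durations` (allowed null
#'   lengths, s), `lead_in` (10 s), `lead_out` (4 s), `tr` (2 s).
#' @return An object of class `experiment_design`: a list with `events`
#'   (tibble: run, onset, duration, category, identity, event_kind, trial),
#'   `nulls` (tibble: run, onset, duration, kind — individual null trials
#'   plus the enforced lead-in/lead-out rows), `run_duration` (per-run
#'   seconds), `n_runs`, and `tr`.
#' @examples
#' d <- generate_design(n_runs = 2, seed = 1)
#' dplyr::count(dplyr::filter(d$events, event_kind == "face"), run)
#' @export
generate_design <- function(n_runs, seed, trial_params = list()) {
  stopifnot_scalar_number(n_runs, "n_runs", min = 1)
  p <- utils::modifyList(list(
    trials_per_category = 8L,
    stimulus_duration = 4,
    event_duration = 1,
    null_range = c(35L, 39L),
    null_durations = seq(0, 10, by = 2),
    lead_in = 10,
    lead_out = 4,
    tr = 2
  ), trial_params)
  if (p$stimulus_duration <= 0 || p$event_duration <= 0 ||
      any(p$null_durations < 0) || p$lead_in < 0 || p$lead_out < 0) {
    stop("trial_params durations must be non-negative (event durations positive)",
         call. = FALSE)
  }
  if (any(p$null_durations > 10)) {
    stop("null trial durations must lie in [0, 10] s", call. = FALSE)
  }

  runs <- lapply(seq_len(n_runs), function(r) {
    with_seed(sub_seed(seed, r), {
      cats <- sample(rep(face_categories, each = p$trials_per_category))
      ids <- integer(length(cats))
      for (cat in face_categories) {
        ids[cats == cat] <- sample(seq_len(p$trials_per_category))
      }
      n_trials <- length(cats)
      n_null <- sample(seq(p$null_range[1], p$null_range[2]), 1L)
      null_dur <- sample(p$null_durations, n_null, replace = TRUE)
      # slot s in 0..n_trials: nulls placed before trial s+1 (slot 0 after
      # the lead-in, slot n_trials before the lead-out); several null trials
      # may share a slot and are laid out consecutively
      slots <- sample(0:n_trials, n_null, replace = TRUE)
      null_before <- vapply(seq_len(n_trials + 1L) - 1L, function(s) {
        sum(null_dur[slots == s])
      }, numeric(1))

      onset <- numeric(n_trials)
      t_cur <- p$lead_in + null_before[1]
      for (i in seq_len(n_trials)) {
        onset[i] <- t_cur
        t_cur <- t_cur + p$stimulus_duration + null_before[i + 1L]
      }
      run_duration <- t_cur + p$lead_out

      # individual null-trial onsets within each slot's gap
      slot_start <- c(p$lead_in, onset + p$stimulus_duration)
      null_onset <- numeric(n_null)
      for (s in unique(slots)) {
        in_slot <- which(slots == s)
        null_onset[in_slot] <-
          slot_start[s + 1L] + cumsum(c(0, null_dur[in_slot]))[seq_along(in_slot)]
      }

      events <- tibble::tibble(
        run = r,
        trial = rep(seq_len(n_trials), each = 2L),
        onset = as.vector(rbind(onset, onset + 2 * p$event_duration)),
        duration = p$event_duration,
        category = rep(cats, each = 2L),
        identity = rep(ids, each = 2L),
        event_kind = rep(c("face", "letter"), n_trials)
      )
      # individual null trials (durations each within [0, 10] s); the
      # enforced 10 s lead-in and 4 s lead-out are separate boundary rows
      ord <- order(null_onset)
      nulls <- tibble::tibble(
        run = r,
        onset = c(0, null_onset[ord], run_duration - p$lead_out),
        duration = c(p$lead_in, null_dur[ord], p$lead_out),
        kind = c("lead_in", rep("null_trial", n_null), "lead_out")
      )
      list(events = events, nulls = nulls, run_duration = run_duration)
    })
  })

  out <- list(
    events = dplyr::bind_rows(lapply(runs, `[[`, "events")),
    nulls = dplyr::bind_rows(lapply(runs, `[[`, "nulls")),
    run_duration = vapply(runs, `[[`, numeric(1), "run_duration"),
    n_runs = as.integer(n_runs),
    tr = p$tr,
    trial_params = p,
    seed = seed
  )
  class(out) <- "experiment_design"
  out
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d run(s), %d stimulus trials/run, TR = %g s\n",
    x$n_runs, sum(x$events$run == 1 & x$events$event_kind == "face"), x$tr
  ))
  cat(sprintf("  run durations: %s s\n",
              paste(format(x$run_duration), collapse = ", ")))
  invisible(x)
}

#' Write / read BIDS-dialect event tables
#'
#' One tab-separated file per design (all runs stacked), columns `onset`,
#' `duration`, `trial_type`, plus `run` and `identity` as extra columns.
#' `trial_type` is `<category>` for face events and `letter` for letter
#' events.
#'
#' @param design An `experiment_design`.
#' @param path Output TSV path.
#' @return `path`, invisibly. `read_events()` returns the events tibble.
#' @export
write_events <- function(design, path) {
  ev <- design$events
  out <- tibble::tibble(
    onset = ev$onset,
    duration = ev$duration,
    trial_type = ifelse(ev$event_kind == "face", ev$category, "letter"),
    run = ev$run,
    identity = ev$identity
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
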