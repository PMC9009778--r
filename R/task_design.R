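#' Build a pseudo-randomised movement-task event schedule
#'
#' Generates the cue schedule of the whole-body movement task. Each body
#' part is cued `repetitions` times within its assigned run-part; the
#' movement order is pseudo-randomised so that no condition is cued twice
#' in a row, and the interval following a cue is `base_iti` seconds except
#' for exactly one randomly chosen repetition per condition, which is
#' followed by `long_iti` seconds. Repetitions are split over
#' `runs_per_part` scanner runs per run-part (first runs take the ceiling
#' share).
#'
#' @param parts A `body_part_set`, see [body_parts()].
#' @param repetitions Number of cues per condition (>= 1).
#' @param base_iti Inter-cue interval in seconds.
#' @param long_iti Lengthened interval in seconds (> `base_iti`), used once
#'   per condition.
#' @param seed Integer seed; the schedule is bit-reproducible for a fixed
#'   seed.
#' @param runs_per_part Number of scanner runs per run-part.
#' @param event_duration Duration in seconds of one cue complex (green cue,
#'   gap, red cue).
#' @param start_offset Onset of the first cue after the start of each run,
#'   seconds.
#' @return An object of class `event_schedule`: a list with `events` (a
#'   data.frame with columns `onset`, `duration`, `trial_type`, `condition`,
#'   `run`, `run_part`, `iti`), the generating parameters and the seed.
#'   `iti` is the interval following each cue; onsets restart at
#'   `start_offset` within each run.
#' @examples
#' sched <- build_event_schedule(body_parts(), repetitions = 9, seed = 1)
#' nrow(sched$events)  # 162
#' @export
build_event_schedule <- function(parts = body_parts(), repetitions = 9L,
                                 base_iti = 10, long_iti = 14.7, seed = 1L,
                                 runs_per_part = 2L, event_duration = 3,
                                 start_offset = 4) {
  stopifnot(inherits(parts, "body_part_set"))
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1L)
    stop("`repetitions` must be >= 1")
  if (!(long_iti > base_iti)) stop("`long_iti` must exceed `base_iti`")
  runs_per_part <- as.integer(runs_per_part)
  if (runs_per_part < 1L) stop("`runs_per_part` must be >= 1")

  run_parts <- sort(unique(parts$run_part))
  rng <- local({set.seed(seed); NULL})
  set.seed(as.integer(seed))

  # one long interval per condition: pick which repetition (1..repetitions)
  long_rep <- stats::setNames(
    vapply(parts$index, function(i) sample.int(repetitions, 1L), integer(1)),
    parts$index)

  events <- list()
  run_id <- 0L
  for (rp in run_parts) {
    conds <- parts$index[parts$run_part == rp]
    # split repetitions over this part's runs: ceiling share first
    base <- repetitions %/% runs_per_part
    extra <- repetitions %% runs_per_part
    reps_by_run <- rep(base, runs_per_part) + c(rep(1L, extra),
                                                rep(0L, runs_per_part - extra))
    rep_counter <- stats::setNames(rep(0L, length(conds)), conds)
    for (r in seq_len(runs_per_part)) {
      run_id <- run_id + 1L
      n_rep <- reps_by_run[r]
      if (n_rep == 0L) next
      order <- shuffle_no_repeat(rep(conds, each = n_rep))
      onset <- start_offset
      for (cond in order) {
        rep_counter[as.character(cond)] <-
          rep_counter[as.character(cond)] + 1L
        iti <- if (rep_counter[as.character(cond)] ==
                   long_rep[as.character(cond)]) long_iti else base_iti
        events[[length(events) + 1L]] <- data.frame(
          onset = onset, duration = event_duration,
          trial_type = parts$label[parts$index == cond],
          condition = cond, run = run_id, run_part = rp, iti = iti,
          stringsAsFactors = FALSE)
        onset <- onset + iti
      }
    }
  }
  ev <- do.call(rbind, events)
  rownames(ev) <- NULL
  structure(list(events = ev, parts = parts, repetitions = repetitions,
                 base_iti = base_iti, long_iti = long_iti,
                 runs_per_part = runs_per_part,
                 event_duration = event_duration,
                 start_offset = start_offset, seed = as.integer(seed)),
            class = "event_schedule")
}

# Uniform shuffles rejected until no element immediately repeats; falls back
# to local swaps if rejection stalls (only relevant for extreme multisets).
shuffle_no_repeat <- function(x, max_tries = 1000L) {
  if (length(unique(x)) <= 1L) return(sample(x))
  for (i in seq_len(max_tries)) {
    s <- sample(x)
    if (!any(s[-1] == s[-length(s)])) return(s)
  }
  # deterministic repair: swap offending element with a later compatible one
  s <- sample(x)
  for (k in which(s[-1] == s[-length(s)])) {
    j <- which(s != s[k] & seq_along(s) > k + 1L &
               c(s[-1], NA)[seq_along(s)] != s[k])
    if (length(j)) {
      tmp <- s[k + 1L]; s[k + 1L] <- s[j[1]]; s[j[1]] <- tmp
    }
  }
  s
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("Movement-task event schedule\n")
  cat(sprintf("  %d events, %d conditions, %d run(s); seed %d\n",
              nrow(x$events), length(unique(x$events$condition)),
              length(unique(x$events$run)), x$seed))
  cat(sprintf("  inter-cue interval %g s (one %g s interval per condition)\n",
              x$base_iti, x$long_iti))
  invisible(x)
}

#' Build the condition-by-volume design matrix
#'
#' Converts an event schedule into the binary stimulus matrix `s` (18
#' conditions x T volumes). A volume is "on" for a condition if its
#' half-open acquisition window `[t, t + tr)` intersects the event window
#' `[onset, onset + boxcar)`. Runs are concatenated in fixed order.
#'
#' @param schedule An `event_schedule`.
#' @param volumes_per_run Integer vector of volume counts, one per run in
#'   the schedule. The standard whole-body protocol uses `c(237, 191, 237, 191)`.
#' @param tr Repetition time in seconds.
#' @param boxcar Regressor duration in seconds from cue onset; use `0` for
#'   impulse regressors (single volume at onset).
#' @return An object of class `design_matrix`: list with `s` (conditions x
#'   T binary matrix with body-part row labels), `tr`, `volumes_per_run`,
#'   `run_starts` (first volume index of each run) and `labels`.
#' @examples
#' sched <- build_event_schedule(seed = 1)
#' dm <- design_matrix(sched, volumes_per_run = c(237, 191, 237, 191))
#' ncol(dm$s)  # 856
#' @export
design_matrix <- function(schedule, volumes_per_run, tr = 2.1, boxcar = 3) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (tr <= 0) stop("`tr` must be positive")
  ev <- schedule$events
  n_runs <- if (nrow(ev)) max(ev$run) else length(volumes_per_run)
  if (length(volumes_per_run) != n_runs)
    stop(sprintf("schedule has %d run(s) but %d volume counts were given",
                 n_runs, length(volumes_per_run)))
  n_cond <- nrow(schedule$parts)
  total_T <- sum(volumes_per_run)
  s <- matrix(0L, n_cond, total_T)
  rownames(s) <- schedule$parts$label
  run_starts <- cumsum(c(1L, utils::head(volumes_per_run, -1L)))
  for (k in seq_len(nrow(ev))) {
    run <- ev$run[k]
    run_dur <- volumes_per_run[run] * tr
    on <- ev$onset[k]
    win <- max(boxcar, 0)
    if (on + win > run_dur || on < 0)
      stop(sprintf(
        "event %d (%s, onset %.1f s) does not fit in run %d (%.1f s)",
        k, ev$trial_type[k], on, run, run_dur))
    if (win > 0) {
      vols <- which((seq_len(volumes_per_run[run]) - 1L) * tr < on + win &
                    seq_len(volumes_per_run[run]) * tr > on)
    } else {
      vols <- floor(on / tr) + 1L
    }
    s[ev$condition[k], run_starts[run] + vols - 1L] <- 1L
  }
  structure(list(s = s, tr = tr, volumes_per_run = as.integer(volumes_per_run),
                 run_starts = run_starts, labels = schedule$parts$label),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d conditions x %d volumes (TR %g s, %d runs)\n",
              nrow(x$s), ncol(x$s), x$tr, length(x$volumes_per_run)))
  invisible(x)
}

#' The whole-body task protocol in one call
#'
#' Convenience constructor for the standard 18-body-part protocol: 9 cues
#' per condition split over two run-parts with two runs each (237 and 191
#' volumes at TR 2.1 s, 856 volumes in total), a 3 s boxcar regressor and
#' the canonical HRF.
#'
#' @param seed Integer seed for the schedule.
#' @param repetitions Cues per condition.
#' @param tr Repetition time, seconds.
#' @param volumes_per_run Volume counts for the four runs.
#' @param boxcar Regressor duration, seconds.
#' @return List with `schedule`, `design` and `hrf`.
#' @examples
#' p <- whole_body_protocol(seed = 1)
#' ncol(p$design$s)  # 856
#' @export
whole_body_protocol <- function(seed = 1L, repetitions = 9L, tr = 2.1,
                                volumes_per_run = c(237L, 191L, 237L, 191L),
                                boxcar = 3) {
  sched <- build_event_schedule(body_parts(), repetitions = repetitions,
                                seed = seed)
  dm <- design_matrix(sched, volumes_per_run = volumes_per_run, tr = tr,
                      boxcar = boxcar)
  list(schedule = sched, design = dm, hrf = canonical_hrf(tr))
}

#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF (difference of two gamma densities: a positive
#' peak and a delayed undershoot) at the repetition time. The kernel is
#' scaled to unit peak so that the fitted amplitude is in percent-signal
#' units.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param duration Kernel length in seconds.
#' @param peak_delay,undershoot_delay Delays of the response peak and
#'   undershoot, seconds.
#' @param peak_disp,undershoot_disp Dispersions of the two gamma components.
#' @param ratio Undershoot-to-peak ratio.
#' @return Object of class `hrf_kernel`: list with `values` (length
#'   `ceiling(duration / tr)`), `tr`, `duration` and the shape parameters.
#' @examples
#' h <- canonical_hrf(tr = 2.1)
#' length(h$values)  # 16
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 1 / 6) {
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be positive")
  n <- max(1L, as.integer(ceiling(duration / tr)))
  t <- (seq_len(n) - 1L) * tr
  v <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  if (max(abs(v)) > 0) v <- v / max(v)
  structure(list(values = v, tr = tr, duration = duration,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               peak_disp = peak_disp,
                               undershoot_disp = undershoot_disp,
                               ratio = ratio)),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("Canonical HRF kernel: %d samples at TR %g s (peak %g s)\n",
              length(x$values), x$tr, x$params$peak_delay))
  invisible(x)
}
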