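# Small fixtures shared across the suite; everything is generated in code.

# a reduced body-part set: n parts, all in one run-part
tiny_parts <- function(n = 4L) {
  body_parts(labels = paste0("part", seq_len(n)), run_part = rep(1L, n))
}

# a small single-run protocol for fast fitting tests; the run is sized to
# hold the schedule plus an HRF tail unless a larger count is requested
tiny_protocol <- function(n_parts = 4L, repetitions = 2L, volumes = NULL,
                          tr = 2, seed = 1L) {
  sched <- build_event_schedule(tiny_parts(n_parts),
                                repetitions = repetitions,
                                base_iti = 6, long_iti = 9, seed = seed,
                                runs_per_part = 1L, start_offset = 2)
  needed <- ceiling((max(sched$events$onset) + 3 + 16) / tr)
  volumes <- if (is.null(volumes)) needed else max(volumes, needed)
  dm <- design_matrix(sched, volumes_per_run = volumes, tr = tr, boxcar = 3)
  list(schedule = sched, design = dm, hrf = canonical_hrf(tr))
}

# a hand-built schedule with explicit onsets (one condition set)
manual_schedule <- function(onsets, conditions, n_parts, run = 1L,
                            duration = 3) {
  parts <- tiny_parts(n_parts)
  k <- length(onsets)
  ev <- data.frame(onset = onsets, duration = rep(duration, k),
                   trial_type = parts$label[conditions],
                   condition = conditions, run = rep(run, k),
                   run_part = rep(1L, k), iti = rep(NA_real_, k))
  structure(list(events = ev, parts = parts, repetitions = NA_integer_,
                 base_iti = NA_real_, long_iti = NA_real_,
                 runs_per_part = 1L, event_duration = duration,
                 start_offset = onsets[1], seed = NA_integer_),
            class = "event_schedule")
}

# random connected weighted graph on n nodes, weights in (0.1, 1)
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.6) {
        wij <- stats::runif(1, 0.1, 1)
        w[i, j] <- w[j, i] <- wij
      }
    }
    # ensure a spanning backbone so the graph is connected
    perm <- sample(n)
    for (k in seq_len(n - 1)) {
      i <- perm[k]; j <- perm[k + 1]
      if (w[i, j] == 0) w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 1)
    }
    if (nrprf:::graph_is_connected(w)) return(w)
  }
}

# two 3-cliques (unit weights) joined by one weak edge
two_clique_graph <- function(bridge = 0.1) {
  w <- matrix(0, 6, 6)
  for (g in list(1:3, 4:6))
    for (i in g) for (j in g) if (i != j) w[i, j] <- 1
  w[3, 4] <- w[4, 3] <- bridge
  w
}
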