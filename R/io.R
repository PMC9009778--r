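#' Prepare raw vertex timeseries for fitting
#'
#' Per run: removes slow drifts with a discrete-cosine high-pass filter
#' (all cosine components below `cutoff`, SPM convention
#' `K = floor(2 * duration * cutoff)` non-constant terms plus the mean),
#' then rescales to percent BOLD signal change around the run mean; runs
#' are concatenated in protocol order.
#'
#' @param runs List of matrices (vertices x volumes), one per run.
#' @param tr Repetition time, seconds.
#' @param cutoff High-pass cutoff frequency, Hz.
#' @return Matrix vertices x total volumes (percent signal change,
#'   mean-free per run).
#' @export
prepare_timeseries <- function(runs, tr, cutoff = 0.01) {
  if (!is.list(runs)) runs <- list(runs)
  nv <- unique(vapply(runs, nrow, integer(1)))
  if (length(nv) != 1) stop("runs must have consistent vertex counts")
  out <- lapply(runs, function(Y) {
    Y <- as.matrix(Y)
    n <- ncol(Y)
    m <- rowMeans(Y)
    if (any(abs(m) < 1e-12))
      stop("zero-mean raw run: percent-change scaling is undefined")
    B <- dct_basis(n, tr, cutoff)
    # residualise each vertex on the low-frequency basis (incl. constant)
    proj <- Y %*% B %*% solve(crossprod(B), t(B))
    100 * (Y - proj) / m
  })
  do.call(cbind, out)
}

dct_basis <- function(n, tr, cutoff) {
  k_max <- floor(2 * n * tr * cutoff)
  t <- seq_len(n) - 0.5
  B <- matrix(1 / sqrt(n), n, 1)
  if (k_max >= 1) {
    for (k in seq_len(k_max))
      B <- cbind(B, sqrt(2 / n) * cos(pi * k * t / n))
  }
  B
}

#' Write / read task events as a tab-separated table
#'
#' BIDS-events-compatible columns: `onset`, `duration`, `trial_type`,
#' `run`, plus `condition`, `run_part` and `iti` so schedules round-trip.
#'
#' @param schedule An `event_schedule`.
#' @param path File path.
#' @return `read_events()` returns the events data.frame.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  utils::write.table(schedule$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read_tsv_checked(path, c("onset", "duration", "trial_type", "run"))
}

#' Write / read a per-vertex fit table
#'
#' Tab-separated, full double precision. `NA` is written explicitly and
#' never silently dropped.
#'
#' @param table Data.frame.
#' @param path File path.
#' @return `read_vertex_table()` returns the data.frame.
#' @export
write_vertex_table <- function(table, path) {
  utils::write.table(format_full_precision(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_vertex_table
#' @export
read_vertex_table <- function(path) {
  read_tsv_checked(path, character(0))
}

format_full_precision <- function(table) {
  as.data.frame(lapply(table, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  out <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      na.strings = "NA", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e))))
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  out
}

#' Write / read a design matrix as a dense tab-separated matrix
#'
#' Conditions are rows; the header row carries the body-part labels.
#'
#' @param design A `design_matrix`.
#' @param path File path.
#' @return `read_design_matrix()` returns the conditions x volumes matrix
#'   (labels as rownames).
#' @export
write_design_matrix <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  m <- t(design$s)
  colnames(m) <- design$labels
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_matrix
#' @export
read_design_matrix <- function(path) {
  m <- as.matrix(read_tsv_checked(path, character(0)))
  t(m)
}

#' Write / read a body graph as an edge list
#'
#' Tab-separated columns `part_a`, `part_b`, `weight` (undirected, each
#' edge once).
#'
#' @param g A `body_graph`.
#' @param path File path.
#' @param labels Node labels for reading.
#' @return `read_edge_list()` returns a symmetric weight matrix.
#' @export
write_edge_list <- function(g, path) {
  w <- as_weight_matrix(g)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(part_a = rownames(w)[idx[, 1]],
                   part_b = colnames(w)[idx[, 2]],
                   weight = sprintf("%.17g", w[idx]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, labels = NULL) {
  df <- read_tsv_checked(path, c("part_a", "part_b", "weight"))
  if (is.null(labels)) labels <- sort(unique(c(df$part_a, df$part_b)))
  w <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_len(nrow(df))) {
    w[df$part_a[k], df$part_b[k]] <- df$weight[k]
    w[df$part_b[k], df$part_a[k]] <- df$weight[k]
  }
  w
}

#' Write a mean response field in long format
#'
#' Columns: `roi`, `center_part`, `part`, `mean_proximity`, `n_vertices`.
#'
#' @param mu A `mean_response_field`.
#' @param path File path.
#' @export
write_mean_field <- function(mu, path) {
  stopifnot(inherits(mu, "mean_response_field"))
  n <- nrow(mu$mu)
  df <- data.frame(
    roi = mu$roi,
    center_part = rep(seq_len(n), each = n),
    part = rep(seq_len(n), n),
    mean_proximity = sprintf("%.17g", as.numeric(t(mu$mu))),
    n_vertices = rep(mu$counts, each = n))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' YAML key-value configuration; unknown keys are rejected on load.
#'
#' @param path File path.
#' @param config Named list.
#' @return `read_config()` returns the validated named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("tr", "dx_max", "boxcar", "fdr_q", "drop_fraction", "seed",
               "repetitions", "base_iti", "long_iti", "volumes_per_run",
               "n_vertices", "subjects", "rois", "noise_sd", "target_r2",
               "beta", "hrf", "paths", "cutoff_hz")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
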