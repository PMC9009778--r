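#' Default ROI tuning profiles for synthetic somatotopic maps
#'
#' Distance slopes (units of dx per homunculus step) controlling how fast
#' body parts fall away from a vertex's preferred part. Steep slopes give
#' small response fields (primary sensorimotor cortex); shallow slopes give
#' large fields (ventral premotor-like areas). ROIs with `size_gradient`
#' interpolate the slope along the strip, emulating the small-to-large size
#' gradients seen in medial and insular areas.
#'
#' @return Data.frame with columns `roi`, `slope`, `size_gradient`.
#' @export
roi_profiles <- function() {
  data.frame(
    roi = c("M1", "S1", "SMA", "PMd", "PMv", "Insula", "iPC", "sPC"),
    slope = c(2.0, 2.0, 1.2, 1.0, 0.5, 1.2, 0.8, 0.8),
    size_gradient = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Generate a somatotopic ground-truth map
#'
#' Lays vertices out on a flattened cortical strip per ROI and subject,
#' with preferred body parts (pRF centres) progressing from 1 (toes) at low
#' y to 18 (tongue) at high y, optional centre jitter, and true distances
#' of non-centre parts increasing with homunculus distance at an ROI-
#' specific slope, plus optional distance noise. Every body-part centre is
#' represented in every ROI (missing centres are back-filled at the
#' vertices whose ideal position is nearest). Deterministic per seed.
#'
#' @param n_vertices Vertices per ROI per subject (>= 18).
#' @param subjects Subject ids.
#' @param profiles ROI profile table, see [roi_profiles()].
#' @param center_jitter SD of the jitter (in body-part index units) added
#'   to the ideal centre progression.
#' @param dx_noise_sd SD of truncated Gaussian noise added to non-centre
#'   distances.
#' @param dx_max Distance bound.
#' @param strip_length Length of the strip in surface units (y axis).
#' @param seed Integer seed.
#' @return Data.frame of class `ground_truth` with one row per vertex:
#'   `subject`, `roi`, `vertex_id`, `x`, `y`, `area`, `true_center`,
#'   `true_size`, `true_dx_1` .. `true_dx_18`; attributes `dx_max`, `seed`.
#' @export
make_somatotopic_ground_truth <- function(n_vertices = 50L,
                                          subjects = 1:2,
                                          profiles = roi_profiles(),
                                          center_jitter = 0,
                                          dx_noise_sd = 0,
                                          dx_max = 10,
                                          strip_length = 100,
                                          seed = 1L) {
  if (n_vertices < 18) stop("need at least 18 vertices per ROI")
  set.seed(as.integer(seed))
  n_parts <- 18L
  rows <- list()
  for (s in subjects) for (k in seq_len(nrow(profiles))) {
    roi <- profiles$roi[k]
    y <- seq(0, strip_length, length.out = n_vertices)
    x <- stats::runif(n_vertices, 0, strip_length / 10)
    ideal <- 1 + (n_parts - 1) * y / strip_length
    ctr <- round(ideal + if (center_jitter > 0)
      stats::rnorm(n_vertices, 0, center_jitter) else 0)
    ctr <- pmin(pmax(ctr, 1L), n_parts)
    # guarantee full centre coverage: back-fill missing parts at the
    # vertices whose ideal position is nearest
    for (p in setdiff(seq_len(n_parts), unique(ctr))) {
      ctr[which.min(abs(ideal - p))] <- p
    }
    slope <- if (profiles$size_gradient[k]) {
      # small fields at low y, large at high y
      profiles$slope[k] * (1.5 - y / strip_length)
    } else rep(profiles$slope[k], n_vertices)
    dx <- matrix(0, n_vertices, n_parts)
    for (v in seq_len(n_vertices)) {
      d <- slope[v] * abs(seq_len(n_parts) - ctr[v])
      if (dx_noise_sd > 0) {
        nz <- d > 0
        d[nz] <- pmax(d[nz] + stats::rnorm(sum(nz), 0, dx_noise_sd), 0.05)
      }
      dx[v, ] <- pmin(d, dx_max)
    }
    size <- apply(dx, 1, prf_size, dx_max = dx_max)
    df <- data.frame(subject = s, roi = roi,
                     vertex_id = seq_len(n_vertices),
                     x = x, y = y,
                     area = stats::runif(n_vertices, 0.5, 1.5),
                     true_center = as.integer(ctr), true_size = size,
                     stringsAsFactors = FALSE)
    dxdf <- as.data.frame(dx)
    names(dxdf) <- paste0("true_dx_", seq_len(n_parts))
    rows[[length(rows) + 1L]] <- cbind(df, dxdf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dx_max") <- dx_max
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ground_truth", "data.frame")
  out
}

true_dx_matrix <- function(truth) {
  cols <- grep("^true_dx_[0-9]+$", names(truth), value = TRUE)
  as.matrix(truth[, cols[order(as.integer(sub("true_dx_", "", cols)))]])
}

#' Simulate vertex BOLD timeseries from a ground-truth map
#'
#' Forward-models every vertex with the non-rigid response field: the true
#' distances give Gaussian weights, the weighted design is convolved with
#' the HRF and scaled by `beta`, and iid Gaussian noise is added. If
#' `target_r2` is given instead of `noise_sd`, the noise level is
#' calibrated by bisection (see [calibrate_noise_sd()]) so the median
#' fitted R2 approximates the target.
#'
#' @param truth A `ground_truth` map.
#' @param design,hrf Design matrix and HRF kernel of the task.
#' @param beta Response amplitude (percent signal per unit prediction).
#' @param noise_sd Noise standard deviation (percent signal); 0 gives
#'   noiseless data.
#' @param target_r2 Optional median fitted R2 to calibrate the noise to.
#' @param seed Integer seed.
#' @return Matrix (vertices x volumes) with attribute `noise_sd`.
#' @export
simulate_vertex_timeseries <- function(truth, design,
                                       hrf = canonical_hrf(design$tr),
                                       beta = 1, noise_sd = 0,
                                       target_r2 = NULL, seed = 1L) {
  X <- conv_design(design, hrf)
  dx <- true_dx_matrix(truth)
  stopifnot(ncol(dx) == ncol(X))
  if (!is.null(target_r2)) {
    noise_sd <- calibrate_noise_sd(truth, design, hrf, target_r2,
                                   beta = beta, seed = seed)
  }
  G <- exp(-dx^2 / 2)
  signal <- G %*% t(X) * beta  # vertices x volumes
  set.seed(as.integer(seed))
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(length(signal), 0, noise_sd), nrow(signal))
  else 0
  out <- signal + noise
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Calibrate the simulation noise level to a target fitted R2
#'
#' Bisection on the noise standard deviation: pilot vertices are simulated
#' and fitted with the non-rigid model, and the median fitted R2 compared
#' with the target. The fitted R2 includes the overfitting inflation of the
#' real pipeline, so the calibration matches the quantity the study
#' reports.
#'
#' @inheritParams simulate_vertex_timeseries
#' @param target_r2 Target median fitted R2 in (0, 1).
#' @param n_pilot Number of pilot vertices per evaluation.
#' @param iterations Bisection iterations.
#' @return Calibrated noise sd.
#' @export
calibrate_noise_sd <- function(truth, design, hrf = canonical_hrf(design$tr),
                               target_r2 = 0.15, beta = 1, n_pilot = 40L,
                               iterations = 12L, seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  X <- conv_design(design, hrf)
  dx <- true_dx_matrix(truth)
  set.seed(as.integer(seed) + 7L)
  pilot <- sample(nrow(dx), min(n_pilot, nrow(dx)))
  G <- exp(-dx[pilot, , drop = FALSE]^2 / 2)
  signal <- G %*% t(X) * beta
  opts <- nrprf_options()
  med_r2 <- function(sd) {
    set.seed(as.integer(seed) + 13L)
    Y <- signal + matrix(stats::rnorm(length(signal), 0, sd), nrow(signal))
    r2 <- vapply(seq_len(nrow(Y)),
                 function(v) fit_nonrigid_core(Y[v, ], X, opts)$r2,
                 numeric(1))
    stats::median(r2)
  }
  lo <- 1e-4
  hi <- stats::sd(as.numeric(signal)) * 2 + 1e-3
  while (med_r2(hi) > target_r2) hi <- hi * 2
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (med_r2(mid) > target_r2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Parameter-recovery report
#'
#' Compares fitted pRF parameters with the generating ground truth:
#' centre accuracy, size bias and RMSE, and mean absolute distance error,
#' overall and per ROI.
#'
#' @param truth A `ground_truth` map.
#' @param fits Per-vertex fit table from [fit_vertices()], same vertex
#'   order (matched on `subject`, `roi`, `vertex_id` when present).
#' @return List with `overall` (one-row data.frame) and `per_roi`.
#' @export
recovery_report <- function(truth, fits) {
  key <- c("subject", "roi", "vertex_id")
  if (all(key %in% names(fits))) {
    m <- merge(truth, fits, by = key, sort = FALSE,
               suffixes = c("_true", "_fit"))
    if (nrow(m) != nrow(truth) || nrow(m) != nrow(fits))
      stop("vertex ids do not match")
  } else {
    if (nrow(fits) != nrow(truth)) stop("vertex tables do not match")
    m <- cbind(truth, fits[, setdiff(names(fits), names(truth)),
                           drop = FALSE])
  }
  dx_true <- true_dx_matrix(m)
  dx_fit <- as.matrix(m[, dx_columns(m), drop = FALSE])
  summarise <- function(idx) {
    data.frame(
      n = length(idx),
      center_accuracy = mean(m$center[idx] == m$true_center[idx]),
      size_bias = mean(m$size[idx] - m$true_size[idx]),
      size_rmse = sqrt(mean((m$size[idx] - m$true_size[idx])^2)),
      dx_mae = mean(abs(dx_fit[idx, , drop = FALSE] -
                          dx_true[idx, , drop = FALSE])))
  }
  per_roi <- do.call(rbind, lapply(unique(m$roi), function(r) {
    cbind(data.frame(roi = r), summarise(which(m$roi == r)))
  }))
  rownames(per_roi) <- NULL
  list(overall = summarise(seq_len(nrow(m))), per_roi = per_roi)
}
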