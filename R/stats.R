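#' Rotate an ROI so the somatotopy points north
#'
#' Rigidly rotates the flattened coordinates of one ROI (and subject) about
#' the ROI centroid so that the vector from the leg-group centroid
#' (vertices whose pRF centre is toes, ankle or knee) to the face-group
#' centroid (lip, jaw or tongue) points along the +y axis. No reflection is
#' applied (rotation determinant +1).
#'
#' @param table Per-vertex fit table with columns `roi`, `x`, `y`, `center`
#'   and optionally `subject`, `selected`.
#' @param roi ROI label.
#' @param subject Optional subject id to restrict to.
#' @param leg_centers,face_centers Body-part indices defining the two
#'   anchor groups.
#' @param selected_only Use only FDR-selected vertices?
#' @return The ROI's rows with added columns `x_rot`, `y_rot`, and the
#'   rotation angle (radians) as attribute `angle`; `NULL` (with a warning)
#'   if either anchor group is empty.
#' @export
rotate_roi <- function(table, roi, subject = NULL, leg_centers = 1:3,
                       face_centers = 16:18, selected_only = TRUE) {
  tab <- table[table$roi == roi, , drop = FALSE]
  if (!is.null(subject) && "subject" %in% names(tab))
    tab <- tab[tab$subject == subject, , drop = FALSE]
  if (selected_only && "selected" %in% names(tab))
    tab <- tab[tab$selected, , drop = FALSE]
  leg <- tab$center %in% leg_centers
  face <- tab$center %in% face_centers
  if (!any(leg) || !any(face)) {
    warning(sprintf("ROI '%s': empty %s group, skipping rotation", roi,
                    if (!any(leg)) "leg" else "face"))
    return(NULL)
  }
  v <- c(mean(tab$x[face]) - mean(tab$x[leg]),
         mean(tab$y[face]) - mean(tab$y[leg]))
  angle <- pi / 2 - atan2(v[2], v[1])
  ctr <- c(mean(tab$x), mean(tab$y))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- t(rot %*% rbind(tab$x - ctr[1], tab$y - ctr[2]))
  tab$x_rot <- xy[, 1] + ctr[1]
  tab$y_rot <- xy[, 2] + ctr[2]
  attr(tab, "angle") <- angle
  tab
}

#' Somatotopy and size gradient test
#'
#' For each ROI, rotates the coordinates per subject (see [rotate_roi()]),
#' regresses the chosen quantity (pRF centre index or pRF size) on the
#' rotated vertical coordinate per subject, and tests the per-subject
#' slopes against zero with a one-sample t-test across subjects. Positive
#' slopes indicate a gradual increase of the quantity from the leg anchor
#' towards the face anchor. The one-sided p-value (slope > 0) is the
#' headline; the two-sided value is also reported.
#'
#' @param table Per-vertex fit table with `subject` column (>= 2 subjects).
#' @param quantity `"center"` or `"size"`.
#' @param rois ROI labels to test; defaults to all in the table.
#' @inheritParams rotate_roi
#' @return Data.frame with one row per ROI: `roi`, `mean_slope`, `t`, `df`,
#'   `p_one_sided`, `p_two_sided`, `n_subjects`; per-subject slopes and
#'   rotation angles as attributes `slopes` and `angles`.
#' @export
gradient_test <- function(table, quantity = c("center", "size"),
                          rois = unique(table$roi), selected_only = TRUE,
                          leg_centers = 1:3, face_centers = 16:18) {
  quantity <- match.arg(quantity)
  if (!"subject" %in% names(table)) stop("`table` must have a subject column")
  subjects <- unique(table$subject)
  if (length(subjects) < 2) stop("gradient test requires >= 2 subjects")
  res <- list()
  all_slopes <- list()
  all_angles <- list()
  for (roi in rois) {
    slopes <- numeric(0)
    angles <- numeric(0)
    for (s in subjects) {
      rt <- rotate_roi(table, roi, subject = s, leg_centers = leg_centers,
                       face_centers = face_centers,
                       selected_only = selected_only)
      if (is.null(rt) || nrow(rt) < 3) next
      qv <- rt[[quantity]]
      if (stats::var(qv) == 0 || stats::var(rt$y_rot) == 0) {
        slopes <- c(slopes, 0)
        angles <- c(angles, attr(rt, "angle"))
        next
      }
      fit <- stats::lm(qv ~ rt$y_rot)
      slopes <- c(slopes, unname(stats::coef(fit)[2]))
      angles <- c(angles, attr(rt, "angle"))
    }
    if (length(slopes) < 2) {
      warning(sprintf("ROI '%s': fewer than 2 usable subjects", roi))
      next
    }
    tt <- stats::t.test(slopes, mu = 0)
    tval <- unname(tt$statistic)
    df <- unname(tt$parameter)
    res[[roi]] <- data.frame(
      roi = roi, mean_slope = mean(slopes), t = tval, df = df,
      p_one_sided = stats::pt(tval, df, lower.tail = FALSE),
      p_two_sided = tt$p.value, n_subjects = length(slopes),
      stringsAsFactors = FALSE)
    all_slopes[[roi]] <- slopes
    all_angles[[roi]] <- angles
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "slopes") <- all_slopes
  attr(out, "angles") <- all_angles
  attr(out, "quantity") <- quantity
  out
}

#' Correlation between two vertex maps
#'
#' Pearson correlation over the vertices that are non-zero in both maps,
#' with `df = N - 2` and the two-sided p-value from the t transform
#' `t = R * sqrt(df / (1 - R^2))`.
#'
#' @param map_a,map_b Numeric vectors on the same vertex index.
#' @return List with `r`, `p_value`, `df`, `n`.
#' @export
map_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("maps must share the vertex index")
  keep <- map_a != 0 & map_b != 0 & is.finite(map_a) & is.finite(map_b)
  n <- sum(keep)
  if (n < 3) stop("fewer than 3 vertices non-zero in both maps")
  r <- stats::cor(map_a[keep], map_b[keep])
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  list(r = r, p_value = p, df = df, n = n)
}

#' Task design-bias test
#'
#' Tests whether fitted body-part distances are artificially coupled by the
#' split of the task over two run-parts. For each selected vertex, the
#' non-centre distances are split by whether the body part was cued in the
#' same run-part as the vertex's pRF centre or in the other run-part; the
#' two pooled distributions are compared with a Welch t-test. Under an
#' unbiased design the two groups have the same distribution.
#'
#' @param table Per-vertex fit table with `center`, `selected` and `dx_*`
#'   columns.
#' @param parts A `body_part_set` giving the run assignment.
#' @param selected_only Use only FDR-selected vertices?
#' @return List with `t`, `df` (Welch-Satterthwaite), `p_value`, and group
#'   means/sizes.
#' @export
design_bias_test <- function(table, parts = body_parts(),
                             selected_only = TRUE) {
  tab <- table
  if (selected_only && "selected" %in% names(tab))
    tab <- tab[tab$selected, , drop = FALSE]
  if (!nrow(tab)) stop("no selected vertices")
  cols <- dx_columns(tab)
  n_parts <- length(cols)
  run_of <- parts$run_part
  same <- numeric(0)
  other <- numeric(0)
  for (v in seq_len(nrow(tab))) {
    ctr <- tab$center[v]
    if (is.na(ctr) || ctr < 1 || ctr > n_parts) next
    dx <- as.numeric(tab[v, cols])
    idx <- setdiff(seq_len(n_parts), ctr)
    grp_same <- idx[run_of[idx] == run_of[ctr]]
    grp_other <- idx[run_of[idx] != run_of[ctr]]
    same <- c(same, dx[grp_same])
    other <- c(other, dx[grp_other])
  }
  if (!length(same) || !length(other))
    stop("one of the run groups is empty")
  if (stats::var(same) == 0 && stats::var(other) == 0 &&
      isTRUE(all.equal(mean(same), mean(other)))) {
    return(list(t = 0, df = length(same) + length(other) - 2, p_value = 1,
                mean_same = mean(same), mean_other = mean(other),
                n_same = length(same), n_other = length(other)))
  }
  tt <- stats::t.test(same, other)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_same = mean(same),
       mean_other = mean(other), n_same = length(same),
       n_other = length(other))
}

#' Head-motion scoring per movement cue
#'
#' Sums the absolute first derivative of the six rigid-body motion
#' parameters over the volumes acquired in the first `window` seconds after
#' each cue; rotations are converted to arc displacement at
#' `rotation_radius` mm. Per condition, a Welch t-test compares that
#' condition's event scores against all other events pooled, flagging cues
#' that cause excess head motion.
#'
#' @param traces List of per-run motion matrices (volumes x 6: three
#'   translations in mm, three rotations in radians), in run order.
#' @param schedule An `event_schedule`.
#' @param tr Repetition time in seconds.
#' @param window Scoring window after cue onset, seconds.
#' @param rotation_radius Radius in mm used to convert rotations to mm.
#' @return List with `events` (condition, run, onset, score per event) and
#'   `conditions` (per-condition mean score, Welch `t`, `df`, `p_value`).
#' @export
head_motion_score <- function(traces, schedule, tr = 2.1, window = 3,
                              rotation_radius = 50) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (!is.list(traces)) traces <- list(traces)
  ev <- schedule$events
  if (max(ev$run) > length(traces))
    stop("one motion trace per run is required")
  if (window < tr)
    warning("scoring window shorter than one TR; using the nearest volume")
  # per-volume displacement: summed |first difference|, rotations scaled
  vol_disp <- lapply(traces, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 6)
    d <- abs(apply(m, 2, function(col) c(0, diff(col))))
    rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius * rowSums(d[, 4:6, drop = FALSE])
  })
  scores <- numeric(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    run <- ev$run[k]
    nv <- length(vol_disp[[run]])
    vol_onsets <- (seq_len(nv) - 1) * tr
    sel <- which(vol_onsets >= ev$onset[k] & vol_onsets < ev$onset[k] + window)
    if (!length(sel))
      sel <- which.min(abs(vol_onsets - ev$onset[k]))
    if (max(sel) > nv) stop("motion trace does not cover all events")
    scores[k] <- sum(vol_disp[[run]][sel])
  }
  conds <- sort(unique(ev$condition))
  cond_res <- lapply(conds, function(cc) {
    own <- scores[ev$condition == cc]
    rest <- scores[ev$condition != cc]
    if (stats::var(scores) == 0) {
      return(data.frame(condition = cc, mean_score = mean(own), t = 0,
                        df = length(scores) - 2, p_value = 1))
    }
    tt <- tryCatch(stats::t.test(own, rest), error = function(e) NULL)
    if (is.null(tt)) {
      # too few events or zero variance in a group: no test possible
      data.frame(condition = cc, mean_score = mean(own), t = NA_real_,
                 df = NA_real_, p_value = NA_real_)
    } else {
      data.frame(condition = cc, mean_score = mean(own),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
    }
  })
  list(events = data.frame(condition = ev$condition, run = ev$run,
                           onset = ev$onset, score = scores),
       conditions = do.call(rbind, cond_res))
}
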