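#' Normalised body-part proximity
#'
#' Converts fitted distances to proximities on `[0, 1]`:
#' `(dx_max - dx) / dx_max`, so 1 marks the response-field centre and 0 the
#' distance bound. In truncated mode (used by the pRF size), parts beyond
#' the half-width-at-half-maximum window are set to zero; the untruncated
#' mode is used for the mean body-part response fields, where distant parts
#' keep graded nonzero proximities.
#'
#' @param dx Vector of distances in `[0, dx_max]`.
#' @param dx_max Distance bound.
#' @param truncated Zero out parts with `dx > FWHM/2`?
#' @param sigma Field standard deviation (sets the FWHM window).
#' @return Vector of proximities in `[0, 1]`.
#' @examples
#' normalized_proximity(c(0, 5, 10))
#' @export
normalized_proximity <- function(dx, dx_max = 10, truncated = FALSE,
                                 sigma = 1) {
  if (any(!is.finite(dx)) || any(dx < 0) || any(dx > dx_max))
    stop("`dx` must lie in [0, dx_max]")
  p <- (dx_max - dx) / dx_max
  if (truncated) p[dx > sigma * sqrt(2 * log(2))] <- 0
  p
}

dx_columns <- function(table) {
  cols <- grep("^dx_[0-9]+$", names(table), value = TRUE)
  cols[order(as.integer(sub("dx_", "", cols)))]
}

#' Mean body-part response field for one ROI
#'
#' For each body part `i` taken as pRF centre, averages the untruncated
#' normalised-proximity profiles of all selected vertices in the ROI whose
#' centre is `i`. With several subjects, the mean is computed per subject
#' and then averaged with equal subject weights; a centre absent for one
#' subject is averaged over the subjects that have it.
#'
#' @param table Per-vertex fit table (see [fit_vertices()]) with columns
#'   `roi`, `center`, `selected`, `dx_1` .. `dx_n` and optionally `subject`.
#' @param roi ROI label to aggregate.
#' @param dx_max Distance bound used during fitting.
#' @param selected_only Use only FDR-selected vertices?
#' @return Object of class `mean_response_field`: list with `roi`, `mu`
#'   (n x n matrix, row = centre body part), `counts` (vertices per row)
#'   and `subjects`.
#' @export
mean_body_part_prf <- function(table, roi, dx_max = 10,
                               selected_only = TRUE) {
  tab <- table[table$roi == roi, , drop = FALSE]
  if (selected_only && "selected" %in% names(tab))
    tab <- tab[tab$selected, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("no vertices for ROI '%s'", roi))
  cols <- dx_columns(tab)
  n <- length(cols)
  subjects <- if ("subject" %in% names(tab)) unique(tab$subject) else 1L
  per_subj <- array(NA_real_, c(length(subjects), n, n))
  counts <- integer(n)
  for (i in seq_len(n)) {
    rows_i <- tab[tab$center == i, , drop = FALSE]
    counts[i] <- nrow(rows_i)
    if (!nrow(rows_i))
      stop(sprintf("ROI '%s' has no vertex with pRF centre %d (%s)",
                   roi, i, body_part_label(table, i)))
    for (s in seq_along(subjects)) {
      rs <- if ("subject" %in% names(rows_i))
        rows_i[rows_i$subject == subjects[s], , drop = FALSE] else rows_i
      if (!nrow(rs)) next
      prox <- t(apply(as.matrix(rs[, cols, drop = FALSE]), 1,
                      normalized_proximity, dx_max = dx_max))
      per_subj[s, i, ] <- colMeans(prox)
    }
  }
  mu <- apply(per_subj, c(2, 3), mean, na.rm = TRUE)
  lbl <- attr(table, "part_labels")
  if (is.null(lbl) || length(lbl) != n) lbl <- cols
  dimnames(mu) <- list(lbl, lbl)
  structure(list(roi = roi, mu = mu, counts = counts, subjects = subjects,
                 dx_max = dx_max),
            class = "mean_response_field")
}

body_part_label <- function(table, i) {
  lbl <- attr(table, "part_labels")
  if (!is.null(lbl) && i <= length(lbl)) lbl[i] else paste("part", i)
}

#' @export
print.mean_response_field <- function(x, ...) {
  cat(sprintf("Mean body-part response field, ROI %s (%d parts)\n",
              x$roi, nrow(x$mu)))
  cat(sprintf("  vertices per centre: %s\n",
              paste(x$counts, collapse = " ")))
  invisible(x)
}

#' Normalised surface area per pRF centre
#'
#' Fraction of an ROI's total vertex surface area carried by vertices
#' preferring each body part.
#'
#' @inheritParams mean_body_part_prf
#' @param n_parts Number of body parts.
#' @return Numeric vector of fractions summing to 1.
#' @export
surface_area_by_center <- function(table, roi, n_parts = 18L,
                                   selected_only = TRUE) {
  tab <- table[table$roi == roi, , drop = FALSE]
  if (selected_only && "selected" %in% names(tab))
    tab <- tab[tab$selected, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("no vertices for ROI '%s'", roi))
  if (any(tab$area <= 0)) stop("vertex areas must be positive")
  total <- sum(tab$area)
  vapply(seq_len(n_parts),
         function(i) sum(tab$area[tab$center == i]) / total, numeric(1))
}

#' Equalise the vertex count per pRF centre
#'
#' Randomly subsamples (without replacement) the selected vertices of an
#' ROI so every body-part centre contributes the same number of vertices:
#' the minimum per-centre count. Used for the equi-representational variant
#' of the graph analysis.
#'
#' @inheritParams mean_body_part_prf
#' @param seed Integer seed; the subsample is reproducible.
#' @return The subsampled rows of `table` for this ROI.
#' @export
equalize_representation <- function(table, roi, seed = 1L,
                                    selected_only = TRUE) {
  tab <- table[table$roi == roi, , drop = FALSE]
  if (selected_only && "selected" %in% names(tab))
    tab <- tab[tab$selected, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("no vertices for ROI '%s'", roi))
  centers <- sort(unique(tab$center))
  n_min <- min(table(tab$center))
  set.seed(as.integer(seed))
  keep <- unlist(lapply(centers, function(i) {
    idx <- which(tab$center == i)
    if (length(idx) == n_min) idx else sample(idx, n_min)
  }))
  out <- tab[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
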