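#' Non-rigid response-field weights
#'
#' Evaluates the static unit Gaussian response field at the fitted body-part
#' distances: `g_i = exp(-dx_i^2 / 2)` (field centre 0, sd 1). A body part
#' at distance 0 sits at the field centre (`g = 1`); at the distance bound
#' `dx_max = 10` the field is numerically zero.
#'
#' @param dx Numeric vector of non-negative body-part distances.
#' @param dx_max Upper bound on distances.
#' @return Vector of response weights in `(0, 1]`.
#' @examples
#' nonrigid_field(c(0, 1, 10))
#' @export
nonrigid_field <- function(dx, dx_max = 10) {
  if (any(!is.finite(dx)) || any(dx < 0) || any(dx > dx_max))
    stop("`dx` must lie in [0, dx_max]")
  exp(-dx^2 / 2)
}

# Per-condition regressors: each design row convolved with the HRF,
# convolution restarted at run boundaries. Returns T x n_cond matrix.
conv_design <- function(design, hrf) {
  stopifnot(inherits(design, "design_matrix"), inherits(hrf, "hrf_kernel"))
  if (!isTRUE(all.equal(design$tr, hrf$tr)))
    stop("design matrix and HRF kernel must share the same TR")
  h <- hrf$values
  n_cond <- nrow(design$s)
  X <- matrix(0, ncol(design$s), n_cond)
  start <- 1L
  for (nv in design$volumes_per_run) {
    idx <- start:(start + nv - 1L)
    for (i in seq_len(n_cond)) {
      r <- design$s[i, idx]
      if (any(r != 0)) {
        full <- stats::convolve(r, rev(h), type = "open")
        X[idx, i] <- full[seq_len(nv)]
      }
    }
    start <- start + nv
  }
  colnames(X) <- design$labels
  X
}

#' Predict a vertex timeseries from response-field weights
#'
#' Forms the effective timeseries `r(t) = sum_i s(x_i, t) g(x_i)` and
#' convolves it with the canonical HRF, restarting the convolution at run
#' boundaries.
#'
#' @param weights Response weight per condition (e.g. [nonrigid_field()]).
#' @param design A `design_matrix`.
#' @param hrf An `hrf_kernel` with the same TR as the design.
#' @return Numeric vector of length T (total volumes).
#' @export
predict_timeseries <- function(weights, design, hrf) {
  X <- conv_design(design, hrf)
  if (length(weights) != ncol(X))
    stop("`weights` must have one entry per condition")
  drop(X %*% weights)
}

#' Fitting options for pRF models
#'
#' @param dx_max Upper bound for the body-part distances (non-rigid model).
#' @param tie_tol Absolute tolerance within which minimal distances are
#'   treated as tied when assigning the pRF centre.
#' @param sigma_bounds Lower/upper bounds for the conventional model width.
#' @param sigma_starts,x0_starts Multi-start grid for the conventional model.
#' @param max_iter Maximum optimiser iterations (conventional model).
#' @param ftol Relative SSE convergence tolerance (conventional model).
#' @return A list of class `nrprf_options`.
#' @export
nrprf_options <- function(dx_max = 10, tie_tol = 1e-6,
                          sigma_bounds = c(0.1, 20),
                          sigma_starts = c(1, 3), x0_starts = 1:18,
                          max_iter = 100L, ftol = 1e-10) {
  stopifnot(dx_max > 0, tie_tol > 0, all(sigma_bounds > 0))
  structure(list(dx_max = dx_max, tie_tol = tie_tol,
                 sigma_bounds = sigma_bounds, sigma_starts = sigma_starts,
                 x0_starts = x0_starts, max_iter = max_iter, ftol = ftol),
            class = "nrprf_options")
}

#' Fit a population response-field model to one vertex timeseries
#'
#' The non-rigid model (default) holds a unit Gaussian response field fixed
#' and fits the distance `dx_i` of every body part to the field centre:
#' `y(t) = beta * (X %*% exp(-dx^2/2)) + e`, with `X` the per-condition
#' HRF-convolved regressors, `dx_i` in `[0, dx_max]` and the amplitude
#' `beta` profiled out by least squares. Because the weights
#' `g = exp(-dx^2/2)` sweep out the full positive orthant `(0, 1]^18` while
#' `beta` is a free scalar, the model's prediction set is exactly the union
#' of the positive and negative linear cones of `X`; the global optimum is
#' therefore obtained by sign-constrained (Lawson-Hanson) least squares and
#' no iterative multi-start search is needed. `beta` and `dx` are jointly
#' identified only up to a scale ridge (the residual depends on `beta * g`
#' alone); the fit is anchored by the convention `max(g) = 1`, i.e. the
#' preferred body part sits exactly at the field centre.
#'
#' The conventional model fits a Gaussian over the rigid homunculus axis
#' (`x_i` = 1..18): `g_i = exp(-(x0 - x_i)^2 / (2 sigma^2))`, with centre
#' `x0` in `[1, 18]` and width `sigma` in `sigma_bounds`, via bounded
#' Levenberg-Marquardt least squares from a multi-start grid.
#'
#' @param y Observed vertex timeseries (percent signal change), length T.
#' @param design A `design_matrix`.
#' @param hrf An `hrf_kernel`; defaults to the canonical HRF at the design's
#'   TR.
#' @param model `"nonrigid"` or `"conventional"`.
#' @param options An [nrprf_options()] list.
#' @return An object of class `nrprf_fit` (and `nonrigid_prf` or
#'   `conventional_prf`): a list with the fitted parameters (`dx`, or `x0`
#'   and `sigma`), `beta`, `center`, `size`, `r2`, `f_stat`, `p_value`,
#'   `sse`, `fitted`, `degenerate` flag and the call inputs needed by the
#'   methods.
#' @examples
#' parts <- body_parts()
#' sched <- build_event_schedule(parts, repetitions = 2, seed = 3)
#' dm <- design_matrix(sched, volumes_per_run = c(64, 52, 64, 52), tr = 2.1)
#' h <- canonical_hrf(2.1)
#' dx <- pmin(2 * abs(1:18 - 7), 10)
#' y <- predict_timeseries(nonrigid_field(dx), dm, h)
#' fit <- nrprf(y, dm, h)
#' fit$center  # 7
#' @export
nrprf <- function(y, design, hrf = canonical_hrf(design$tr),
                  model = c("nonrigid", "conventional"),
                  options = nrprf_options()) {
  model <- match.arg(model)
  X <- conv_design(design, hrf)
  if (length(y) != nrow(X))
    stop(sprintf("timeseries length %d does not match design (%d volumes)",
                 length(y), nrow(X)))
  if (any(!is.finite(y))) stop("`y` must be finite")
  fit <- if (model == "nonrigid") fit_nonrigid_core(y, X, options)
  else fit_conventional_core(y, X, options)
  fit$model <- model
  fit$y <- y
  fit$labels <- design$labels
  class(fit) <- c(if (model == "nonrigid") "nonrigid_prf"
                  else "conventional_prf", "nrprf_fit")
  fit
}

# Global non-rigid fit via sign-constrained least squares on the convolved
# design; see ?nrprf for the reduction argument.
fit_nonrigid_core <- function(y, X, options) {
  n_cond <- ncol(X)
  dx_max <- options$dx_max
  g_floor <- exp(-dx_max^2 / 2)
  if (stats::var(y) == 0 || all(colSums(abs(X)) == 0)) {
    return(degenerate_nonrigid(y, X, options))
  }
  pos <- pracma::lsqnonneg(X, y)
  neg <- pracma::lsqnonneg(X, -y)
  if (pos$resid.norm <= neg$resid.norm) {
    cvec <- pos$x; sign_beta <- 1
    sse <- pos$resid.norm
  } else {
    cvec <- neg$x; sign_beta <- -1
    sse <- neg$resid.norm
  }
  if (max(cvec) <= 0) return(degenerate_nonrigid(y, X, options))
  beta <- sign_beta * max(cvec)
  g <- pmin(pmax(cvec / max(cvec), g_floor), 1)
  dx <- pmin(sqrt(-2 * log(g)), dx_max)
  dx[cvec == 0] <- dx_max
  fitted <- drop(X %*% cvec) * sign_beta
  gof <- goodness_of_fit(y, fitted, n_params = n_cond + 1L)
  list(dx = stats::setNames(dx, colnames(X)), beta = beta,
       center = prf_center(dx, options$tie_tol),
       size = prf_size(dx, dx_max),
       r2 = gof$r2, f_stat = gof$f_stat, p_value = gof$p_value,
       sse = sse, fitted = fitted, degenerate = FALSE,
       negative_beta = sign_beta < 0, options = options)
}

degenerate_nonrigid <- function(y, X, options) {
  n_cond <- ncol(X)
  dx <- rep(options$dx_max, n_cond)
  list(dx = stats::setNames(dx, colnames(X)), beta = 0,
       center = prf_center(dx, options$tie_tol),
       size = prf_size(dx, options$dx_max),
       r2 = 0, f_stat = 0, p_value = 1,
       sse = sum((y - mean(y))^2), fitted = rep(0, length(y)),
       degenerate = TRUE, negative_beta = FALSE, options = options)
}

fit_conventional_core <- function(y, X, options) {
  n_cond <- ncol(X)
  xi <- seq_len(n_cond)
  if (stats::var(y) == 0) {
    return(list(x0 = NA_real_, sigma = NA_real_, beta = 0, center = NA_real_,
                size = NA_real_, r2 = 0, f_stat = 0, p_value = 1,
                sse = sum((y - mean(y))^2), fitted = rep(0, length(y)),
                degenerate = TRUE, negative_beta = FALSE, options = options))
  }
  resid_fn <- function(par) {
    g <- exp(-(par[1] - xi)^2 / (2 * par[2]^2))
    p <- drop(X %*% g)
    denom <- sum(p^2)
    beta <- if (denom > 0) sum(p * y) / denom else 0
    y - beta * p
  }
  lower <- c(1, options$sigma_bounds[1])
  upper <- c(n_cond, options$sigma_bounds[2])
  best <- NULL
  for (s0 in options$sigma_starts) for (x0 in options$x0_starts) {
    # per-start iteration-cap warnings are expected for starts far from
    # the optimum; convergence of the retained solution is flagged instead
    res <- try(withCallingHandlers(
      minpack.lm::nls.lm(
        par = c(x0, s0), lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = options$max_iter, ftol = options$ftol)),
      warning = function(w) invokeRestart("muffleWarning")), silent = TRUE)
    if (inherits(res, "try-error")) next
    sse <- res$deviance
    if (is.null(best) || sse < best$sse)
      best <- list(par = res$par, sse = sse, converged = res$info %in% 1:4)
  }
  if (is.null(best)) stop("conventional pRF fit failed from every start")
  x0 <- best$par[1]; sigma <- best$par[2]
  g <- exp(-(x0 - xi)^2 / (2 * sigma^2))
  p <- drop(X %*% g)
  beta <- sum(p * y) / sum(p^2)
  fitted <- beta * p
  gof <- goodness_of_fit(y, fitted, n_params = 3L)
  list(x0 = x0, sigma = sigma, beta = beta, center = x0, size = sigma,
       r2 = gof$r2, f_stat = gof$f_stat, p_value = gof$p_value,
       sse = best$sse, fitted = fitted, degenerate = FALSE,
       negative_beta = beta < 0, converged = best$converged,
       options = options)
}

#' pRF centre from fitted body-part distances
#'
#' The centre is the index of the body part with the minimal distance to
#' the response-field centre. When several parts tie for the minimum
#' (within `tie_tol`), the centre is the floor of the mean tied index.
#'
#' @param dx Vector of fitted distances.
#' @param tie_tol Absolute tie tolerance.
#' @return Integer body-part index.
#' @examples
#' prf_center(c(3, 0.2, 5, rep(10, 15)))  # 2
#' @export
prf_center <- function(dx, tie_tol = 1e-6) {
  stopifnot(length(dx) >= 1, all(is.finite(dx)))
  tied <- which(dx <= min(dx) + tie_tol)
  if (length(tied) == 1L) tied else as.integer(floor(mean(tied)))
}

#' pRF size from fitted body-part distances
#'
#' The size is the normalised-proximity-weighted count of body parts inside
#' the half-width-at-half-maximum window of the unit Gaussian field:
#' `size = sum_i P(dx_i) * FWHM/2` with
#' `P(d) = (dx_max - d)/dx_max` for `d <= FWHM/2` and 0 beyond, and
#' `FWHM = 2 * sqrt(2 * log(2))` (about 2.355) for sd 1. A population with
#' size about 1 has a single body part in its response field.
#'
#' @param dx Vector of fitted distances.
#' @param dx_max Distance bound used during fitting.
#' @param sigma Standard deviation of the static field (1 in the model).
#' @return Non-negative size scalar.
#' @examples
#' prf_size(c(0, rep(10, 17)))  # ~1.177
#' @export
prf_size <- function(dx, dx_max = 10, sigma = 1) {
  half_fwhm <- sigma * sqrt(2 * log(2))
  p <- normalized_proximity(dx, dx_max = dx_max, truncated = TRUE,
                            sigma = sigma)
  sum(p) * half_fwhm
}

#' Goodness of fit against the zero-signal null
#'
#' Computes the F-statistic of the model prediction against the null of no
#' signal, with hypothesis df equal to the parameter count and error df
#' `T - n_params`. The data are mean-free percent-change timeseries, so no
#' intercept enters the count: the full whole-body protocol (T = 856, 18
#' distances + amplitude) yields df (19, 837). `r2 = 1 - SSE/SStot`.
#'
#' @param y Observed timeseries.
#' @param prediction Model prediction, same length.
#' @param n_params Number of model parameters.
#' @return List with `f_stat`, `p_value`, `r2`, `df` (length-2), `sse` and
#'   a `degenerate` flag (zero total variance).
#' @export
goodness_of_fit <- function(y, prediction, n_params) {
  stopifnot(length(y) == length(prediction), n_params < length(y))
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0)
    return(list(f_stat = 0, p_value = 1, r2 = 0,
                df = c(n_params, length(y) - n_params), sse = 0,
                degenerate = TRUE))
  sse <- sum((y - prediction)^2)
  ss0 <- sum(y^2)
  df1 <- n_params
  df2 <- length(y) - n_params
  f <- ((ss0 - sse) / df1) / (sse / df2)
  list(f_stat = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       r2 = 1 - sse / sstot, df = c(df1, df2), sse = sse,
       degenerate = FALSE)
}

#' Benjamini-Hochberg vertex selection
#'
#' Step-up false-discovery-rate control on per-vertex goodness-of-fit
#' p-values.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical mask of selected vertices.
#' @export
select_vertices <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Fit pRF models to a matrix of vertex timeseries
#'
#' Applies [nrprf()] to every row of a vertices x volumes matrix and
#' assembles the per-vertex table used by the downstream pipeline
#' (aggregation, graphs, statistics).
#'
#' @param Y Matrix, vertices x volumes.
#' @param design,hrf,model,options As in [nrprf()].
#' @param vertex_info Optional data.frame with one row per vertex (e.g.
#'   `vertex_id`, `subject`, `roi`, `x`, `y`, `area`); carried through to
#'   the output.
#' @param fdr_q FDR level for the `selected` flag.
#' @return A data.frame with columns from `vertex_info`, `dx_1` ..
#'   `dx_<n>` (non-rigid) or `x0`/`sigma` (conventional), `beta`, `center`,
#'   `size`, `r2`, `f_stat`, `p_value`, `selected`.
#' @export
fit_vertices <- function(Y, design, hrf = canonical_hrf(design$tr),
                         model = c("nonrigid", "conventional"),
                         options = nrprf_options(), vertex_info = NULL,
                         fdr_q = 0.05) {
  model <- match.arg(model)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- conv_design(design, hrf)
  if (ncol(Y) != nrow(X))
    stop("`Y` must be vertices x volumes matching the design")
  fits <- vector("list", n)
  for (v in seq_len(n)) {
    fits[[v]] <- if (model == "nonrigid")
      fit_nonrigid_core(Y[v, ], X, options)
    else fit_conventional_core(Y[v, ], X, options)
  }
  base <- data.frame(
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    center = vapply(fits, function(f) as.numeric(f$center), numeric(1)),
    size = vapply(fits, function(f) as.numeric(f$size), numeric(1)),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    f_stat = vapply(fits, `[[`, numeric(1), "f_stat"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"))
  if (model == "nonrigid") {
    dxm <- t(vapply(fits, `[[`, numeric(ncol(X)), "dx"))
    colnames(dxm) <- paste0("dx_", seq_len(ncol(X)))
    base <- cbind(as.data.frame(dxm), base)
  } else {
    base <- cbind(data.frame(
      x0 = vapply(fits, `[[`, numeric(1), "x0"),
      sigma = vapply(fits, `[[`, numeric(1), "sigma")), base)
  }
  base$selected <- select_vertices(base$p_value, fdr_q)
  if (!is.null(vertex_info)) {
    stopifnot(nrow(vertex_info) == n)
    base <- cbind(vertex_info, base)
  } else if (is.null(base$vertex_id)) {
    base <- cbind(data.frame(vertex_id = seq_len(n)), base)
  }
  rownames(base) <- NULL
  attr(base, "part_labels") <- design$labels
  base
}

# ---- S3 methods for nrprf_fit ------------------------------------------

#' @export
print.nrprf_fit <- function(x, ...) {
  cat(sprintf("%s pRF fit\n",
              if (x$model == "nonrigid") "Non-rigid" else "Conventional"))
  if (x$degenerate) cat("  degenerate fit (no signal)\n")
  cat(sprintf("  centre: %s (body part %s)   size: %.3f\n",
              format(x$center),
              if (!is.na(x$center) && x$center == round(x$center) &&
                  x$center >= 1 && x$center <= length(x$labels))
                x$labels[round(x$center)] else "-",
              x$size))
  cat(sprintf("  beta: %.4g   R2: %.4f   F: %.4g (p = %.3g)\n",
              x$beta, x$r2, x$f_stat, x$p_value))
  invisible(x)
}

#' @export
coef.nrprf_fit <- function(object, ...) {
  if (object$model == "nonrigid") c(object$dx, beta = object$beta)
  else c(x0 = object$x0, sigma = object$sigma, beta = object$beta)
}

#' @export
fitted.nrprf_fit <- function(object, ...) object$fitted

#' @export
residuals.nrprf_fit <- function(object, ...) object$y - object$fitted

#' @export
predict.nrprf_fit <- function(object, design = NULL, hrf = NULL, ...) {
  if (is.null(design)) return(object$fitted)
  if (is.null(hrf)) hrf <- canonical_hrf(design$tr)
  w <- if (object$model == "nonrigid") nonrigid_field(object$dx)
  else exp(-(object$x0 - seq_along(design$labels))^2 / (2 * object$sigma^2))
  object$beta * predict_timeseries(w, design, hrf)
}

#' @export
summary.nrprf_fit <- function(object, ...) {
  out <- list(model = object$model, center = object$center,
              size = object$size, beta = object$beta, r2 = object$r2,
              f_stat = object$f_stat, p_value = object$p_value,
              degenerate = object$degenerate,
              proximity = if (object$model == "nonrigid")
                normalized_proximity(object$dx) else NULL)
  class(out) <- "summary.nrprf_fit"
  out
}

#' @export
print.summary.nrprf_fit <- function(x, ...) {
  cat(sprintf("%s pRF fit: centre %s, size %.3f, beta %.4g\n",
              if (x$model == "nonrigid") "Non-rigid" else "Conventional",
              format(x$center), x$size, x$beta))
  cat(sprintf("R2 = %.4f, F = %.3f, p = %.3g%s\n", x$r2, x$f_stat,
              x$p_value, if (x$degenerate) " (degenerate)" else ""))
  if (!is.null(x$proximity)) {
    cat("Normalised body-part proximities (1 = field centre):\n")
    print(round(x$proximity, 3))
  }
  invisible(x)
}

#' @export
plot.nrprf_fit <- function(x, ...) {
  if (x$model == "nonrigid") {
    p <- normalized_proximity(x$dx)
    graphics::barplot(p, names.arg = seq_along(p),
                      xlab = "body part", ylab = "normalised proximity",
                      main = "Non-rigid pRF profile", ...)
  } else {
    xi <- seq_along(x$labels)
    g <- exp(-(x$x0 - xi)^2 / (2 * x$sigma^2))
    graphics::plot(xi, g, type = "h", xlab = "body part",
                   ylab = "response weight",
                   main = "Conventional pRF profile", ...)
  }
  invisible(x)
}

#' @export
simulate.nrprf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_hat <- stats::sd(residuals(object))
  n <- length(object$y)
  out <- replicate(nsim, object$fitted + stats::rnorm(n, 0, sd_hat))
  as.data.frame(out)
}
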