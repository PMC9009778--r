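test_that("nonrigid_field evaluates the static Gaussian", {
  expect_equal(nonrigid_field(0), 1)
  expect_equal(nonrigid_field(1), exp(-0.5))
  expect_lt(nonrigid_field(10), 1e-21)  # numerically zero at the bound
  expect_error(nonrigid_field(-0.1), "dx")
  expect_error(nonrigid_field(10.5), "dx")
})

test_that("predict_timeseries is linear and places the HRF at events", {
  p <- tiny_protocol()
  T <- ncol(p$design$s)
  expect_equal(predict_timeseries(rep(0, 4), p$design, p$hrf), rep(0, T))
  w <- c(1, 0, 0, 0)
  pred <- predict_timeseries(w, p$design, p$hrf)
  expect_equal(predict_timeseries(2 * w, p$design, p$hrf), 2 * pred)
  # impulse response: one event, impulse regressor, weight 1 -> shifted HRF
  sched <- manual_schedule(onsets = 4, conditions = 1L, n_parts = 1L)
  dm <- design_matrix(sched, volumes_per_run = 25L, tr = 2, boxcar = 0)
  h <- canonical_hrf(2)
  pr <- predict_timeseries(1, dm, h)
  onset_vol <- 3L  # volume with acquisition start 4 s
  expect_equal(pr[onset_vol:(onset_vol + length(h$values) - 1)], h$values,
               tolerance = 1e-10)
  expect_lt(max(abs(pr[seq_len(onset_vol - 1)])), 1e-10)  # FFT round-off
  # tr mismatch is a configuration error
  expect_error(predict_timeseries(1, dm, canonical_hrf(1.5)), "TR")
})

test_that("noiseless non-rigid fits recover center, amplitude and scale", {
  p <- tiny_protocol(n_parts = 4L, repetitions = 3L, volumes = 40L)
  dx_true <- c(0, 0.8, 2.0, 3.5)
  y <- 1.3 * predict_timeseries(nonrigid_field(dx_true), p$design, p$hrf)
  fit <- nrprf(y, p$design, p$hrf)
  expect_s3_class(fit, "nonrigid_prf")
  expect_equal(fit$center, 1L)
  expect_gte(fit$r2, 0.999)
  expect_equal(unname(fit$dx), dx_true, tolerance = 1e-6)
  expect_equal(fit$beta, 1.3, tolerance = 1e-6)
  # scale equivariance: y * c scales beta, leaves dx unchanged
  fit2 <- nrprf(3 * y, p$design, p$hrf)
  expect_equal(fit2$beta, 3 * fit$beta, tolerance = 1e-8)
  expect_equal(fit2$dx, fit$dx, tolerance = 1e-8)
})

test_that("fitted distances respect the bounds exactly", {
  p <- tiny_protocol(n_parts = 4L, repetitions = 2L, volumes = 30L)
  set.seed(5)
  for (k in 1:20) {
    y <- rnorm(ncol(p$design$s))
    fit <- nrprf(y, p$design, p$hrf)
    expect_true(all(fit$dx >= 0 & fit$dx <= fit$options$dx_max))
  }
})

test_that("the fit attains the SSE of an exhaustive grid search", {
  # oracle: profile-beta SSE over a 0.25-step lattice on dx (4 conditions);
  # the fitted solution must be at least as good
  p <- tiny_protocol(n_parts = 4L, repetitions = 2L, volumes = 28L)
  X <- nrprf:::conv_design(p$design, p$hrf)
  lattice <- seq(0, 10, by = 0.25)
  grid_sse <- function(y) {
    ss0 <- sum(y^2)
    best <- Inf
    G1 <- exp(-lattice^2 / 2)
    for (a in G1) for (b in G1) {
      gcd <- as.matrix(expand.grid(G1, G1))
      P <- cbind(a, b, gcd[, 1], gcd[, 2]) %*% t(X)
      num <- P %*% y
      den <- rowSums(P^2)
      sse <- ss0 - ifelse(den > 0, num^2 / den, 0)
      best <- min(best, sse)
    }
    best
  }
  set.seed(11)
  for (k in 1:2) {
    dx_true <- runif(4, 0, 4)
    y <- predict_timeseries(nonrigid_field(dx_true), p$design, p$hrf) +
      rnorm(ncol(p$design$s), 0, 0.3)
    fit <- nrprf(y, p$design, p$hrf)
    expect_lte(fit$sse, grid_sse(y) + 1e-8)
  }
})

test_that("degenerate and negative-amplitude inputs are flagged", {
  p <- tiny_protocol()
  T <- ncol(p$design$s)
  fit <- nrprf(rep(2, T), p$design, p$hrf)
  expect_true(fit$degenerate)
  expect_equal(fit$r2, 0)
  expect_equal(fit$p_value, 1)
  y <- -predict_timeseries(nonrigid_field(c(0, 2, 4, 6)), p$design, p$hrf)
  fit_neg <- nrprf(y, p$design, p$hrf)
  expect_true(fit_neg$negative_beta)
  expect_lt(fit_neg$beta, 0)
})

test_that("prf_center follows the minimum-distance rule with floored ties", {
  expect_equal(prf_center(c(3, 0.2, 5, rep(10, 15))), 2L)
  dx <- rep(10, 18); dx[c(3, 6)] <- 0.5
  expect_equal(prf_center(dx), 4L)        # floor((3 + 6) / 2)
  expect_equal(prf_center(rep(1, 18)), 9L)  # floor(mean(1:18))
  # ties only within the tolerance
  dx2 <- rep(10, 18); dx2[3] <- 0.5; dx2[6] <- 0.5 + 1e-3
  expect_equal(prf_center(dx2), 3L)
})

test_that("prf_size counts proximity-weighted parts in the FWHM window", {
  half <- sqrt(2 * log(2))
  expect_equal(prf_size(c(0, rep(10, 17))), half)
  expect_equal(prf_size(rep(0, 18)), 18 * half)
  expect_equal(prf_size(c(0, 1, rep(10, 16))), (1 + 0.9) * half)
  # monotone: moving one part outward never increases the size
  dx <- c(0, 0.5, 1.0, rep(10, 15))
  sizes <- vapply(seq(0.5, 10, by = 0.5),
                  function(d) prf_size(replace(dx, 3, d)), numeric(1))
  expect_true(all(diff(sizes) <= 1e-12))
})

test_that("goodness_of_fit reproduces the protocol degrees of freedom", {
  set.seed(2)
  y <- rnorm(856)
  g <- goodness_of_fit(y, y * 0.5, n_params = 19)
  expect_equal(g$df, c(19, 837))
  expect_equal(goodness_of_fit(y, y, 19)$r2, 1)
  g0 <- goodness_of_fit(rep(0, 100), rep(0, 100), 5)
  expect_true(g0$degenerate)
})

test_that("F-test against the zero-signal null is valid (conservative)", {
  # the model prediction set is a positive cone, not a 19-dim linear
  # subspace, so rejection under the null stays at or below nominal alpha
  p <- whole_body_protocol(seed = 3)
  set.seed(33)
  Y <- matrix(rnorm(300 * 856), 300)
  fits <- fit_vertices(Y, p$design, p$hrf)
  rej <- mean(fits$p_value < 0.05)
  expect_lte(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
  # and BH selection retains at most ~q under the null
  expect_lte(mean(fits$selected), 0.05)
})

test_that("select_vertices implements BH step-up", {
  expect_equal(select_vertices(c(0.001, 0.02, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(select_vertices(rep(1, 5)), rep(FALSE, 5))
  expect_identical(select_vertices(numeric(0)), logical(0))
  set.seed(9)
  frac <- mean(replicate(200, mean(select_vertices(runif(50)))))
  expect_lte(frac, 0.05)
})

test_that("conventional fits recover their generating parameters", {
  p <- whole_body_protocol(seed = 8)
  xi <- 1:18
  g <- exp(-(7 - xi)^2 / (2 * 1.5^2))
  y <- 0.8 * predict_timeseries(g, p$design, p$hrf)
  fit <- nrprf(y, p$design, p$hrf, model = "conventional")
  expect_s3_class(fit, "conventional_prf")
  expect_equal(fit$x0, 7, tolerance = 0.05)
  expect_equal(fit$sigma, 1.5, tolerance = 0.05)
  expect_equal(fit$beta, 0.8, tolerance = 0.01)
  # single-condition responder: x0 lands on that part
  y1 <- predict_timeseries(as.numeric(xi == 12), p$design, p$hrf)
  fit1 <- nrprf(y1, p$design, p$hrf, model = "conventional")
  expect_lt(abs(fit1$x0 - 12), 0.5)
  # symmetric response around part 9
  g9 <- exp(-(9 - xi)^2 / (2 * 4))
  fit9 <- nrprf(predict_timeseries(g9, p$design, p$hrf), p$design, p$hrf,
                model = "conventional")
  expect_equal(fit9$x0, 9, tolerance = 0.05)
})

test_that("nonrigid and conventional center maps agree on somatotopic data", {
  p <- whole_body_protocol(seed = 13)
  truth <- make_somatotopic_ground_truth(n_vertices = 30, subjects = 1,
                                         seed = 14)
  truth <- truth[truth$roi %in% c("PMd", "iPC"), ]
  Y <- simulate_vertex_timeseries(truth, p$design, p$hrf, noise_sd = 0.2,
                                  seed = 15)
  fit_nr <- fit_vertices(Y, p$design, p$hrf, model = "nonrigid")
  fit_cv <- fit_vertices(Y, p$design, p$hrf, model = "conventional")
  r <- cor(fit_nr$center, fit_cv$center)
  expect_gte(r, 0.8)
})

test_that("nrprf_fit methods are coherent", {
  p <- tiny_protocol()
  dx <- c(0, 1, 3, 6)
  y <- predict_timeseries(nonrigid_field(dx), p$design, p$hrf) +
    rnorm(ncol(p$design$s), 0, 0.05)
  fit <- nrprf(y, p$design, p$hrf)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_length(coef(fit), 5L)  # 4 distances + beta
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, p$design, p$hrf), fitted(fit),
               tolerance = 1e-8)
  expect_output(print(fit), "Non-rigid")
  expect_output(print(summary(fit)), "proximities")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(length(y), 2L))
  expect_error(nrprf(y[-1], p$design, p$hrf), "length")
})
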