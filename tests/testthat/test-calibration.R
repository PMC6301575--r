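test_that("NWAE obeys its identity, unit and toy-vector values", {
  set.seed(1)
  x <- rnorm(64)
  expect_equal(nwae(x, x, d = 0, d0 = 4), 0)
  # zero estimate against a nonzero reference: each error term is 1
  expect_equal(nwae(x, numeric(64), d = 0, d0 = 4), 1)
  # 12-sample toy vectors, hand-computed with first differences
  r <- c(0, 1, 3, 2, 4, 6, 5, 4, 2, 1, 0, 1)
  e <- c(0, 2, 3, 1, 4, 5, 5, 3, 2, 2, 0, 0)
  w <- nwae_weights()
  hand <- 0
  rt <- r; et <- e
  for (i in 1:3) {
    if (i > 1) { rt <- diff(rt); et <- diff(et) }
    hand <- hand + (1 / 3) * sum(abs(rt - et)) / sum(abs(rt))
  }
  expect_equal(nwae(r, e, w, d = 0, d0 = 0), hand, tolerance = 1e-12)
  # invariant to common positive scaling
  expect_equal(nwae(5 * r, 5 * e, w, d = 0, d0 = 0), hand, tolerance = 1e-12)
  # the delayed-range trim scores a planted shift as d recovers it
  xs <- c(numeric(3), x[1:61])
  expect_lt(nwae(x, xs, d = -3, d0 = 5), 1e-12)
  expect_gt(nwae(x, xs, d = 0, d0 = 5), 0.1)
  expect_error(nwae(x, xs, d = 9, d0 = 5), "exceed")
  expect_error(nwae(rep(1, 64), x, d = 0, d0 = 4), "zero-energy")
})

test_that("NWAE weights must be a unit simplex", {
  expect_error(nwae_weights(c(0.5, 0.5, 0.5)), "summing")
  expect_equal(nwae_weights()$w, rep(1 / 3, 3))
})

test_that("coarse alignment finds constructed shifts", {
  set.seed(2)
  base <- as.numeric(stats::arima.sim(list(ar = 0.9), 3000))
  expect_equal(coarse_align(base, base, 11025, f0_hz = 210), 0L)
  k <- 9L
  est <- c(numeric(k), base[1:(3000 - k)])
  expect_equal(coarse_align(base, est, 11025, f0_hz = 210), k)
  # noisy shifted pulse train at ~20 dB SNR: within one sample
  flow <- glottal_pulse_train(pulse_spec(f0 = 220, duration_s = 0.4, seed = 3))
  ref <- flow$samples
  est2 <- c(numeric(6), ref[1:(length(ref) - 6)]) +
    rnorm(length(ref), 0, sd(ref) * 0.1)
  expect_lt(abs(coarse_align(ref, est2, 11025, f0_hz = 220) - 6), 2)
  expect_error(coarse_align(rep(1, 100), rnorm(100), 11025), "degenerate")
})

test_that("the mask notch has unit DC gain and removes a planted resonance", {
  spec <- pulse_spec(f0 = 210, duration_s = 0.5, seed = 4)
  g <- synth_calibration_pair(spec, formant_hz = 700, formant_bw_hz = 90)
  iv <- inverse_filter_oral_airflow(g$mask, g$fs)
  expect_equal(sum(iv$notch$b) / sum(iv$notch$a), 1, tolerance = 1e-6)
  expect_lt(abs(iv$formant_hz - 700), 15)
  expect_lt(abs(iv$bandwidth_hz - 90), 20)
  # residual formant ripple (departure from the band-passed clean flow)
  # drops by >= 20 dB after the notch
  fs <- g$fs
  flow <- glottal_pulse_train(spec)
  bp0 <- signal::butter(2, c(60, 1100) / (fs / 2), type = "pass")
  ideal <- as.numeric(signal::filtfilt(bp0, flow$samples))
  masked <- as.numeric(signal::filtfilt(bp0, g$mask))
  i <- 1000:(length(ideal) - 1000)
  e_before <- sum((masked[i] - ideal[i])^2)
  e_after <- sum((iv$flow[i] - ideal[i])^2)
  expect_gt(10 * log10(e_before / e_after), 20)
  # formant-free input passes nearly unchanged (band-passed)
  bp <- signal::butter(2, c(60, 1100) / (fs / 2), type = "pass")
  ideal <- as.numeric(signal::filtfilt(bp, flow$samples))
  g0 <- synth_calibration_pair(spec, formant_bw_hz = 2000, formant_hz = 700)
  iv0 <- tryCatch(inverse_filter_oral_airflow(g0$mask, fs),
                  error = function(e) NULL)
  if (!is.null(iv0)) {
    i <- 1000:(length(ideal) - 1000)
    expect_lt(sqrt(mean((iv0$flow[i] - ideal[i])^2)) / sqrt(mean(ideal[i]^2)),
              0.25)
  }
})

test_that("PSO is seed-reproducible, monotone, and solves simple programs", {
  sphere <- function(x) sum((x - c(0.3, -0.2, 0.7))^2)
  cfg <- pso_config(n_particles = 20, max_iter = 80, seed = 5)
  r1 <- pso_optimize(sphere, rep(-2, 3), rep(2, 3), cfg)
  r2 <- pso_optimize(sphere, rep(-2, 3), rep(2, 3), cfg)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 0))
  expect_lt(r1$value, 1e-6)
  # collapsed bounds return the point itself
  r3 <- pso_optimize(sphere, c(1, 1, 1), c(1, 1, 1), cfg)
  expect_equal(r3$par, c(1, 1, 1))
  expect_equal(r3$value, sphere(c(1, 1, 1)))
  # integer dimensions are rounded
  r4 <- pso_optimize(function(x) (x[1] - 2.2)^2 + (x[2] - 3)^2,
                     c(-5, -5), c(5, 5), cfg, integer_dims = 2L)
  expect_equal(r4$par[2], round(r4$par[2]))
  expect_error(pso_optimize(function(x) NaN, -1, 1, cfg), "non-finite")
})

test_that("transfer-grid lookup covers the bounds and returns nearest cells", {
  grid <- cached_grid()
  b <- q_bounds()
  expect_equal(min(grid$q4s), b$lower[4])
  expect_equal(max(grid$q4s), b$upper[4])
  # lookup at a node equals the exact branch computation
  f <- grid$f
  cell <- transfer_grid_lookup(grid, 1.0, 1.0)
  exact <- subglottal_branches(tracheal_geometry(q_set()), f)
  expect_equal(cell$Zsub2$values, exact$Zsub2$values, tolerance = 1e-12)
  # off-node lookups snap to the nearest node
  near <- transfer_grid_lookup(grid, 1.0 + 0.02, 1.0 - 0.02)
  expect_equal(near$Zsub2$values, cell$Zsub2$values, tolerance = 1e-12)
})

test_that("grid-based objective stays close to the exact-geometry objective", {
  q_true <- q_set(c(1.1, 0.9, 1.2, 1.02, 0.97))  # off the 0.05 grid in q4/q5
  g <- synth_calibration_pair(pulse_spec(f0 = 210, duration_s = 0.4, seed = 6),
                              q_true = q_true)
  fs <- g$fs
  bp <- signal::butter(2, c(60, 1100) / (fs / 2), type = "pass")
  ref <- inverse_filter_oral_airflow(g$mask, fs)$flow
  m <- round(0.05 * fs)
  keep <- (m + 1):(length(ref) - m)
  d0 <- round(fs / 210 / 2)
  score <- function(branches) {
    fir <- ibif_filter(q_true, fs = fs, branches = branches)
    est <- as.numeric(signal::filtfilt(bp,
      estimate_glottal_flow(g$acc, fir)$samples))[keep]
    min(vapply(-2:2, function(d) nwae(ref[keep], est, d = d, d0 = d0),
               numeric(1)))
  }
  grid <- cached_grid()
  o_grid <- score(transfer_grid_lookup(grid, 1.02, 0.97))
  o_exact <- score(subglottal_branches(tracheal_geometry(q_true), grid$f))
  expect_lt(abs(o_grid - o_exact), 0.02)
})

test_that("PSO calibration recovers a planted Q set and delay", {
  grid <- cached_grid()
  q_true <- q_set(c(1.4, 0.8, 1.6, 1.1, 0.95))
  g <- synth_calibration_pair(pulse_spec(f0 = 210, duration_s = 0.5, seed = 4),
                              q_true = q_true, delay_samples = 7)
  fit <- fit_q_parameters(list(g),
                          cfg = pso_config(n_particles = 25, max_iter = 60,
                                           seed = 1),
                          grid = grid)
  expect_lt(fit$nwae, 0.05)
  expect_lt(max(abs(fit$q$q[1:3] / q_true$q[1:3] - 1)), 0.10)
  expect_lte(abs(fit$d - 7), 1)
  # degenerate search space returns the collapsed point
  b1 <- q_bounds(lower = c(1, 1, 1, 1, 1) - 1e-9, upper = c(1, 1, 1, 1, 1))
  fit1 <- fit_q_parameters(list(g), cfg = pso_config(n_particles = 5,
                                                     max_iter = 2, seed = 1),
                           bounds = b1, grid = grid)
  expect_equal(fit1$q$q, rep(1, 5), tolerance = 1e-6)
})
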