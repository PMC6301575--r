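fs <- 11025

test_that("ACFL is the cycle peak-to-peak amplitude", {
  tri <- c(seq(0, 300, length.out = 30), seq(300, 0, length.out = 30))
  expect_equal(acfl(tri), 300)
  t <- (0:99) / 100
  expect_equal(acfl(120 * sin(2 * pi * t)), 2 * 120, tolerance = 1e-3)
  set.seed(1)
  pulse <- cumsum(rnorm(50))
  expect_equal(acfl(pulse), max(pulse) - min(pulse))
  expect_error(acfl(numeric(0)), "empty")
})

test_that("MFDR is the most negative first-difference derivative in L/s^2", {
  ramp <- seq(1000, 0, length.out = 101)          # mL/s over 100 samples
  slope <- diff(ramp)[1] * fs / 1000              # L/s^2
  expect_equal(mfdr(ramp, fs), slope)
  # sinusoid amplitude A at frequency f: min derivative -2*pi*f*A
  f0 <- 150; A <- 200
  t <- (0:(fs / f0 * 3)) / fs
  x <- A * sin(2 * pi * f0 * t)
  expect_equal(mfdr(x, fs), -2 * pi * f0 * A / 1000, tolerance = 0.01)
  set.seed(2)
  z <- rnorm(40)
  expect_equal(mfdr(z, fs), min(diff(z)) * fs / 1000)
})

test_that("the OQ/SQ line construction matches flank geometry", {
  # symmetric triangle (unique peak sample): SQ exactly 1
  tri <- c(seq(0, 1, length.out = 61), seq(1, 0, length.out = 61)[-1])
  r <- oq_sq(tri, fs = fs)
  expect_equal(r$SQ, 1, tolerance = 0.02)
  # 3:1 rise:fall sawtooth
  saw <- c(seq(0, 1, length.out = 90), seq(1, 0, length.out = 30))
  r3 <- oq_sq(saw, fs = fs)
  expect_equal(r3$SQ, 3, tolerance = 0.05 * 3)
  # independent geometry oracle on a generated pulse cycle
  flow <- glottal_pulse_train(pulse_spec(f0 = 150, oq = 0.5, sq = 1.6,
                                         duration_s = 0.1))
  truth <- attr(flow, "truth")
  i <- 2
  cyc <- flow$samples[truth$start[i]:(truth$start[i] + truth$n[i] - 1L)]
  est <- oq_sq(cyc, fs = fs)
  want <- oracle_line_quotients(0.5, 1.6)
  expect_equal(est$OQ, want$OQ, tolerance = 0.05)
  expect_equal(est$SQ, want$SQ, tolerance = 0.1)
  # flat cycle is skipped
  expect_null(oq_sq(rep(1, 50), fs = fs))
})

test_that("NAQ arithmetic, homogeneity and sinusoid closed form hold", {
  expect_equal(naq(300, 300, 0.005), 0.2)   # 0.3 L/s, 300 L/s^2, 5 ms
  expect_equal(naq(3 * 300, 3 * 300, 0.005), 0.2)
  # sinusoid: ACFL = 2A, |MFDR| = 2*pi*f*A, T0 = 1/f -> NAQ = 1/pi
  f0 <- 200; A <- 100
  t <- (0:(round(fs / f0) - 1)) / fs
  x <- A * sin(2 * pi * f0 * t)
  a <- acfl(x); m <- mfdr(x, fs)
  expect_equal(naq(a, m, 1 / f0), 1 / pi, tolerance = 0.02)
  expect_error(naq(300, 0, 0.005), "zero")
})

test_that("spectral measures match constructed harmonic amplitudes", {
  f0 <- 200
  t <- (0:550) / fs
  x <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t)
  sm <- spectral_measures(x, f0, fs)
  expect_equal(sm$H1H2, 20 * log10(2), tolerance = 0.2)
  # eight equal harmonics: HRF = 20 log10(7)
  xe <- rowSums(sapply(1:8, function(k) sin(2 * pi * k * f0 * t + k)))
  sme <- spectral_measures(xe, f0, fs)
  expect_equal(sme$HRF, 20 * log10(7), tolerance = 0.2)
  # amplitudes match a zero-padded DFT peak oracle
  flow <- glottal_pulse_train(pulse_spec(f0 = f0, duration_s = 0.05))
  y <- flow$samples[1:551] - mean(flow$samples[1:551])
  smp <- spectral_measures(y, f0, fs)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:550) / 550)
  spec <- Mod(fft(c(y * w, numeric(8192 - 551))))[1:4096]
  fbin <- fs / 8192
  for (k in 1:8) {
    lo <- floor((k * f0 - f0 / 4) / fbin) + 1
    hi <- ceiling((k * f0 + f0 / 4) / fbin) + 1
    expect_equal(20 * log10(smp$A[k]), 20 * log10(max(spec[lo:hi])),
                 tolerance = 0.2)
  }
})

test_that("SPL estimation follows the daily linear calibration", {
  cal <- spl_calibration(slope = 1, intercept = 0)
  x <- 10^(70 / 20)               # RMS whose dB level is 70
  expect_equal(spl_estimate(rep(x, 100), cal), 70, tolerance = 1e-9)
  cal2 <- spl_calibration(slope = 0.8, intercept = 30)
  set.seed(3)
  fr <- rnorm(551)
  base <- spl_estimate(fr, cal2)
  expect_equal(spl_estimate(2 * fr, cal2) - base, 0.8 * 20 * log10(2),
               tolerance = 1e-9)
  expect_error(spl_calibration(slope = -1), "slope")
})

test_that("derived measures follow their log laws", {
  d <- derived_measures(100, 300, spl_db = 80)
  expect_equal(d$logACFL, 40)
  expect_equal(d$logMFDR, 10 * log10(300^2))
  expect_equal(d$ACFLp, 80 / 40)
  d2 <- derived_measures(100 * 10, 300, spl_db = 80)
  expect_equal(d2$logACFL - d$logACFL, 20)
  expect_equal(derived_measures(50, 50, 80)$MFDRp,
               derived_measures(50, 50, 80)$ACFLp)
  expect_error(derived_measures(0, 300), "zero")
})

test_that("frame aggregation averages cycle measures", {
  flow <- glottal_pulse_train(pulse_spec(f0 = 200, duration_s = 0.06))
  fr <- frame_stream(flow)[[1]]
  ff <- frame_features(fr, 200)
  cycles <- segment_cycles(fr$flow, 200, fs)
  per_acfl <- vapply(cycles, acfl, numeric(1))
  expect_equal(ff$ACFL, mean(per_acfl), tolerance = 1e-9)
  expect_equal(ff$n_cycles, length(cycles))
})

test_that("features are amplitude-scale equivariant", {
  spec <- pulse_spec(f0 = 180, acfl = 250, duration_s = 0.2, seed = 5)
  f1 <- extract_features(glottal_pulse_train(spec))$features
  spec2 <- spec; spec2$acfl <- 250 * 3
  f2 <- extract_features(glottal_pulse_train(spec2))$features
  expect_equal(f2$ACFL, 3 * f1$ACFL, tolerance = 1e-6)
  expect_equal(f2$MFDR, 3 * f1$MFDR, tolerance = 1e-6)
  expect_equal(f2$OQ, f1$OQ, tolerance = 1e-6)
  expect_equal(f2$SQ, f1$SQ, tolerance = 1e-6)
  expect_equal(f2$NAQ, f1$NAQ, tolerance = 1e-6)
  expect_equal(f2$H1H2, f1$H1H2, tolerance = 1e-6)
  expect_equal(f2$HRF, f1$HRF, tolerance = 1e-6)
  expect_equal(f2$logACFL - f1$logACFL, rep(20 * log10(3), nrow(f1)),
               tolerance = 1e-6)
})

test_that("forward-simulated signals yield features near generator truth", {
  q <- q_set()
  for (f0 in c(110, 240, 390)) {
    spec <- pulse_spec(f0 = f0, acfl = 320, oq = 0.6, sq = 2,
                       duration_s = 0.6, seed = f0)
    flow <- glottal_pulse_train(spec)
    a <- forward_simulate_acceleration(flow, q)
    est <- estimate_glottal_flow(a, ibif_filter(q, fs = fs))
    feats <- extract_features(est)$features
    feats <- feats[feats$index > 3 & feats$index < max(feats$index) - 2, ]
    expect_gt(nrow(feats), 2)
    expect_lt(abs(mean(feats$ACFL) - 320) / 320, 0.1)
    want <- oracle_line_quotients(0.6, 2)
    expect_lt(abs(mean(feats$OQ) - want$OQ), 0.1)
    expect_lt(abs(mean(feats$SQ) - 2), 0.35)   # closing-slope smoothing
    expect_lt(abs(mean(feats$f0_hz) - f0) / f0, 0.02)
  }
})
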