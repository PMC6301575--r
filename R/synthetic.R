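## Forward generators for testing: parametric glottal pulse trains,
## calibration gesture pairs, and two-group feature cohorts.

#' Glottal pulse-train specification
#'
#' @param f0 fundamental frequency in Hz; a scalar or a per-cycle vector
#'   (recycled). Must lie in [70, 600].
#' @param acfl peak-to-peak flow amplitude (mL/s).
#' @param oq open quotient target in (0, 1).
#' @param sq speed quotient target (> 0), ratio of opening to closing time.
#' @param jitter cycle-to-cycle period perturbation, percent sd of T0.
#' @param shimmer cycle-to-cycle amplitude perturbation, percent sd.
#' @param duration_s signal duration in seconds.
#' @param fs sampling rate (Hz).
#' @param seed RNG seed for the perturbations.
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(f0 = 200, acfl = 300, oq = 0.6, sq = 2,
                       jitter = 0, shimmer = 0, duration_s = 1,
                       fs = 11025, seed = 1) {
  if (any(f0 < 70) || any(f0 > 600)) stop("pulse_spec: f0 outside [70, 600] Hz")
  if (oq <= 0 || oq >= 1) stop("pulse_spec: oq must be in (0, 1)")
  if (sq <= 0) stop("pulse_spec: sq must be > 0")
  if (acfl <= 0) stop("pulse_spec: acfl must be > 0")
  structure(list(f0 = f0, acfl = acfl, oq = oq, sq = sq, jitter = jitter,
                 shimmer = shimmer, duration_s = duration_s, fs = fs,
                 seed = seed),
            class = "pulse_spec")
}

# Glottal pulse on [0, 1): linear rise over [0, t1), linear fall over
# [t1, t1+t2), closed elsewhere; t1 + t2 = oq, t1/t2 = sq. Unit peak, zero
# baseline. Linear flanks keep the open/speed quotients analytic under the
# median-line measurement convention; the first derivative is piecewise
# constant, so MFDR is -1/t2 per unit amplitude.
.pulse_cycle <- function(n, oq, sq) {
  t1 <- oq * sq / (1 + sq)
  t2 <- oq / (1 + sq)
  tt <- (0:(n - 1)) / n
  y <- numeric(n)
  ri <- tt < t1
  y[ri] <- tt[ri] / t1
  fi <- tt >= t1 & tt < t1 + t2
  y[fi] <- 1 - (tt[fi] - t1) / t2
  y
}

#' Synthesize a quasi-periodic glottal pulse train
#'
#' Piecewise-linear pulses with independently parameterized opening and
#' closing phases, so the open and speed quotients (and the flow
#' declination rate) are analytic properties of the waveform. Optional jitter and
#' shimmer perturb period and amplitude per cycle. The returned flow is
#' AC-coupled; per-cycle ground truth (start sample, period, t1, t2,
#' amplitude) is attached as attribute `truth`.
#'
#' @param spec a `pulse_spec`.
#' @return a `glottal_flow` with attribute `truth` (data.frame).
#' @export
glottal_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  rs <- .seed_guard(spec$seed)
  on.exit(rs())
  n_total <- round(spec$duration_s * spec$fs)
  samples <- numeric(n_total)
  truth <- list()
  pos <- 1L
  ci <- 1L
  while (TRUE) {
    f0c <- spec$f0[((ci - 1L) %% length(spec$f0)) + 1L]
    T0 <- spec$fs / f0c
    if (spec$jitter > 0) T0 <- T0 * (1 + stats::rnorm(1, 0, spec$jitter / 100))
    n_cyc <- max(4L, as.integer(round(T0)))
    if (pos + n_cyc - 1L > n_total) break
    amp <- spec$acfl
    if (spec$shimmer > 0) amp <- amp * (1 + stats::rnorm(1, 0, spec$shimmer / 100))
    cyc <- amp * .pulse_cycle(n_cyc, spec$oq, spec$sq)
    samples[pos:(pos + n_cyc - 1L)] <- cyc
    t1 <- spec$oq * spec$sq / (1 + spec$sq) * n_cyc / spec$fs
    t2 <- spec$oq / (1 + spec$sq) * n_cyc / spec$fs
    truth[[ci]] <- data.frame(start = pos, n = n_cyc, T0 = n_cyc / spec$fs,
                              t1 = t1, t2 = t2, amp = amp, f0 = spec$fs / n_cyc)
    pos <- pos + n_cyc
    ci <- ci + 1L
  }
  gf <- glottal_flow(samples, fs = spec$fs)
  attr(gf, "truth") <- do.call(rbind, truth)
  gf
}

# save/restore the global RNG state around seeded generation
.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthesize a stream with labeled voiced and unvoiced spans
#'
#' Pulse train inside the given spans, low-level white noise elsewhere;
#' used to benchmark the voicing detector against known labels.
#'
#' @param duration_s total duration (s).
#' @param voiced_spans two-column matrix of span start/end times (s).
#' @param spec a `pulse_spec` for the voiced parts (duration ignored).
#' @param noise_rms RMS of the unvoiced background noise (flow units).
#' @param seed RNG seed.
#' @return a `glottal_flow` with attribute `voiced_fun`, a function(t)
#'   returning TRUE inside voiced spans.
#' @export
synth_labeled_stream <- function(duration_s, voiced_spans,
                                 spec = pulse_spec(), noise_rms = 1,
                                 seed = 1) {
  rs <- .seed_guard(seed)
  on.exit(rs())
  fs <- spec$fs
  n <- round(duration_s * fs)
  x <- stats::rnorm(n, 0, noise_rms)
  for (i in seq_len(nrow(voiced_spans))) {
    i0 <- max(1L, round(voiced_spans[i, 1] * fs) + 1L)
    i1 <- min(n, round(voiced_spans[i, 2] * fs))
    seg_spec <- spec
    seg_spec$duration_s <- (i1 - i0 + 1L) / fs
    seg <- glottal_pulse_train(seg_spec)
    x[i0:(i0 + length(seg$samples) - 1L)] <- x[i0:(i0 + length(seg$samples) - 1L)] +
      seg$samples
  }
  gf <- glottal_flow(x, fs = fs)
  attr(gf, "voiced_fun") <- function(t) {
    apply(outer(t, voiced_spans[, 1], ">=") &
          outer(t, voiced_spans[, 2], "<="), 1, any)
  }
  gf
}

#' Synthesize a calibration gesture pair
#'
#' Produces the two channels of a laboratory calibration recording: the
#' accelerometer channel via the forward skin/subglottal transfer at a
#' known Q set, and the oral-airflow (mask) channel as the flow colored by
#' one vocal-tract resonance, with an optional integer delay and additive
#' noise; the finite mask bandwidth is imposed downstream by the analysis
#' bandpass of [inverse_filter_oral_airflow()].
#'
#' @param spec a `pulse_spec` for the underlying glottal flow.
#' @param q_true the `q_set` used in the forward model.
#' @param acc an `accelerometer_spec`.
#' @param formant_hz vocal-tract resonance frequency (Hz).
#' @param formant_bw_hz resonance bandwidth (Hz).
#' @param delay_samples integer delay applied to the mask channel.
#' @param snr_db per-channel additive white noise SNR; Inf for noiseless.
#' @param vowel,loudness gesture labels.
#' @return object of class `calibration_gesture` with fields `mask`
#'   (numeric), `acc` (`acc_signal`), `fs`, `f0`, labels, and the planted
#'   truth (`q_true`, `delay_samples`).
#' @export
synth_calibration_pair <- function(spec = pulse_spec(duration_s = 0.5),
                                   q_true = q_set(),
                                   acc = accelerometer_spec(),
                                   formant_hz = 700, formant_bw_hz = 90,
                                   delay_samples = 0, snr_db = Inf,
                                   vowel = "a", loudness = "comfortable") {
  flow <- glottal_pulse_train(spec)
  fs <- flow$fs
  acc_sig <- forward_simulate_acceleration(flow, q = q_true, acc = acc)
  # mask channel: flow through one resonance, then mask band limit
  r <- exp(-pi * formant_bw_hz / fs)
  th <- 2 * pi * formant_hz / fs
  a <- c(1, -2 * r * cos(th), r^2)
  g <- sum(a)                          # unity gain at DC
  mask <- as.numeric(signal::filter(signal::Arma(b = g, a = a), flow$samples))
  if (delay_samples != 0) {
    d <- as.integer(delay_samples)
    mask <- if (d > 0) c(numeric(d), mask[1:(length(mask) - d)])
            else c(mask[(1 - d):length(mask)], numeric(-d))
  }
  if (is.finite(snr_db)) {
    rs <- .seed_guard(spec$seed + 1000L)
    on.exit(rs())
    add_noise <- function(x) {
      x + stats::rnorm(length(x), 0, stats::sd(x) * 10^(-snr_db / 20))
    }
    mask <- add_noise(mask)
    acc_sig$samples <- add_noise(acc_sig$samples)
  }
  mean_f0 <- mean(spec$f0)
  structure(list(mask = mask, acc = acc_sig, fs = fs, f0 = mean_f0,
                 vowel = vowel, loudness = loudness,
                 q_true = q_true, delay_samples = delay_samples),
            class = "calibration_gesture")
}

#' Two-group cohort specification
#'
#' Defaults mirror the study design: 48 patient/control pairs of one-week
#' recordings, with the patient group's ACFL family shifted upward by a
#' medium effect size (Cohen's d 0.5 on the between-subject scale).
#' Frame counts per window are reduced relative to a full 5-minute window
#' so cohorts remain cheap to simulate; the voicing structure (sparse
#' voiced frames within windows, day boundaries) is preserved.
#'
#' @param n_pairs number of patient/control pairs (default 48).
#' @param effect_d Cohen's d of the patient shift applied to the
#'   log-ACFL-family subject means (default 0.5).
#' @param days_per_subject monitored days (default 7).
#' @param windows_per_day 5-minute windows retained per day (default 6).
#' @param frames_per_window mean voiced frames per window (default 60).
#' @param base means and dispersions of the frame measures; see Details.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @details `base` is a list with entries `log_acfl_mean` (log mL/s),
#'   `between_sd` and `within_sd` (log scale), `oq_mean`, `oq_sd`,
#'   `log_sq_mean`, `log_sq_sd`, `f0_mean`, `f0_sd` (Hz), `h1h2_mean`,
#'   `h1h2_sd` (dB), `hrf_mean`, `hrf_sd` (dB), `spl_mean`, `spl_sd`
#'   (dB SPL), `mfdr_shape_sd` (log scale of the MFDR/ACFL link).
#' @export
cohort_spec <- function(n_pairs = 48, effect_d = 0.5, days_per_subject = 7,
                        windows_per_day = 6, frames_per_window = 60,
                        base = list(), seed = 1) {
  b <- utils::modifyList(list(
    log_acfl_mean = log(300), between_sd = 0.35, within_sd = 0.45,
    oq_mean = 0.55, oq_sd = 0.07, log_sq_mean = log(1.7), log_sq_sd = 0.2,
    f0_mean = 220, f0_sd = 30, h1h2_mean = 5, h1h2_sd = 3,
    hrf_mean = -5, hrf_sd = 2.5, spl_mean = 82, spl_sd = 5,
    mfdr_shape_sd = 0.15), base)
  structure(list(n_pairs = n_pairs, effect_d = effect_d,
                 days_per_subject = days_per_subject,
                 windows_per_day = windows_per_day,
                 frames_per_window = frames_per_window,
                 base = b, seed = seed),
            class = "cohort_spec")
}

#' Simulate a two-group frame-feature cohort
#'
#' Generates per-frame values of the eleven glottal measures for every
#' subject in a paired patient/control cohort. Subjects receive latent
#' means (between-subject variation); frames add within-subject noise.
#' Patients' log-ACFL means are shifted by `effect_d` between-subject
#' standard deviations, which propagates to logACFL, ACFL' and (via the
#' physiological MFDR ~ ACFL * f0 link) weakly to the MFDR family,
#' emulating the elevated-airflow signature of phonotraumatic vocal
#' hyperfunction. The remaining measures are exchangeable between groups.
#'
#' @param spec a `cohort_spec`.
#' @return data.frame with columns subject, pair, group ("patient" or
#'   "control"), day, window, plus the 11 measure columns
#'   (ACFL, MFDR, OQ, SQ, NAQ, H1H2, HRF, logACFL, logMFDR, ACFLp, MFDRp).
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rs <- .seed_guard(spec$seed)
  on.exit(rs())
  b <- spec$base
  rows <- vector("list", spec$n_pairs * 2L)
  idx <- 0L
  for (p in seq_len(spec$n_pairs)) {
    for (grp in c("patient", "control")) {
      idx <- idx + 1L
      shift <- if (grp == "patient") spec$effect_d * b$between_sd else 0
      mu_acfl <- stats::rnorm(1, b$log_acfl_mean + shift, b$between_sd)
      mu_oq   <- stats::rnorm(1, b$oq_mean, b$oq_sd / 2)
      mu_sq   <- stats::rnorm(1, b$log_sq_mean, b$log_sq_sd / 2)
      mu_f0   <- stats::rnorm(1, b$f0_mean, b$f0_sd)
      mu_h1h2 <- stats::rnorm(1, b$h1h2_mean, b$h1h2_sd / 2)
      mu_hrf  <- stats::rnorm(1, b$hrf_mean, b$hrf_sd / 2)
      spl_b   <- stats::rnorm(1, b$spl_mean - 20 / log(10) * b$log_acfl_mean,
                              b$spl_sd / 2)
      n_frames_day <- spec$windows_per_day * spec$frames_per_window
      n <- spec$days_per_subject * n_frames_day
      day <- rep(seq_len(spec$days_per_subject), each = n_frames_day)
      window <- rep(rep(seq_len(spec$windows_per_day),
                        each = spec$frames_per_window),
                    times = spec$days_per_subject) +
        (day - 1L) * spec$windows_per_day
      acfl <- exp(stats::rnorm(n, mu_acfl, b$within_sd))
      f0 <- pmin(pmax(stats::rnorm(n, mu_f0, b$f0_sd / 3), 80), 500)
      oq <- pmin(pmax(stats::rnorm(n, mu_oq, b$oq_sd), 0.2), 0.95)
      sq <- exp(stats::rnorm(n, mu_sq, b$log_sq_sd))
      # |MFDR| (L/s^2) scales with ACFL (mL/s) and f0 for a fixed pulse shape
      mfdr_abs <- acfl / 1000 * pi * f0 * exp(stats::rnorm(n, 0, b$mfdr_shape_sd))
      mfdr <- -mfdr_abs
      naq <- (acfl / 1000) / (mfdr_abs / f0)
      h1h2 <- stats::rnorm(n, mu_h1h2, b$h1h2_sd)
      hrf <- stats::rnorm(n, mu_hrf, b$hrf_sd)
      spl <- spl_b + 20 * log10(acfl) + stats::rnorm(n, 0, b$spl_sd / 2)
      dm <- derived_measures(acfl, mfdr, spl)
      rows[[idx]] <- data.frame(
        subject = sprintf("%s%02d", substr(grp, 1, 1), p), pair = p,
        group = grp, day = day, window = window,
        ACFL = acfl, MFDR = mfdr, OQ = oq, SQ = sq, NAQ = naq,
        H1H2 = h1h2, HRF = hrf,
        logACFL = dm$logACFL, logMFDR = dm$logMFDR,
        ACFLp = dm$ACFLp, MFDRp = dm$MFDRp)
    }
  }
  do.call(rbind, rows)
}

#' Names of the eleven frame-based glottal measures
#' @return character vector in the canonical column order.
#' @export
measure_names <- function() {
  c("ACFL", "MFDR", "OQ", "SQ", "NAQ", "H1H2", "HRF",
    "logACFL", "logMFDR", "ACFLp", "MFDRp")
}
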