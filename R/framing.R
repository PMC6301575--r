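## Frame segmentation, voicing / stability gates, f0, and glottal cycles.

#' Framing and gating configuration
#'
#' @param frame_s frame length in seconds (default 0.05; 551 samples at
#'   11025 Hz, floor rounding).
#' @param acf_threshold minimum normalized autocorrelation peak for voicing.
#' @param band_split_hz boundary between the low and high energy bands.
#' @param band_ratio_min minimum low/high band energy ratio for voicing.
#' @param energy_floor minimum frame RMS for voicing.
#' @param rms_ratio_max onset/offset gate threshold on the half-frame RMS
#'   ratio (applied symmetrically, default 1.5).
#' @param f0_min_hz,f0_max_hz f0 search band (default 70-1000 Hz).
#' @param f0_gate_hz frames with f0 above this are not analyzed (500 Hz).
#' @param gate_on which channel the RMS gate reads: "flow" or "acc".
#' @return list of class `framing_config`.
#' @export
framing_config <- function(frame_s = 0.05, acf_threshold = 0.4,
                           band_split_hz = 1000, band_ratio_min = 1,
                           energy_floor = 1e-6, rms_ratio_max = 1.5,
                           f0_min_hz = 70, f0_max_hz = 1000,
                           f0_gate_hz = 500, gate_on = c("flow", "acc")) {
  structure(list(frame_s = frame_s, acf_threshold = acf_threshold,
                 band_split_hz = band_split_hz, band_ratio_min = band_ratio_min,
                 energy_floor = energy_floor, rms_ratio_max = rms_ratio_max,
                 f0_min_hz = f0_min_hz, f0_max_hz = f0_max_hz,
                 f0_gate_hz = f0_gate_hz, gate_on = match.arg(gate_on)),
            class = "framing_config")
}

#' Split signals into nonoverlapping frames
#'
#' @param flow a `glottal_flow`.
#' @param acc_sig optional `acc_signal` of the same length and rate.
#' @param config a `framing_config`.
#' @return list of frames; each frame is a list with `index`, `t_start`,
#'   `flow` and `acc` sample vectors, and `fs`.
#' @export
frame_stream <- function(flow, acc_sig = NULL, config = framing_config()) {
  fs <- flow$fs
  flen <- floor(config$frame_s * fs)
  n <- length(flow$samples) %/% flen
  lapply(seq_len(n), function(i) {
    idx <- ((i - 1L) * flen + 1L):(i * flen)
    list(index = i, t_start = (i - 1L) * flen / fs,
         flow = flow$samples[idx],
         acc = if (is.null(acc_sig)) flow$samples[idx] else acc_sig$samples[idx],
         fs = fs)
  })
}

.norm_acf <- function(x, lags) {
  x <- x - mean(x)
  e <- sum(x^2)
  if (e == 0) return(rep(0, length(lags)))
  n <- length(x)
  vapply(lags, function(l) sum(x[1:(n - l)] * x[(l + 1):n]) / e, numeric(1))
}

#' Voicing decision for one frame
#'
#' A frame is voiced when its normalized autocorrelation peak in the f0
#' lag band, its low/high band energy ratio, and its RMS all exceed their
#' thresholds (periodicity + spectral + energy evidence).
#'
#' @param frame a frame from [frame_stream()].
#' @param config a `framing_config`.
#' @return logical flag.
#' @export
detect_voiced <- function(frame, config = framing_config()) {
  x <- frame$acc
  fs <- frame$fs
  if (sqrt(mean(x^2)) < config$energy_floor) return(FALSE)
  lags <- max(2L, floor(fs / config$f0_max_hz)):ceiling(fs / config$f0_min_hz)
  lags <- lags[lags < length(x) - 2L]
  if (!length(lags)) return(FALSE)
  r <- .norm_acf(x, lags)
  if (max(r) < config$acf_threshold) return(FALSE)
  sp <- Mod(fft(x * .hann(length(x))))^2
  f <- (seq_along(sp) - 1) * fs / length(sp)
  half <- f <= fs / 2
  lo <- sum(sp[half & f <= config$band_split_hz])
  hi <- sum(sp[half & f > config$band_split_hz])
  if (hi > 0 && lo / hi < config$band_ratio_min) return(FALSE)
  TRUE
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Onset/offset stability gate
#'
#' Rejects frames whose half-frame RMS ratio departs from unity by more
#' than the threshold in either direction (max(r, 1/r) > 1.5 by default),
#' removing both voice onsets and offsets.
#'
#' @param frame a frame (uses the channel named in `config$gate_on`).
#' @param config a `framing_config`.
#' @return list with `reject` (logical) and `ratio`.
#' @export
onset_offset_gate <- function(frame, config = framing_config()) {
  x <- if (config$gate_on == "flow") frame$flow else frame$acc
  h <- length(x) %/% 2
  r1 <- sqrt(mean(x[1:h]^2))
  r2 <- sqrt(mean(x[(h + 1):(2 * h)]^2))
  if (r1 == 0 || r2 == 0)
    return(list(reject = TRUE, ratio = NA_real_, reason = "silent_half"))
  r <- r1 / r2
  list(reject = max(r, 1 / r) > config$rms_ratio_max, ratio = r,
       reason = "rms_ratio")
}

#' Estimate the fundamental frequency of a voiced frame
#'
#' Autocorrelation method in the configured band: among local maxima whose
#' height reaches 85% of the global maximum, the smallest lag is taken
#' (guards against octave errors on pulse-like waveforms), refined by
#' parabolic interpolation.
#'
#' @param frame a frame.
#' @param config a `framing_config`.
#' @return list with `f0_hz` (NA when no admissible peak) and `f0_reject`
#'   (TRUE when f0 exceeds the analysis gate).
#' @export
estimate_f0 <- function(frame, config = framing_config()) {
  x <- frame$acc
  fs <- frame$fs
  lmin <- max(2L, floor(fs / config$f0_max_hz))
  lmax <- min(ceiling(fs / config$f0_min_hz), length(x) - 3L)
  if (lmax <= lmin) return(list(f0_hz = NA_real_, f0_reject = FALSE))
  lags <- lmin:lmax
  r <- .norm_acf(x, lags)
  pk <- which(diff(sign(diff(r))) == -2) + 1L
  if (!length(pk)) return(list(f0_hz = NA_real_, f0_reject = FALSE))
  rmax <- max(r[pk])
  if (rmax <= 0) return(list(f0_hz = NA_real_, f0_reject = FALSE))
  cand <- pk[r[pk] >= 0.85 * rmax]
  i <- cand[which.min(lags[cand])]
  # parabolic refinement around the chosen peak
  l0 <- lags[i]
  if (i > 1L && i < length(lags)) {
    y1 <- r[i - 1L]; y2 <- r[i]; y3 <- r[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (den < 0) l0 <- l0 + 0.5 * (y1 - y3) / den
  }
  f0 <- fs / l0
  list(f0_hz = f0, f0_reject = f0 > config$f0_gate_hz)
}

#' Delimit glottal cycles within a frame
#'
#' Cycle boundaries are successive flow minima near integer multiples of
#' the period 1/f0: the first boundary is the minimum in the first period,
#' each next boundary the minimum in [0.8, 1.2] periods after the previous
#' one, so every cycle's length is within 20% of 1/f0.
#'
#' @param flow_samples numeric flow samples of the frame.
#' @param f0_hz frame fundamental frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return list of cycles (each a list with `samples`, `start`, `T0`), or
#'   an empty list when fewer than two cycles fit (frame to be dropped).
#' @export
segment_cycles <- function(flow_samples, f0_hz, fs) {
  if (!is.finite(f0_hz) || f0_hz <= 0) return(list())
  T0 <- fs / f0_hz
  n <- length(flow_samples)
  if (diff(range(flow_samples)) == 0) return(list())
  b <- which.min(flow_samples[1:min(n, ceiling(T0))])
  bounds <- b
  repeat {
    lo <- bounds[length(bounds)] + floor(0.8 * T0)
    hi <- bounds[length(bounds)] + ceiling(1.2 * T0)
    if (hi > n) break
    w <- lo:hi
    bounds <- c(bounds, w[which.min(flow_samples[w])])
  }
  if (length(bounds) < 3L) return(list())
  lapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- bounds[i]:(bounds[i + 1L] - 1L)
    list(samples = flow_samples[idx], start = bounds[i],
         T0 = length(idx) / fs)
  })
}

#' Gate and annotate a stream of frames
#'
#' Applies the voicing, onset/offset and f0 gates to every frame and
#' returns a bookkeeping table; gates are evaluated independently so the
#' per-reason rejection counts are conserved.
#'
#' @param frames list from [frame_stream()].
#' @param config a `framing_config`.
#' @return data.frame with columns index, t_start, voiced, rms_reject,
#'   f0_hz, f0_reject, accepted.
#' @export
gate_frames <- function(frames, config = framing_config()) {
  rows <- lapply(frames, function(fr) {
    v <- detect_voiced(fr, config)
    g <- onset_offset_gate(fr, config)
    f0 <- if (v) estimate_f0(fr, config) else list(f0_hz = NA_real_, f0_reject = FALSE)
    if (v && is.na(f0$f0_hz)) v <- FALSE   # no admissible peak: reclassify
    data.frame(index = fr$index, t_start = fr$t_start, voiced = v,
               rms_reject = isTRUE(g$reject), f0_hz = f0$f0_hz,
               f0_reject = isTRUE(f0$f0_reject))
  })
  out <- do.call(rbind, rows)
  out$accepted <- out$voiced & !out$rms_reject & !out$f0_reject
  out
}
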