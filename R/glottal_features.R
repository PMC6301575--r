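## The eleven frame-based glottal airflow measures. Flow is handled in
## mL/s internally; MFDR is reported in L/s^2.

#' Peak-to-peak flow of one glottal cycle (ACFL)
#'
#' @param cycle a cycle from [segment_cycles()] or a numeric vector.
#' @return peak-to-peak amplitude in mL/s.
#' @export
acfl <- function(cycle) {
  x <- if (is.list(cycle)) cycle$samples else cycle
  if (!length(x)) stop("acfl: empty cycle")
  max(x) - min(x)
}

#' Maximum flow declination rate of one cycle (MFDR)
#'
#' Most negative value of the first-difference derivative of the cycle
#' flow, converted from mL/s^2 to L/s^2.
#'
#' @param cycle a cycle or numeric vector (mL/s).
#' @param fs sampling rate (Hz).
#' @return MFDR in L/s^2 (negative).
#' @export
mfdr <- function(cycle, fs) {
  x <- if (is.list(cycle)) cycle$samples else cycle
  if (length(x) < 3L) stop("mfdr: need at least 3 samples")
  min(diff(x)) * fs / 1000
}

#' Open and speed quotient of one cycle
#'
#' Robust line construction: on each flank a line is drawn from the cycle
#' peak through the flank point at the flank's median amplitude, and
#' extended to the level at which 80% of the peak-to-peak amplitude below
#' the peak is passed; the two crossing abscissae delimit the open phase.
#' t1 is the opening (start to peak) and t2 the closing (peak to end)
#' duration; OQ = (t1 + t2)/T0, SQ = t1/t2.
#'
#' @param cycle a cycle (list with `samples`, `T0`) or numeric vector.
#' @param fs sampling rate (Hz), required when `cycle` is a bare vector.
#' @return list with `OQ`, `SQ`, `t1`, `t2`, or NULL when a flank is flat
#'   (cycle skipped).
#' @export
oq_sq <- function(cycle, fs = NULL) {
  if (is.list(cycle)) {
    x <- cycle$samples
    T0 <- cycle$T0
    if (is.null(fs)) fs <- length(x) / T0
  } else {
    x <- cycle
    if (is.null(fs)) stop("oq_sq: fs required for a bare vector")
    T0 <- length(x) / fs
  }
  n <- length(x)
  p <- which.max(x)
  if (p <= 1L || p >= n) return(NULL)
  amp <- max(x) - min(x)
  if (amp == 0) return(NULL)
  level <- x[p] - 0.8 * amp
  flank_cross <- function(side) {
    idx <- if (side == "left") p:1 else p:n
    med <- stats::median(x[idx])
    # first sample at or below the flank median, walking away from the peak
    k <- which(x[idx] <= med)[1]
    if (is.na(k) || k == 1L) return(NA_real_)
    i_med <- idx[k]
    slope <- (x[p] - x[i_med]) / (p - i_med)   # signed in sample units
    if (slope == 0 || !is.finite(slope)) return(NA_real_)
    p + (level - x[p]) / slope
  }
  a_start <- flank_cross("left")
  a_end <- flank_cross("right")
  if (is.na(a_start) || is.na(a_end)) return(NULL)
  t1 <- (p - a_start) / fs
  t2 <- (a_end - p) / fs
  if (t1 <= 0 || t2 <= 0) return(NULL)
  list(OQ = (t1 + t2) / T0, SQ = t1 / t2, t1 = t1, t2 = t2)
}

#' Normalized amplitude quotient
#'
#' NAQ = ACFL / (|MFDR| * T0) with ACFL converted to L/s so the quotient
#' is dimensionless.
#'
#' @param acfl_mls ACFL in mL/s.
#' @param mfdr_ls2 MFDR in L/s^2 (sign ignored).
#' @param T0_s glottal period in seconds.
#' @return NAQ (dimensionless).
#' @export
naq <- function(acfl_mls, mfdr_ls2, T0_s) {
  if (any(mfdr_ls2 == 0) || any(T0_s <= 0))
    stop("naq: undefined for zero MFDR or nonpositive period")
  (acfl_mls / 1000) / (abs(mfdr_ls2) * T0_s)
}

#' Spectral measures H1-H2 and HRF of a frame
#'
#' Harmonic amplitudes A_k are picked as spectral peaks within +/- f0/4 of
#' k*f0 on the Hann-windowed, zero-padded amplitude spectrum; when no peak
#' exists in the search band the amplitude at the bin nearest k*f0 is
#' used. H1-H2 = 20 log10(A1/A2); HRF = 20 log10(sum(A2..A8)/A1), the
#' upper-harmonics-to-fundamental convention.
#'
#' @param flow_samples frame flow samples.
#' @param f0_hz frame fundamental frequency.
#' @param fs sampling rate (Hz).
#' @param nfft zero-padded FFT length (default 8192).
#' @return list with `H1H2` and `HRF` in dB, and the amplitudes `A`.
#' @export
spectral_measures <- function(flow_samples, f0_hz, fs, nfft = 8192) {
  x <- flow_samples - mean(flow_samples)
  n <- length(x)
  spec <- Mod(fft(c(x * .hann(n), numeric(nfft - n))))[1:(nfft %/% 2)]
  fbin <- fs / nfft
  A <- vapply(1:8, function(k) {
    ctr <- k * f0_hz
    lo <- max(1L, floor((ctr - f0_hz / 4) / fbin) + 1L)
    hi <- min(length(spec), ceiling((ctr + f0_hz / 4) / fbin) + 1L)
    if (lo > hi) return(spec[min(length(spec), round(ctr / fbin) + 1L)])
    max(spec[lo:hi])
  }, numeric(1))
  if (any(A[1:2] == 0)) return(list(H1H2 = NA_real_, HRF = NA_real_, A = A))
  list(H1H2 = 20 * log10(A[1] / A[2]),
       HRF = 20 * log10(sum(A[2:8]) / A[1]),
       A = A)
}

#' SPL calibration coefficients
#'
#' Daily linear regression mapping accelerometer level to acoustic SPL:
#' y = m x + b with x the frame acceleration RMS in dB (20 log10).
#'
#' @param slope m (> 0).
#' @param intercept b.
#' @param day calibration day.
#' @return object of class `spl_calibration`.
#' @export
spl_calibration <- function(slope = 1, intercept = 0, day = 1L) {
  if (!is.finite(slope) || slope <= 0) stop("spl_calibration: slope must be > 0")
  structure(list(slope = slope, intercept = intercept, day = day),
            class = "spl_calibration")
}

#' Estimate SPL of a frame from the accelerometer channel
#'
#' @param acc_samples frame acceleration samples.
#' @param cal an `spl_calibration` (same-day, else nearest-day, chosen by
#'   the caller).
#' @return estimated SPL in dB.
#' @export
spl_estimate <- function(acc_samples, cal) {
  stopifnot(inherits(cal, "spl_calibration"))
  r <- sqrt(mean(acc_samples^2))
  if (r == 0) return(NA_real_)
  cal$slope * (20 * log10(r)) + cal$intercept
}

#' SPL-normalized and logarithmic derived measures
#'
#' logX = 10 log10 |X|^2; X' = SPL / logX.
#'
#' @param acfl_mls ACFL (mL/s), nonzero.
#' @param mfdr_ls2 MFDR (L/s^2), nonzero.
#' @param spl_db estimated SPL (dB), may be NA (then the primed measures
#'   are NA).
#' @return list with `logACFL`, `logMFDR` (dB) and `ACFLp`, `MFDRp`.
#' @export
derived_measures <- function(acfl_mls, mfdr_ls2, spl_db = NA_real_) {
  if (any(acfl_mls == 0) || any(mfdr_ls2 == 0))
    stop("derived_measures: zero input")
  la <- 10 * log10(acfl_mls^2)
  lm <- 10 * log10(mfdr_ls2^2)
  list(logACFL = la, logMFDR = lm,
       ACFLp = spl_db / la, MFDRp = spl_db / lm)
}

#' Compute the eleven measures for one accepted frame
#'
#' Cycle-based measures (ACFL, MFDR, OQ, SQ, NAQ) are averaged over all
#' accepted cycles in the frame; spectral measures are computed once per
#' frame. Frames with fewer than two segmentable cycles, or whose cycles
#' all fail the quotient construction, yield NULL.
#'
#' @param frame a frame from [frame_stream()].
#' @param f0_hz frame fundamental frequency.
#' @param spl_cal optional `spl_calibration` for the primed measures.
#' @return one-row data.frame of the 11 measures plus `n_cycles`, or NULL.
#' @export
frame_features <- function(frame, f0_hz, spl_cal = NULL) {
  cycles <- segment_cycles(frame$flow, f0_hz, frame$fs)
  if (length(cycles) < 2L) return(NULL)
  per <- lapply(cycles, function(cy) {
    q <- oq_sq(cy)
    if (is.null(q)) return(NULL)
    a <- acfl(cy)
    m <- mfdr(cy, frame$fs)
    if (m == 0) return(NULL)
    c(ACFL = a, MFDR = m, OQ = q$OQ, SQ = q$SQ,
      NAQ = naq(a, m, cy$T0))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) return(NULL)
  avg <- colMeans(do.call(rbind, per))
  sm <- spectral_measures(frame$flow, f0_hz, frame$fs)
  spl <- if (is.null(spl_cal)) NA_real_ else spl_estimate(frame$acc, spl_cal)
  dm <- derived_measures(avg["ACFL"], avg["MFDR"], spl)
  data.frame(index = frame$index, f0_hz = f0_hz, n_cycles = length(per),
             ACFL = avg[["ACFL"]], MFDR = avg[["MFDR"]], OQ = avg[["OQ"]],
             SQ = avg[["SQ"]], NAQ = avg[["NAQ"]],
             H1H2 = sm$H1H2, HRF = sm$HRF,
             logACFL = dm$logACFL, logMFDR = dm$logMFDR,
             ACFLp = dm$ACFLp, MFDRp = dm$MFDRp, SPL = spl)
}

#' Frame, gate and featurize a flow stream
#'
#' End-to-end per-frame analysis: segmentation into 50 ms frames, the
#' three gates, and feature extraction on accepted frames.
#'
#' @param flow a `glottal_flow`.
#' @param acc_sig optional `acc_signal` (for the VAD and SPL channels).
#' @param config a `framing_config`.
#' @param spl_cal optional `spl_calibration`.
#' @return list with `frames` (the gate table from [gate_frames()]) and
#'   `features` (data.frame, one row per accepted frame).
#' @export
extract_features <- function(flow, acc_sig = NULL,
                             config = framing_config(), spl_cal = NULL) {
  frames <- frame_stream(flow, acc_sig, config)
  gates <- gate_frames(frames, config)
  keep <- which(gates$accepted)
  feats <- lapply(keep, function(i)
    frame_features(frames[[i]], gates$f0_hz[i], spl_cal))
  feats <- feats[!vapply(feats, is.null, logical(1))]
  list(frames = gates,
       features = if (length(feats)) do.call(rbind, feats) else NULL)
}
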