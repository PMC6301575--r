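#' Accelerometer signal
#'
#' Container for a calibrated neck-surface acceleration waveform. Samples are
#' in acceleration units (cm/s^2 after sensitivity calibration); the nominal
#' ambulatory sampling rate is 11025 Hz.
#'
#' @param samples numeric vector of finite samples.
#' @param fs sampling rate in Hz (default 11025).
#' @param subject optional subject identifier.
#' @param day optional day identifier.
#' @param t0 start time offset in seconds.
#' @return An object of class `acc_signal`.
#' @export
acc_signal <- function(samples, fs = 11025, subject = NA_character_,
                       day = NA_integer_, t0 = 0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("acc_signal: samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("acc_signal: fs must be a positive scalar")
  structure(list(samples = samples, fs = fs, subject = subject,
                 day = day, t0 = t0),
            class = "acc_signal")
}

#' Glottal airflow signal
#'
#' AC-coupled glottal airflow estimate in mL/s. The accelerometer is an AC
#' sensor, so the estimated flow carries no DC component; constructors remove
#' any residual mean unless `ac_couple = FALSE`.
#'
#' @param samples numeric vector (mL/s).
#' @param fs sampling rate in Hz.
#' @param ac_couple subtract the mean on construction (default TRUE).
#' @param provenance optional list recording the Q set / filter used.
#' @return An object of class `glottal_flow`.
#' @export
glottal_flow <- function(samples, fs = 11025, ac_couple = TRUE,
                         provenance = list()) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("glottal_flow: samples must be finite")
  if (ac_couple && length(samples)) samples <- samples - mean(samples)
  structure(list(samples = samples, fs = fs, provenance = provenance),
            class = "glottal_flow")
}

#' @export
print.acc_signal <- function(x, ...) {
  cat(sprintf("<acc_signal> %d samples @ %g Hz (%.2f s)",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.na(x$subject)) cat(sprintf(", subject %s", x$subject))
  cat("\n")
  invisible(x)
}

#' @export
print.glottal_flow <- function(x, ...) {
  cat(sprintf("<glottal_flow> %d samples @ %g Hz (%.2f s), peak-to-peak %.1f mL/s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (length(x$samples)) diff(range(x$samples)) else 0))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x an `acc_signal` or `glottal_flow`.
#' @return duration in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$fs
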