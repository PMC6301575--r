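#' Build the subject-specific inverse FIR filter
#'
#' Convenience wrapper: evaluates T_skin for a Q set on the n-point DFT grid
#' and designs the inverse FIR ([design_inverse_fir()]).
#'
#' @param q a `q_set`.
#' @param acc an `accelerometer_spec`.
#' @param fs sampling rate (Hz).
#' @param n_taps filter length (default 1102).
#' @param branches optional precomputed subglottal branches on the same
#'   (oversampled) grid.
#' @param oversample design-grid oversampling factor (default 4).
#' @return a `fir_filter`.
#' @export
ibif_filter <- function(q = q_set(), acc = accelerometer_spec(), fs = 11025,
                        n_taps = 1102, branches = NULL, oversample = 4) {
  f <- (1:((n_taps * oversample) %/% 2)) * fs / (n_taps * oversample)
  tsk <- skin_transfer(q, acc, f, branches = branches)
  design_inverse_fir(tsk, acc, n_taps = n_taps, fs = fs,
                     oversample = oversample)
}

# FFT linear convolution of x with taps h (length n), returning the "same"
# segment aligned so that sample k of the output corresponds to sample k of
# x filtered with the centering delay removed.
.fft_conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  Re(fft(fft(c(x, numeric(nfft - length(x)))) *
         fft(c(h, numeric(nfft - length(h)))), inverse = TRUE))[1:n] / nfft
}

#' Estimate the glottal airflow from an accelerometer signal
#'
#' Convolves the acceleration signal with the inverse FIR in consecutive
#' chunks (default one hour) using overlap-save with an overlap of
#' n_taps - 1 samples, so the concatenated output is identical to a
#' single-pass convolution up to floating-point round-off. The filter's
#' centering group delay is removed; the output has the input's length.
#'
#' @param acc_sig an `acc_signal`.
#' @param fir a `fir_filter` designed at the signal's sampling rate.
#' @param chunk_s chunk length in seconds (default 3600).
#' @return a `glottal_flow` (mL/s, AC-coupled).
#' @export
estimate_glottal_flow <- function(acc_sig, fir, chunk_s = 3600) {
  stopifnot(inherits(acc_sig, "acc_signal"), inherits(fir, "fir_filter"))
  if (!isTRUE(all.equal(acc_sig$fs, fir$fs)))
    stop("estimate_glottal_flow: sampling-rate mismatch between signal and filter")
  x <- acc_sig$samples
  n <- length(x)
  if (n == 0) return(glottal_flow(numeric(0), fs = acc_sig$fs))
  m <- length(fir$h)
  L <- max(as.integer(round(chunk_s * acc_sig$fs)), m)
  # full linear convolution assembled chunkwise (overlap-save)
  full <- numeric(n + m - 1L)
  start <- 1L
  while (start <= n) {
    stop_i <- min(start + L - 1L, n)
    pre <- max(start - (m - 1L), 1L)
    seg <- x[pre:stop_i]
    conv <- .fft_conv_full(seg, fir$h)
    # valid region of this chunk in the full convolution:
    out_lo <- start
    out_hi <- stop_i
    local_lo <- (start - pre) + 1L
    full[out_lo:out_hi] <- conv[local_lo:(local_lo + (out_hi - out_lo))]
    if (stop_i == n) {
      # tail of the final chunk completes the full convolution
      full[(n + 1L):(n + m - 1L)] <-
        conv[(local_lo + (out_hi - out_lo) + 1L):length(conv)]
    }
    start <- stop_i + 1L
  }
  # remove the centering delay; keep input length
  y <- full[(fir$delay + 1L):(fir$delay + n)]
  glottal_flow(y, fs = acc_sig$fs,
               provenance = list(n_taps = fir$n_taps, delay = fir$delay))
}
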