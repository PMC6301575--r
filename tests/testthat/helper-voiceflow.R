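# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# transfer grid at the ambulatory rate (a few seconds to build)
cached_grid <- function() {
  if (is.null(.fixtures$grid))
    .fixtures$grid <- transfer_grid(fs = 11025)
  .fixtures$grid
}

# independent geometry oracle for the open/speed-quotient line
# construction on an ideal piecewise-linear pulse: anchors at the flank
# midpoints, lines equal the flanks, crossings at the 80%-of-amplitude
# level, so each open-phase arm measures 0.8 of its true duration.
oracle_line_quotients <- function(oq, sq) {
  list(OQ = 0.8 * oq, SQ = sq)
}

# brute-force seven summary statistics (moment formulas written out)
oracle_summary_stats <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  c(mean = m,
    median = stats::median(x),
    p5 = as.numeric(stats::quantile(x, 0.05, type = 7)),
    p95 = as.numeric(stats::quantile(x, 0.95, type = 7)),
    sd = stats::sd(x),
    skew = mean((x - m)^3) / m2^1.5,
    kurt = mean((x - m)^4) / m2^2)
}

# exhaustive-k Benjamini-Hochberg oracle
oracle_bh <- function(p, m, alpha) {
  ps <- sort(p)
  L <- 0L
  for (k in seq_along(ps)) if (ps[k] <= k / m * alpha) L <- k
  if (L == 0L) rep(FALSE, length(p)) else p <= ps[L]
}

# direct-geometry measurement of a clean pulse train: per-cycle
# peak-to-peak and open-phase spans read straight off the waveform,
# independent of the package's cycle/feature code
oracle_pulse_geometry <- function(gf) {
  truth <- attr(gf, "truth")
  x <- gf$samples
  base <- min(x)
  out <- lapply(seq_len(nrow(truth)), function(i) {
    idx <- truth$start[i]:(truth$start[i] + truth$n[i] - 1L)
    cyc <- x[idx]
    open <- which(cyc > base + 1e-9 * (max(x) - base))
    c(acfl = max(cyc) - min(cyc),
      oq = length(open) / length(cyc))
  })
  as.data.frame(do.call(rbind, out))
}
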