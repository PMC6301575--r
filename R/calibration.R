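## Subject-specific calibration: NWAE objective, time alignment, particle
## swarm search over the Q factors and a residual delay.

#' NWAE derivative-order weights
#'
#' @param w numeric length-3 weights for derivative orders 0, 1, 2; each in
#'   [0, 1], summing to 1. Default 1/3 each.
#' @return object of class `nwae_weights`.
#' @export
nwae_weights <- function(w = rep(1 / 3, 3)) {
  w <- as.numeric(w)
  if (length(w) != 3L || any(w < 0) || any(w > 1) ||
      abs(sum(w) - 1) > 1e-9)
    stop("nwae_weights: need three weights in [0,1] summing to 1")
  structure(list(w = w), class = "nwae_weights")
}

#' Normalized weighted absolute error between two flow signals
#'
#' NWAE = sum_i w_i e_i, where e_i is the sum of absolute differences of
#' the (i-1)-th discrete derivative of reference and estimate, normalized
#' by the sum of absolute values of the reference derivative. Both signals
#' are trimmed to N - 2 d0 samples: the estimate on indices
#' [d0, N-1-d0] and the reference on the delayed range [d0+d, N-1-d0+d]
#' (0-based), so a residual delay d within +/- d0 can be scored.
#'
#' @param ref reference (mask-derived) flow samples.
#' @param est estimated flow samples, same length N.
#' @param w an `nwae_weights`.
#' @param d integer delay applied to the reference indices, |d| <= d0.
#' @param d0 trim half-width in samples (>= |d|).
#' @return nonnegative error; 0 iff the trimmed signals are identical.
#' @export
nwae <- function(ref, est, w = nwae_weights(), d = 0L, d0 = 0L) {
  stopifnot(inherits(w, "nwae_weights"))
  N <- length(est)
  if (length(ref) != N) stop("nwae: signals must share length")
  d <- as.integer(round(d)); d0 <- as.integer(d0)
  if (abs(d) > d0) stop("nwae: |d| must not exceed d0")
  if (N - 2L * d0 < 4L) stop("nwae: signals too short for the trim")
  et <- est[(d0 + 1L):(N - d0)]
  rt <- ref[(d0 + d + 1L):(N - d0 + d)]
  total <- 0
  for (i in 1:3) {
    if (i > 1) { et <- diff(et); rt <- diff(rt) }
    den <- sum(abs(rt))
    if (den == 0) stop("nwae: zero-energy reference derivative (order ",
                       i - 1, ")")
    total <- total + w$w[i] * sum(abs(rt - et)) / den
  }
  total
}

#' Inverse filter the oral-airflow (mask) channel
#'
#' Band-passes the sustained-vowel segment to the mask band (60-1100 Hz)
#' and removes the first vocal-tract resonance with a single notch
#' (anti-resonance) filter constrained to unity gain at DC. The resonance
#' frequency and bandwidth come from closed-phase covariance analysis: a
#' second-order all-pole fit is solved by least squares on short sliding
#' segments of the differenced signal, and the segments with the smallest
#' normalized residual -- the free-decay intervals of the closed glottal
#' phase, where the vocal tract rings without excitation -- vote by
#' median for the pole in the search band.
#'
#' @param mask_samples oral airflow samples.
#' @param fs sampling rate (Hz).
#' @param band mask passband (Hz), default c(60, 1100).
#' @param formant_band resonance search band (Hz), default c(300, 1200).
#' @param f0_hz optional fundamental; estimated from the signal when NULL.
#' @param n_vote number of lowest-residual segments pooled (default 30).
#' @return list with `flow` (reference flow samples), `formant_hz`,
#'   `bandwidth_hz`, `f0_hz`, and `notch` (b, a coefficients).
#' @export
inverse_filter_oral_airflow <- function(mask_samples, fs,
                                        band = c(60, 1100),
                                        formant_band = c(300, 1200),
                                        f0_hz = NULL, n_vote = 30) {
  if (is.null(f0_hz)) {
    lags <- max(2L, floor(fs / 500)):min(ceiling(fs / 70),
                                         length(mask_samples) - 3L)
    f0_hz <- fs / lags[which.max(.norm_acf(mask_samples, lags))]
  }
  xd <- diff(mask_samples)                 # removes the closed-phase pedestal
  seg_len <- max(8L, round(0.3 * fs / f0_hz))
  starts <- seq(3L + seg_len, length(xd) - seg_len, by = 2L)
  est <- lapply(starts, function(s) {
    idx <- s:(s + seg_len - 1L)
    y <- xd[idx]
    fit <- stats::lm.fit(cbind(xd[idx - 1L], xd[idx - 2L]), y)
    a <- fit$coefficients
    if (any(is.na(a))) return(NULL)
    p <- 1 / polyroot(c(1, -a))
    i <- which.max(Mod(p))
    c(F = abs(Arg(p[i])) * fs / (2 * pi),
      B = -fs * log(Mod(p[i])) / pi,
      r2 = sum(fit$residuals^2) / max(sum(y^2), 1e-300))
  })
  est <- do.call(rbind, est)
  ok <- est[, "F"] >= formant_band[1] & est[, "F"] <= formant_band[2] &
    est[, "B"] > 0 & is.finite(est[, "r2"])
  if (sum(ok) < 3)
    stop("inverse_filter_oral_airflow: no spectral peak in the formant band")
  est <- est[ok, , drop = FALSE]
  best <- est[order(est[, "r2"])[seq_len(min(n_vote, nrow(est)))], ,
              drop = FALSE]
  formant_hz <- stats::median(best[, "F"])
  bandwidth_hz <- stats::median(best[, "B"])
  r <- exp(-pi * bandwidth_hz / fs)
  th <- 2 * pi * formant_hz / fs
  b <- c(1, -2 * r * cos(th), r^2)
  b <- b / sum(b)                          # unity gain at DC
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bp, mask_samples))
  y <- as.numeric(signal::filter(signal::Arma(b = b, a = 1), x))
  list(flow = y, formant_hz = formant_hz, bandwidth_hz = bandwidth_hz,
       f0_hz = f0_hz, notch = list(b = b, a = 1))
}

#' Coarse time alignment by cross-correlation
#'
#' Integer lag maximizing the sample cross-correlation between reference
#' and estimate within a mid-lag neighborhood of +/- one period.
#'
#' @param ref,est numeric signals of equal length.
#' @param fs sampling rate (Hz).
#' @param f0_hz period estimate; when NULL it is taken from the reference
#'   autocorrelation.
#' @return integer lag in samples (positive: `est` lags `ref`).
#' @export
coarse_align <- function(ref, est, fs, f0_hz = NULL) {
  if (stats::sd(ref) == 0 || stats::sd(est) == 0)
    stop("coarse_align: degenerate constant input")
  if (is.null(f0_hz)) {
    lags <- max(2L, floor(fs / 1000)):min(ceiling(fs / 70), length(ref) - 3L)
    r <- .norm_acf(ref, lags)
    f0_hz <- fs / lags[which.max(r)]
  }
  half <- ceiling(fs / f0_hz)
  cc <- stats::ccf(est, ref, lag.max = half, plot = FALSE)
  as.integer(cc$lag[which.max(cc$acf)])
}

#' PSO configuration
#'
#' Standard constriction-factor settings: 40 particles, inertia 0.72,
#' cognitive = social = 1.49, 200 iterations, with early stop when the
#' best objective improves by less than `tol` over `patience` iterations.
#'
#' @param n_particles swarm size.
#' @param inertia velocity inertia weight.
#' @param c_cog,c_soc cognitive and social acceleration coefficients.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the best objective.
#' @param patience iterations without `tol` improvement before stopping.
#' @param seed RNG seed (recorded in outputs).
#' @return object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 40, inertia = 0.72, c_cog = 1.49,
                       c_soc = 1.49, max_iter = 200, tol = 1e-6,
                       patience = 20, seed = 1) {
  stopifnot(n_particles >= 2, max_iter >= 1, tol > 0, patience >= 1)
  structure(list(n_particles = n_particles, inertia = inertia,
                 c_cog = c_cog, c_soc = c_soc, max_iter = max_iter,
                 tol = tol, patience = patience, seed = seed),
            class = "pso_config")
}

#' Bound-constrained particle swarm minimization
#'
#' Global-best PSO with velocity clamping to the box width, reflection at
#' the bounds, and optional integer-rounded dimensions. Deterministic
#' given the configured seed; the best objective is non-increasing over
#' iterations.
#'
#' @param fn objective function taking a numeric vector.
#' @param lower,upper box constraints.
#' @param cfg a `pso_config`.
#' @param integer_dims indices of dimensions rounded to integers before
#'   evaluation and in the result.
#' @param init optional start point seeded as the first particle (default:
#'   the box midpoint).
#' @return list with `par`, `value`, `iterations`, `trace` (best objective
#'   per iteration), `seed`.
#' @export
pso_optimize <- function(fn, lower, upper, cfg = pso_config(),
                         integer_dims = integer(0), init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower <= upper))
  rs <- .seed_guard(cfg$seed)
  on.exit(rs())
  span <- upper - lower
  np <- cfg$n_particles
  pos <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), np, d)
  pos[1, ] <- if (is.null(init)) (lower + upper) / 2 else init
  pos[1, ] <- pmin(pmax(pos[1, ], lower), upper)
  vel <- matrix(stats::runif(np * d, -1, 1), np, d) *
    matrix(span, np, d, byrow = TRUE) * 0.1
  snap <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    if (length(integer_dims)) x[integer_dims] <- round(x[integer_dims])
    x
  }
  evalf <- function(x) {
    v <- fn(snap(x))
    if (!is.finite(v)) Inf else v
  }
  pval <- apply(pos, 1, evalf)
  if (all(!is.finite(pval))) stop("pso_optimize: all particles non-finite")
  pbest <- pos
  gi <- which.min(pval)
  gbest <- pos[gi, ]; gval <- pval[gi]
  trace <- numeric(0)
  stall <- 0L
  for (it in seq_len(cfg$max_iter)) {
    r1 <- matrix(stats::runif(np * d), np, d)
    r2 <- matrix(stats::runif(np * d), np, d)
    vel <- cfg$inertia * vel +
      cfg$c_cog * r1 * (pbest - pos) +
      cfg$c_soc * r2 * (matrix(gbest, np, d, byrow = TRUE) - pos)
    vmax <- matrix(span, np, d, byrow = TRUE)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pos + vel
    # reflect at the box
    for (j in seq_len(d)) {
      below <- pos[, j] < lower[j]
      above <- pos[, j] > upper[j]
      pos[below, j] <- lower[j] + (lower[j] - pos[below, j])
      pos[above, j] <- upper[j] - (pos[above, j] - upper[j])
      pos[, j] <- pmin(pmax(pos[, j], lower[j]), upper[j])
      vel[below | above, j] <- -0.5 * vel[below | above, j]
    }
    val <- apply(pos, 1, evalf)
    imp <- val < pval
    pbest[imp, ] <- pos[imp, ]
    pval[imp] <- val[imp]
    gi <- which.min(pval)
    if (pval[gi] < gval - cfg$tol) stall <- 0L else stall <- stall + 1L
    if (pval[gi] < gval) { gval <- pval[gi]; gbest <- pbest[gi, ] }
    trace <- c(trace, gval)
    if (stall >= cfg$patience) break
  }
  list(par = snap(gbest), value = gval, iterations = length(trace),
       trace = trace, seed = cfg$seed)
}

#' Precompute subglottal branches over a (Q4, Q5) grid
#'
#' The geometry-dependent responses Zsub2 and Hsub1 are precomputed on an
#' equally spaced grid covering the Q4/Q5 bounds; lookups return the
#' nearest cell, which removes the transmission-line evaluation from the
#' PSO inner loop.
#'
#' @param bounds a `q_bounds`.
#' @param fs sampling rate (Hz).
#' @param n_taps FIR/DFT length defining the frequency grid.
#' @param spacing grid spacing in Q units (default 0.05).
#' @param oversample FIR design-grid oversampling factor (default 4).
#' @param ... passed to [tracheal_geometry()] (area, losses, termination).
#' @return object of class `transfer_grid`.
#' @export
transfer_grid <- function(bounds = q_bounds(), fs = 11025, n_taps = 1102,
                          spacing = 0.05, oversample = 4, ...) {
  q4s <- seq(bounds$lower[4], bounds$upper[4], by = spacing)
  q5s <- seq(bounds$lower[5], bounds$upper[5], by = spacing)
  f <- (1:((n_taps * oversample) %/% 2)) * fs / (n_taps * oversample)
  cells <- vector("list", length(q4s) * length(q5s))
  k <- 0L
  for (i5 in seq_along(q5s)) for (i4 in seq_along(q4s)) {
    k <- k + 1L
    q <- q_set(c(1, 1, 1, q4s[i4], q5s[i5]))
    cells[[k]] <- subglottal_branches(tracheal_geometry(q, ...), f)
  }
  structure(list(q4s = q4s, q5s = q5s, cells = cells, f = f, fs = fs,
                 n_taps = n_taps, spacing = spacing, oversample = oversample),
            class = "transfer_grid")
}

#' Nearest-cell lookup in a transfer grid
#' @param grid a `transfer_grid`.
#' @param q4,q5 geometry factors.
#' @return list with `Zsub2`, `Hsub1` of the nearest precomputed cell.
#' @export
transfer_grid_lookup <- function(grid, q4, q5) {
  i4 <- which.min(abs(grid$q4s - q4))
  i5 <- which.min(abs(grid$q5s - q5))
  grid$cells[[(i5 - 1L) * length(grid$q4s) + i4]]
}

#' Estimate subject-specific Q parameters by PSO
#'
#' Minimizes the mean NWAE over the supplied calibration gestures with
#' respect to the five Q factors and a residual integer delay d. For each
#' gesture the mask channel is inverse filtered to the reference flow, the
#' IBIF estimate at the default Q is coarse-aligned to it once, and every
#' particle then scores its FIR estimate against the reference in the
#' common mask band (both signals band-passed to 60-1100 Hz) on the
#' trimmed ranges.
#'
#' @param gestures list of `calibration_gesture` objects.
#' @param cfg a `pso_config`.
#' @param bounds a `q_bounds`.
#' @param grid optional `transfer_grid` (built on demand when NULL).
#' @param acc an `accelerometer_spec`.
#' @param n_taps FIR length (default 1102).
#' @return list with `q` (`q_set`), `d` (samples), `nwae` (final mean
#'   objective), `per_gesture` values, `pso` diagnostics, `seed`, and the
#'   grid `spacing`.
#' @export
fit_q_parameters <- function(gestures, cfg = pso_config(),
                             bounds = q_bounds(), grid = NULL,
                             acc = accelerometer_spec(), n_taps = 1102) {
  if (!length(gestures)) stop("fit_q_parameters: need at least one gesture")
  if (inherits(gestures, "calibration_gesture")) gestures <- list(gestures)
  fs <- gestures[[1]]$fs
  if (is.null(grid)) grid <- transfer_grid(bounds, fs = fs, n_taps = n_taps)
  bp <- signal::butter(2, c(60, 1100) / (fs / 2), type = "pass")
  fir0 <- ibif_filter(q_set(), acc, fs = fs, n_taps = n_taps,
                      branches = transfer_grid_lookup(grid, 1, 1))
  prep <- lapply(gestures, function(g) {
    ref <- inverse_filter_oral_airflow(g$mask, fs)$flow
    est0 <- estimate_glottal_flow(g$acc, fir0)$samples
    est0 <- as.numeric(signal::filtfilt(bp, est0))
    lag <- coarse_align(ref, est0, fs, f0_hz = g$f0)
    # absorb the coarse lag by shifting the reference onto the estimate:
    # lag > 0 means the estimate lags the reference, so delay the reference
    if (lag > 0) ref <- c(numeric(lag), ref[1:(length(ref) - lag)])
    if (lag < 0) ref <- c(ref[(1 - lag):length(ref)], numeric(-lag))
    d0 <- max(4L, as.integer(round(fs / g$f0 / 2)))
    # discard filter edge transients on both channels before scoring
    margin <- as.integer(round(0.05 * fs))
    keep <- (margin + 1L):(length(ref) - margin)
    list(ref = ref[keep], keep = keep, acc_sig = g$acc, d0 = d0, lag = lag)
  })
  objective <- function(par) {
    q <- q_set(par[1:5])
    d <- as.integer(round(par[6]))
    br <- transfer_grid_lookup(grid, par[4], par[5])
    fir <- ibif_filter(q, acc, fs = fs, n_taps = n_taps, branches = br)
    vals <- vapply(prep, function(pg) {
      est <- estimate_glottal_flow(pg$acc_sig, fir)$samples
      est <- as.numeric(signal::filtfilt(bp, est))[pg$keep]
      dd <- max(min(d, pg$d0), -pg$d0)
      nwae(pg$ref, est, d = dd, d0 = pg$d0)
    }, numeric(1))
    mean(vals)
  }
  d0max <- max(vapply(prep, `[[`, integer(1), "d0"))
  res <- pso_optimize(objective, lower = c(bounds$lower, -d0max),
                      upper = c(bounds$upper, d0max), cfg = cfg,
                      integer_dims = 6L, init = c(rep(1, 5), 0))
  # deterministic local refinement: the objective is smooth in the skin
  # factors (q1-q3) once the geometry cell and delay are fixed, so polish
  # them by Nelder-Mead over the 3x3 neighborhood of the best (q4, q5)
  # cell; then rescan the integer delay
  clamp13 <- function(p) pmin(pmax(p, bounds$lower[1:3]), bounds$upper[1:3])
  for (dq4 in c(-1, 0, 1) * grid$spacing) {
    for (dq5 in c(-1, 0, 1) * grid$spacing) {
      q45 <- pmin(pmax(res$par[4:5] + c(dq4, dq5), bounds$lower[4:5]),
                  bounds$upper[4:5])
      o <- stats::optim(res$par[1:3], function(p)
        objective(c(clamp13(p), q45, res$par[6])),
        method = "Nelder-Mead",
        control = list(maxit = 80, reltol = 1e-6))
      if (o$value < res$value) {
        res$value <- o$value
        res$par <- c(clamp13(o$par), q45, res$par[6])
      }
    }
  }
  dvals <- vapply(-d0max:d0max, function(d)
    objective(c(res$par[1:5], d)), numeric(1))
  if (min(dvals) < res$value) {
    res$value <- min(dvals)
    res$par[6] <- (-d0max:d0max)[which.min(dvals)]
  }
  per <- tryCatch({
    q <- q_set(res$par[1:5])
    br <- transfer_grid_lookup(grid, res$par[4], res$par[5])
    fir <- ibif_filter(q, acc, fs = fs, n_taps = n_taps, branches = br)
    vapply(prep, function(pg) {
      est <- as.numeric(signal::filtfilt(bp,
        estimate_glottal_flow(pg$acc_sig, fir)$samples))[pg$keep]
      dd <- max(min(res$par[6], pg$d0), -pg$d0)
      nwae(pg$ref, est, d = dd, d0 = pg$d0)
    }, numeric(1))
  }, error = function(e) rep(NA_real_, length(prep)))
  lag1 <- prep[[1]]$lag
  list(q = q_set(res$par[1:5]),
       d = as.integer(res$par[6]) - as.integer(lag1),
       d_residual = as.integer(res$par[6]), align_lag = lag1,
       nwae = res$value, per_gesture = per,
       pso = list(iterations = res$iterations, trace = res$trace),
       seed = cfg$seed, spacing = grid$spacing)
}
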