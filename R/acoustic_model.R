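## Mechano-acoustic model of the subglottal tract and neck skin.
## All acoustic quantities are in CGS units: impedances in dyn.s/cm^5,
## flows in cm^3/s (= mL/s), pressures in dyn/cm^2.

# air constants (CGS, body temperature)
.AIR <- list(rho = 1.14e-3,   # density g/cm^3
             c   = 3.5e4,     # sound speed cm/s
             mu  = 1.86e-4,   # shear viscosity g/(cm s)
             eta = 1.4,       # adiabatic constant
             lam = 5.5e-5,    # heat conduction coefficient cal/(cm s K)
             cp  = 0.24)      # specific heat cal/(g K)

#' Accelerometer specification
#'
#' Contact area and moving mass of the neck-surface accelerometer. Defaults
#' approximate a light-weight clinical sensor (BU-series form factor).
#'
#' @param area_cm2 contact area A_acc in cm^2 (> 0).
#' @param mass_g sensor mass M_acc in g (>= 0).
#' @return object of class `accelerometer_spec`.
#' @export
accelerometer_spec <- function(area_cm2 = 0.44, mass_g = 0.28) {
  if (!is.numeric(area_cm2) || area_cm2 <= 0)
    stop("accelerometer_spec: area_cm2 must be > 0")
  if (!is.numeric(mass_g) || mass_g < 0)
    stop("accelerometer_spec: mass_g must be >= 0")
  structure(list(area_cm2 = area_cm2, mass_g = mass_g),
            class = "accelerometer_spec")
}

#' Subject scale factors Q
#'
#' Five dimensionless factors scaling the default skin resistance, skin
#' mass, skin stiffness, tracheal length and accelerometer position. The
#' all-ones set reproduces the default model.
#'
#' @param q numeric length-5 vector, all positive.
#' @return object of class `q_set`.
#' @export
q_set <- function(q = c(1, 1, 1, 1, 1)) {
  q <- as.numeric(q)
  if (length(q) != 5L || any(!is.finite(q)) || any(q <= 0))
    stop("q_set: need 5 finite positive factors")
  structure(list(q = q), class = "q_set")
}

#' Bounds for the Q search space
#'
#' Physiological-plausibility box for the five Q factors. Defaults allow a
#' four-fold change in the skin mechanical parameters and a 30% change in
#' tracheal geometry; the all-ones default set lies inside.
#'
#' @param lower,upper numeric length-5 vectors.
#' @return object of class `q_bounds`.
#' @export
q_bounds <- function(lower = c(0.25, 0.25, 0.25, 0.7, 0.7),
                     upper = c(4, 4, 4, 1.3, 1.3)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 5L || length(upper) != 5L || any(lower >= upper))
    stop("q_bounds: need lower < upper, length 5")
  if (any(lower > 1) || any(upper < 1))
    warning("q_bounds: default all-ones Q outside bounds")
  structure(list(lower = lower, upper = upper), class = "q_bounds")
}

#' Skin mechanical parameters implied by a Q set
#'
#' Default (Q = 1) values: resistance 2320 g/(s cm^2), mass per area
#' 2.4 g/cm^2, stiffness 491000 dyn/cm^3.
#'
#' @param q a `q_set`.
#' @return list with `Rm`, `Mm`, `Km`.
#' @export
skin_params <- function(q = q_set()) {
  stopifnot(inherits(q, "q_set"))
  list(Rm = 2320 * q$q[1], Mm = 2.4 * q$q[2], Km = 491000 * q$q[3])
}

#' Tracheal geometry implied by a Q set
#'
#' The trachea is modeled as a uniform lossy cylindrical line of length
#' 10*Q4 cm split at the accelerometer position 5*Q5 cm (from the glottis)
#' into sections sub1 (glottis to sensor) and sub2 (sensor to bronchi).
#'
#' @param q a `q_set`.
#' @param area_cm2 uniform cross-sectional area (default 2.5 cm^2).
#' @param seg_len_cm nominal segment length for the lumped line (default 0.5).
#' @param losses include viscothermal boundary-layer losses (default TRUE).
#' @param termination distal (bronchial) termination: `"lung"` (a
#'   resistive load of half the characteristic impedance, the default --
#'   absorptive enough to give the broad subglottal resonances seen in
#'   neck-surface signals while keeping the tracheal-length factor
#'   identifiable), `"pressure_release"` (Z = 0), `"characteristic"`
#'   (rho*c/A, quasi-anechoic; makes the input impedance
#'   length-independent), `"closed"` (Z = Inf), or a numeric impedance in
#'   dyn.s/cm^5.
#' @return object of class `tracheal_geometry`.
#' @export
tracheal_geometry <- function(q = q_set(), area_cm2 = 2.5, seg_len_cm = 0.5,
                              losses = TRUE, termination = "lung") {
  stopifnot(inherits(q, "q_set"))
  length_cm <- 10 * q$q[4]
  acc_position_cm <- 5 * q$q[5]
  if (acc_position_cm <= 0 || acc_position_cm >= length_cm)
    stop("tracheal_geometry: accelerometer position must lie inside the trachea")
  if (area_cm2 <= 0) stop("tracheal_geometry: area must be > 0")
  structure(list(length_cm = length_cm, acc_position_cm = acc_position_cm,
                 area_cm2 = area_cm2, seg_len_cm = seg_len_cm,
                 losses = losses, termination = termination),
            class = "tracheal_geometry")
}

#' Frequency grid of an n-point DFT
#'
#' @param fs sampling rate (Hz).
#' @param n DFT length.
#' @return positive-frequency bin centers 0, fs/n, ..., fs/2 (Hz).
#' @export
freq_grid <- function(fs, n) (0:(n %/% 2)) * fs / n

#' Frequency response container
#'
#' @param values complex values on the grid.
#' @param f frequency grid (Hz), same length.
#' @param fs sampling rate the grid belongs to.
#' @return object of class `freq_response`.
#' @export
freq_response <- function(values, f, fs) {
  if (length(values) != length(f)) stop("freq_response: length mismatch")
  structure(list(values = as.complex(values), f = as.numeric(f), fs = fs),
            class = "freq_response")
}

#' @export
print.freq_response <- function(x, ...) {
  cat(sprintf("<freq_response> %d points, %g-%g Hz (fs %g)\n",
              length(x$f), min(x$f), max(x$f), x$fs))
  invisible(x)
}

#' Export a frequency response as a data frame
#' @param x a `freq_response`.
#' @return data.frame with columns `f_hz`, `re`, `im`.
#' @export
freq_response_table <- function(x) {
  stopifnot(inherits(x, "freq_response"))
  data.frame(f_hz = x$f, re = Re(x$values), im = Im(x$values))
}

#' Mechanical load impedance of the neck skin
#'
#' Series RMK skin branch plus the accelerometer radiation mass, divided by
#' the sensor contact area:
#' Z_skin = (1/A_acc) (R_m + jw M_m - j K_m / w + jw M_acc / A_acc).
#' The stiffness reactance is the mechanical -j K/w form.
#'
#' @param params list with Rm, Mm, Km (see [skin_params()]).
#' @param acc an `accelerometer_spec`.
#' @param f frequency grid in Hz, strictly positive.
#' @return `freq_response` of the acoustic skin impedance (dyn.s/cm^5).
#' @export
skin_impedance <- function(params, acc = accelerometer_spec(), f) {
  stopifnot(inherits(acc, "accelerometer_spec"))
  if (any(f <= 0)) stop("skin_impedance: grid must exclude w = 0")
  w <- 2 * pi * f
  z <- (params$Rm + 1i * w * params$Mm - 1i * params$Km / w +
        1i * w * acc$mass_g / acc$area_cm2) / acc$area_cm2
  freq_response(z, f, fs = 2 * max(f))
}

# classic soft-tissue wall constants per unit area (CGS)
.WALL <- list(rw = 1600,    # resistance g s^-1 cm^-2
              mw = 1.5,     # mass g cm^-2
              kw = 3e5)     # stiffness dyn cm^-3

# per-unit-length series impedance z and shunt admittance y of a cylinder;
# losses add the viscothermal boundary layer and the yielding-wall branch
.line_zy <- function(w, area, losses) {
  a <- .AIR
  S <- 2 * sqrt(pi * area)           # perimeter
  if (losses) {
    Rl <- (S / area^2) * sqrt(w * a$rho * a$mu / 2)
    Gl <- S * (a$eta - 1) / (a$rho * a$c^2) * sqrt(w * a$lam / (2 * a$cp * a$rho))
    zw <- .WALL$rw + 1i * w * .WALL$mw - 1i * .WALL$kw / w
    Yw <- S / zw                     # yielding-wall shunt admittance
  } else {
    Rl <- 0; Gl <- 0; Yw <- 0
  }
  list(z = Rl + 1i * w * a$rho / area,
       y = Gl + Yw + 1i * w * area / (a$rho * a$c^2))
}

# chain (ABCD) matrix of a uniform lossy line of length len, vectorized in w;
# returns list of four complex vectors
.line_abcd <- function(w, len, area, losses) {
  zy <- .line_zy(w, area, losses)
  gam <- sqrt(zy$z * zy$y)
  Zc <- sqrt(zy$z / zy$y)
  gl <- gam * len
  list(A = cosh(gl), B = Zc * sinh(gl), C = sinh(gl) / Zc, D = cosh(gl))
}

.termination_z <- function(geom, w) {
  a <- .AIR
  if (is.numeric(geom$termination)) return(rep(geom$termination + 0i, length(w)))
  switch(geom$termination,
         lung             = rep(complex(real = 0.5 * a$rho * a$c / geom$area_cm2),
                                length(w)),
         characteristic   = rep(complex(real = a$rho * a$c / geom$area_cm2),
                                length(w)),
         pressure_release = rep(0 + 0i, length(w)),
         closed           = rep(complex(real = Inf), length(w)),
         stop("tracheal_geometry: unknown termination"))
}

#' Subglottal branch responses at the sensor position
#'
#' Input impedance `Zsub2` of the tracheal section below the accelerometer
#' (looking toward the bronchial termination) and flow transfer `Hsub1` of
#' the section above it (glottal flow to flow arriving at the sensor,
#' loaded by Zsub2). Both are computed from the exact chain matrices of the
#' uniform lossy line, so they are continuous in the geometry factors.
#'
#' @param geom a `tracheal_geometry`.
#' @param f frequency grid (Hz), strictly positive.
#' @return list with `Zsub2` and `Hsub1`, both `freq_response`.
#' @export
subglottal_branches <- function(geom, f) {
  stopifnot(inherits(geom, "tracheal_geometry"))
  if (any(f <= 0)) stop("subglottal_branches: grid must exclude w = 0")
  w <- 2 * pi * f
  l2 <- geom$length_cm - geom$acc_position_cm
  m2 <- .line_abcd(w, l2, geom$area_cm2, geom$losses)
  Zt <- .termination_z(geom, w)
  Zsub2 <- ifelse(is.infinite(Re(Zt)),
                  m2$A / m2$C,
                  (m2$A * Zt + m2$B) / (m2$C * Zt + m2$D))
  m1 <- .line_abcd(w, geom$acc_position_cm, geom$area_cm2, geom$losses)
  Hsub1 <- 1 / (m1$C * Zsub2 + m1$D)
  fs <- 2 * max(f)
  list(Zsub2 = freq_response(Zsub2, f, fs), Hsub1 = freq_response(Hsub1, f, fs))
}

#' Skin transfer function T_skin
#'
#' Composition T_skin(w) = Hsub1(w) Zsub2(w) jw / (Zsub2(w) + Zskin(w)):
#' glottal flow to volume acceleration at the skin surface (times -1 and
#' divided by A_acc it gives the measured skin acceleration; the inverse
#' filter divides it back out).
#'
#' @param q a `q_set`.
#' @param acc an `accelerometer_spec`.
#' @param f frequency grid (Hz), strictly positive.
#' @param geom optional `tracheal_geometry` (default derived from `q`).
#' @param branches optional precomputed output of [subglottal_branches()]
#'   on the same grid (used by the calibration transfer grid).
#' @return `freq_response` of T_skin.
#' @export
skin_transfer <- function(q = q_set(), acc = accelerometer_spec(), f,
                          geom = NULL, branches = NULL) {
  if (is.null(branches)) {
    if (is.null(geom)) geom <- tracheal_geometry(q)
    branches <- subglottal_branches(geom, f)
  }
  if (!isTRUE(all.equal(branches$Zsub2$f, f)))
    stop("skin_transfer: component responses must share the grid")
  zs <- skin_impedance(skin_params(q), acc, f)
  w <- 2 * pi * f
  tv <- branches$Hsub1$values * branches$Zsub2$values * (1i * w) /
    (branches$Zsub2$values + zs$values)
  if (any(!is.finite(tv))) stop("skin_transfer: non-finite response")
  freq_response(tv, f, fs = 2 * max(f))
}

#' Design the inverse FIR filter
#'
#' Samples the regularized inverse spectrum of T_skin on a 4x-oversampled
#' DFT grid, zeroes the DC bin, tapers bins below `dc_edge_hz` to zero with
#' a raised cosine (the accelerometer is AC-coupled and the flow estimate
#' carries no DC), takes the inverse FFT and truncates the centered
#' impulse response to `n_taps` coefficients. A mild Tikhonov floor bounds
#' the inverse gain at near-zeros of the forward transfer: frequencies the
#' forward path suppresses carry no recoverable flow, so their inverse
#' gain must not explode. The introduced group delay of n/2 samples is
#' stored in the filter and removed again by [estimate_glottal_flow()].
#'
#' @param tskin `freq_response` of T_skin on the oversampled design grid
#'   excluding DC (length `oversample * n_taps / 2`).
#' @param acc an `accelerometer_spec`.
#' @param n_taps filter length (default 1102).
#' @param fs sampling rate (default 11025 Hz).
#' @param dc_edge_hz lower band edge of the raised-cosine DC taper.
#' @param oversample design-grid oversampling factor (default 4).
#' @param tikhonov regularization strength relative to the median in-band
#'   (60-2000 Hz) magnitude of T_skin (default 0.01; 0 disables).
#' @return object of class `fir_filter` with fields `h`, `fs`, `delay`.
#' @export
design_inverse_fir <- function(tskin, acc = accelerometer_spec(),
                               n_taps = 1102, fs = 11025, dc_edge_hz = 40,
                               oversample = 4, tikhonov = 0.002) {
  half <- (n_taps * oversample) %/% 2
  if (length(tskin$values) != half)
    stop("design_inverse_fir: T_skin must be sampled on bins 1..n/2 of the oversampled grid")
  T <- tskin$values
  if (tikhonov > 0) {
    f <- (1:half) * fs / (n_taps * oversample)
    typ <- stats::median(Mod(T)[f >= 60 & f <= 2000])
    target <- -acc$area_cm2 * Conj(T) / (Mod(T)^2 + (tikhonov * typ)^2)
  } else {
    target <- -acc$area_cm2 / T
  }
  fir_from_spectrum(target, n_taps = n_taps, fs = fs, dc_edge_hz = dc_edge_hz,
                    oversample = oversample)
}

#' Build a centered real FIR from a positive-frequency target spectrum
#'
#' Shared low-level designer by oversampled frequency sampling: `target`
#' holds the desired response on the positive-frequency bins of an
#' `oversample * n_taps`-point DFT (DC is forced to zero, bins under
#' `dc_edge_hz` tapered). The long inverse DFT is centered and truncated
#' to `n_taps` coefficients under a raised-cosine edge taper, which
#' suppresses both the time-aliasing and the inter-bin ripple a direct
#' n_taps-point sampling would leave.
#'
#' @param target complex vector of length `(oversample * n_taps) %/% 2`
#'   (bins 1..N/2 of the oversampled grid).
#' @param n_taps filter length (even).
#' @param fs sampling rate (Hz).
#' @param dc_edge_hz raised-cosine taper edge; 0 disables the taper.
#' @param edge_taper fraction of the centered impulse response covered by
#'   the raised-cosine edge taper (default 0.5); 0 disables it.
#' @param dc value of the DC bin (default 0: the inverse filter passes no
#'   DC because the accelerometer is AC-coupled).
#' @param oversample design-grid oversampling factor (default 1: plain
#'   n_taps-point sampling).
#' @return `fir_filter` with coefficients `h`, rate `fs`, group `delay`
#'   (samples).
#' @export
fir_from_spectrum <- function(target, n_taps, fs, dc_edge_hz = 0,
                              edge_taper = 0.5, dc = 0, oversample = 1) {
  if (n_taps %% 2 != 0) stop("fir_from_spectrum: n_taps must be even")
  N <- n_taps * oversample
  half <- N %/% 2
  if (length(target) != half)
    stop("fir_from_spectrum: need (oversample * n_taps)/2 bins")
  f <- (1:half) * fs / N
  if (dc_edge_hz > 0) {
    tap <- ifelse(f < dc_edge_hz, 0.5 * (1 - cos(pi * f / dc_edge_hz)), 1)
    target <- target * tap
  }
  if (any(!is.finite(target)))
    stop("fir_from_spectrum: non-finite target spectrum after regularization")
  # hermitian full spectrum; the Nyquist bin must be real
  full <- complex(length.out = N)
  full[1] <- complex(real = dc)
  full[2:(half + 1)] <- target
  full[half + 1] <- complex(real = Re(target[half]))
  full[(half + 2):N] <- Conj(target[(half - 1):1])
  h <- Re(fft(full, inverse = TRUE)) / N
  h <- c(h[(half + 1):N], h[1:half])        # center energy
  ctr <- half + 1L
  h <- h[(ctr - n_taps %/% 2):(ctr + n_taps %/% 2 - 1L)]
  if (edge_taper > 0) {
    nt <- max(1L, round(n_taps * edge_taper / 2))
    ramp <- 0.5 * (1 - cos(pi * (1:nt) / nt))
    w <- rep(1, n_taps)
    w[1:nt] <- ramp
    w[(n_taps - nt + 1):n_taps] <- rev(ramp)
    h <- h * w
  }
  structure(list(h = h, fs = fs, delay = n_taps %/% 2, n_taps = n_taps),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> %d taps @ %g Hz, group delay %d samples\n",
              x$n_taps, x$fs, x$delay))
  invisible(x)
}

#' Frequency response of an FIR filter at probe frequencies
#'
#' Direct DFT evaluation (no zero-padding shortcuts), with the stored
#' centering delay removed so the value is comparable to the design target.
#'
#' @param fir a `fir_filter`.
#' @param f probe frequencies (Hz).
#' @param remove_delay divide out the centering delay (default TRUE).
#' @return complex response values.
#' @export
fir_response <- function(fir, f, remove_delay = TRUE) {
  n <- length(fir$h)
  k <- 0:(n - 1)
  vapply(f, function(fi) {
    ph <- exp(-2i * pi * fi * k / fir$fs)
    v <- sum(fir$h * ph)
    if (remove_delay) v <- v * exp(2i * pi * fi * fir$delay / fir$fs)
    v
  }, complex(1))
}

#' Forward-simulate the accelerometer signal from a glottal flow
#'
#' Applies the skin transfer in the frequency domain: the skin acceleration
#' is F^-1(-T_skin(w) U_g(w) / A_acc). This is the exact forward model the
#' inverse FIR approximately undoes; it is used to synthesize test and
#' calibration signals.
#'
#' @param flow a `glottal_flow`.
#' @param q a `q_set` (or pass `tskin_fun` for a custom transfer).
#' @param acc an `accelerometer_spec`.
#' @param tskin_fun optional function(f) returning complex T_skin values.
#' @return an `acc_signal` at the flow's sampling rate.
#' @export
forward_simulate_acceleration <- function(flow, q = q_set(),
                                          acc = accelerometer_spec(),
                                          tskin_fun = NULL) {
  stopifnot(inherits(flow, "glottal_flow"))
  x <- flow$samples
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n, 2)))
  f <- (1:(nfft %/% 2)) * flow$fs / nfft
  tv <- if (is.null(tskin_fun)) {
    skin_transfer(q, acc, f)$values
  } else {
    as.complex(tskin_fun(f))
  }
  Hfull <- complex(length.out = nfft)
  Hfull[2:(nfft %/% 2 + 1)] <- -tv / acc$area_cm2
  Hfull[nfft %/% 2 + 1] <- complex(real = Re(Hfull[nfft %/% 2 + 1]))
  Hfull[(nfft %/% 2 + 2):nfft] <- Conj(Hfull[(nfft %/% 2):2])
  X <- fft(c(x, numeric(nfft - n)))
  a <- Re(fft(X * Hfull, inverse = TRUE)) / nfft
  acc_signal(a[seq_len(n)], fs = flow$fs)
}
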