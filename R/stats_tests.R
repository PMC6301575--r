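## Window- and week-level summary statistics, normalization, paired
## hypothesis testing and Benjamini-Hochberg FDR control.

#' The seven summary statistics of a value vector
#'
#' Mean, median, 5th percentile, 95th percentile, standard deviation,
#' skewness and kurtosis. Percentiles use linear interpolation between
#' order statistics (quantile type 7); kurtosis is the non-excess
#' (Pearson) convention m4/m2^2, skewness m3/m2^(3/2). For constant input
#' the sd is 0 and skewness/kurtosis are reported as 0 (flagged upstream
#' rather than dropping the window).
#'
#' @param x numeric values (voiced-frame measures).
#' @return named numeric vector of length 7.
#' @export
summary_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(stats::setNames(rep(NA_real_, 7), .stat_names()))
  s <- stats::sd(x)
  if (n < 2 || s == 0) {
    sk <- 0; ku <- 0
  } else {
    m <- mean(x)
    m2 <- mean((x - m)^2)
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2
  }
  stats::setNames(
    c(mean(x), stats::median(x),
      stats::quantile(x, 0.05, names = FALSE, type = 7),
      stats::quantile(x, 0.95, names = FALSE, type = 7),
      if (n < 2) 0 else s, sk, ku),
    .stat_names())
}

.stat_names <- function() c("mean", "median", "p5", "p95", "sd", "skew", "kurt")

#' Frame capacity and voicing gate of the analysis window
#'
#' 5-minute windows of 50 ms frames hold 6000 frames; the 0.5% voicing
#' gate is 30 frames.
#'
#' @param window_s window length (s), default 300.
#' @param frame_s frame length (s), default 0.05.
#' @param voicing_fraction minimum voiced fraction, default 0.005.
#' @return list with `frames_per_window` and `min_voiced_frames`.
#' @export
window_arithmetic <- function(window_s = 300, frame_s = 0.05,
                              voicing_fraction = 0.005) {
  fpw <- as.integer(round(window_s / frame_s))
  list(frames_per_window = fpw,
       min_voiced_frames = as.integer(round(voicing_fraction * fpw)))
}

#' Summarize the voiced frames of one window
#'
#' @param values measure values of the window's voiced frames.
#' @param min_frames inclusion gate (default 30 of 6000).
#' @return named 7-vector, or NULL when the window is below the gate.
#' @export
summarize_window <- function(values, min_frames = 30L) {
  values <- values[is.finite(values)]
  if (length(values) < min_frames) return(NULL)
  summary_stats(values)
}

#' Week-long summary statistics for every measure
#'
#' The seven statistics of each of the eleven measures over a subject's
#' full week of voiced frames: a named 77-vector.
#'
#' @param frame_table data.frame with the measure columns (see
#'   [measure_names()]).
#' @param measures measure columns to summarize.
#' @return named numeric vector, names `<measure>_<stat>`.
#' @export
weeklong_statistics <- function(frame_table, measures = measure_names()) {
  out <- unlist(lapply(measures, function(m) {
    s <- summary_stats(frame_table[[m]])
    stats::setNames(s, paste0(m, "_", names(s)))
  }))
  out
}

#' Window summary table for a cohort frame table
#'
#' Applies the voicing gate and the seven statistics to every
#' subject-window stratum.
#'
#' @param frames cohort frame table ([synth_cohort()] layout).
#' @param min_frames voicing gate in frames (default 30).
#' @param measures measure columns.
#' @return data.frame with subject, pair, group, day, window,
#'   n_voiced, and 77 statistic columns.
#' @export
summarize_windows <- function(frames, min_frames = 30L,
                              measures = measure_names()) {
  key <- interaction(frames$subject, frames$window, drop = TRUE)
  parts <- split(frames, key)
  rows <- lapply(parts, function(p) {
    if (nrow(p) < min_frames) return(NULL)
    stats_row <- unlist(lapply(measures, function(m) {
      s <- summary_stats(p[[m]])
      stats::setNames(s, paste0(m, "_", names(s)))
    }))
    cbind(data.frame(subject = p$subject[1], pair = p$pair[1],
                     group = p$group[1], day = p$day[1],
                     window = p$window[1], n_voiced = nrow(p)),
          as.data.frame(as.list(stats_row)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("summarize_windows: no window passed the gate")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-normalize window statistics
#'
#' Weekly scheme: each feature is centered and scaled across the voiced
#' windows of all subjects pooled. Daily scheme: within each subject-day
#' stratum. Zero-sd strata are set to 0 and flagged.
#'
#' @param windows window summary table from [summarize_windows()].
#' @param scheme "weekly" or "daily".
#' @param feature_cols columns to normalize (default: all statistic
#'   columns).
#' @return list with `data` (normalized table) and `flat` (character
#'   vector of zero-sd feature/stratum labels).
#' @export
z_normalize <- function(windows, scheme = c("weekly", "daily"),
                        feature_cols = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(windows),
                            c("subject", "pair", "group", "day", "window",
                              "n_voiced"))
  out <- windows
  flat <- character(0)
  strata <- if (scheme == "weekly") rep(1L, nrow(windows))
            else interaction(windows$subject, windows$day, drop = TRUE)
  for (col in feature_cols) {
    for (s in unique(strata)) {
      i <- strata == s
      if (sum(i) < 2L) stop("z_normalize: stratum with fewer than 2 windows")
      v <- windows[[col]][i]
      sdv <- stats::sd(v)
      if (!is.finite(sdv) || sdv == 0) {
        out[[col]][i] <- 0
        flat <- c(flat, paste0(col, "@", s))
      } else {
        out[[col]][i] <- (v - mean(v)) / sdv
      }
    }
  }
  list(data = out, flat = flat)
}

#' Paired t-tests with effect sizes across subject pairs
#'
#' Classical two-sided paired t-test per statistic, Cohen's d from the
#' pooled standard deviation of the two groups (a paired-sd variant is
#' available), and an advisory chi-square goodness-of-fit normality flag
#' on the pair differences.
#'
#' @param patient,control matrices (pairs x statistics) of week-long
#'   statistics, aligned by pair.
#' @param d_convention "pooled" (default) or "paired".
#' @return data.frame with statistic, patient and control mean/sd, t, p,
#'   cohens_d, normal_ok.
#' @export
paired_tests <- function(patient, control, d_convention = c("pooled", "paired")) {
  d_convention <- match.arg(d_convention)
  patient <- as.matrix(patient); control <- as.matrix(control)
  if (!all(dim(patient) == dim(control)))
    stop("paired_tests: unequal pair matrices")
  if (nrow(patient) < 2) stop("paired_tests: need at least 2 pairs")
  rows <- lapply(seq_len(ncol(patient)), function(j) {
    x <- patient[, j]; y <- control[, j]
    diffs <- x - y
    # essentially-constant differences (incl. floating-point residue)
    if (stats::sd(diffs) <= 1e-10 * (abs(mean(diffs)) + 1e-300)) {
      tt <- list(statistic = if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs)),
                 p.value = if (mean(diffs) == 0) 1 else 0)
      degenerate <- TRUE
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      degenerate <- FALSE
    }
    sd_pool <- sqrt((stats::var(x) + stats::var(y)) / 2)
    dd <- if (d_convention == "pooled") {
      if (sd_pool == 0) NA_real_ else mean(diffs) / sd_pool
    } else {
      if (stats::sd(diffs) == 0) NA_real_ else mean(diffs) / stats::sd(diffs)
    }
    data.frame(statistic = colnames(patient)[j] %||% paste0("V", j),
               patient_mean = mean(x), patient_sd = stats::sd(x),
               control_mean = mean(y), control_sd = stats::sd(y),
               t = unname(tt$statistic), p = tt$p.value, cohens_d = dd,
               degenerate = degenerate,
               normal_ok = chisq_normality(diffs)$ok)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chi-square goodness-of-fit check against normality
#'
#' Advisory screen: bins the values, compares observed counts with those
#' of a fitted normal, chi-square with bins - 3 degrees of freedom. Never
#' gates a t-test.
#'
#' @param x numeric values.
#' @param bins number of equal-probability bins (default 8).
#' @param alpha flag level (default 0.05).
#' @return list with `ok` (TRUE when not significantly non-normal),
#'   `statistic`, `p`.
#' @export
chisq_normality <- function(x, bins = 8L, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < bins * 2L || stats::sd(x) == 0)
    return(list(ok = NA, statistic = NA_real_, p = NA_real_))
  edges <- stats::qnorm(seq(0, 1, length.out = bins + 1L),
                        mean(x), stats::sd(x))
  if (any(diff(edges) <= 0))       # essentially-constant input
    return(list(ok = NA, statistic = NA_real_, p = NA_real_))
  obs <- table(cut(x, edges, include.lowest = TRUE))
  expd <- n / bins
  stat <- sum((obs - expd)^2 / expd)
  df <- bins - 3L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(ok = p >= alpha, statistic = stat, p = p)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the supplied p-values and finds L = max{k : P_(k) <= (k/m) alpha};
#' all hypotheses with p <= P_(L) are rejected. `m` is the total number of
#' tests in the family and may exceed the number of supplied p-values
#' (e.g., when only the smallest of the family are enumerated).
#'
#' @param pvals p-values in [0, 1].
#' @param m family size (default: length of `pvals`).
#' @param alpha FDR level (default 0.1).
#' @return list of class `fdr_result`: sorted `p`, `m`, `alpha`, threshold
#'   index `L` (0 when nothing is rejected), `p_threshold`, and `reject`
#'   flags in the input order.
#' @export
benjamini_hochberg <- function(pvals, m = length(pvals), alpha = 0.1) {
  if (any(pvals < 0 | pvals > 1)) stop("benjamini_hochberg: p-values outside [0,1]")
  if (m < length(pvals))
    stop("benjamini_hochberg: m smaller than the number of p-values")
  ord <- order(pvals)
  ps <- pvals[ord]
  k <- seq_along(ps)
  ok <- which(ps <= k / m * alpha)
  L <- if (length(ok)) max(ok) else 0L
  thr <- if (L > 0) ps[L] else NA_real_
  reject <- if (L > 0) pvals <= thr else rep(FALSE, length(pvals))
  structure(list(p_sorted = ps, m = m, alpha = alpha, L = L,
                 p_threshold = thr, reject = reject),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> m = %d, alpha = %g: %d rejection(s)%s\n",
              x$m, x$alpha, sum(x$reject),
              if (x$L > 0) sprintf(" (p <= %.4g)", x$p_threshold) else ""))
  invisible(x)
}
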