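## End-to-end pipeline over a subject manifest, plus config round-trip.

#' Pipeline configuration
#'
#' Defaults for every stage; any entry can be overridden. `yaml_path`
#' loads overrides from a YAML file first.
#'
#' @param ... named overrides.
#' @param yaml_path optional YAML file of overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml_path = NULL) {
  cfg <- list(
    fs = 11025, n_taps = 1102,
    acc = list(area_cm2 = 0.44, mass_g = 0.28),
    grid_spacing = 0.05,
    pso = list(n_particles = 20, max_iter = 40, seed = 1),
    framing = list(),
    min_voiced_frames = 30L,
    window_s = 300, alpha_fdr = 0.1,
    classify_min_pairs = 6L,
    seed = 1)
  if (!is.null(yaml_path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml_path))
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulate a cohort of raw recordings and a manifest
#'
#' For each subject: a short ambulatory-style accelerometer recording
#' (voiced pulse-train spans with silence between, forward-simulated
#' through a subject-specific Q set) and one calibration gesture pair.
#' Patients receive a higher flow amplitude. Everything is written as
#' float WAV plus a JSON truth sidecar; a manifest CSV ties it together.
#'
#' @param dir output directory (created).
#' @param n_pairs subject pairs (default 2; smoke scale).
#' @param duration_s ambulatory recording length per subject (s).
#' @param seed RNG seed.
#' @return the manifest data.frame (also written to `manifest.csv`).
#' @export
simulate_manifest <- function(dir, n_pairs = 2, duration_s = 4, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- .seed_guard(seed)
  on.exit(rs())
  rows <- list()
  for (p in seq_len(n_pairs)) for (grp in c("patient", "control")) {
    sid <- sprintf("%s%02d", substr(grp, 1, 1), p)
    q_true <- q_set(c(stats::runif(3, 0.8, 1.25), stats::runif(2, 0.9, 1.1)))
    f0 <- stats::runif(1, 150, 280)
    acfl0 <- if (grp == "patient") stats::runif(1, 300, 450)
             else stats::runif(1, 200, 330)
    spans <- cbind(seq(0.2, duration_s - 1, by = 1.2),
                   seq(0.2, duration_s - 1, by = 1.2) + 0.8)
    spec <- pulse_spec(f0 = f0, acfl = acfl0, jitter = 0.5, shimmer = 2,
                       duration_s = duration_s, seed = seed + p * 10 +
                         (grp == "patient"))
    flow <- synth_labeled_stream(duration_s, spans, spec,
                                 noise_rms = acfl0 * 0.002,
                                 seed = spec$seed)
    acc_sig <- forward_simulate_acceleration(flow, q = q_true)
    gest <- synth_calibration_pair(
      pulse_spec(f0 = f0, acfl = acfl0, duration_s = 0.5, seed = spec$seed + 1),
      q_true = q_true)
    acc_path <- file.path(dir, paste0(sid, "_acc.wav"))
    mask_path <- file.path(dir, paste0(sid, "_mask.wav"))
    gacc_path <- file.path(dir, paste0(sid, "_calacc.wav"))
    scale <- max(abs(acc_sig$samples))
    write_wav(acc_sig$samples, spec$fs, acc_path)
    write_wav(gest$mask, spec$fs, mask_path)
    write_wav(gest$acc$samples, spec$fs, gacc_path)
    jsonlite::write_json(
      list(subject = sid, q_true = q_true$q, f0 = f0, acfl = acfl0,
           voiced_spans = spans, scale = scale),
      file.path(dir, paste0(sid, "_truth.json")), auto_unbox = TRUE,
      digits = NA)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sid, pair = p, group = grp,
      acc_wav = acc_path, mask_wav = mask_path, cal_acc_wav = gacc_path,
      spl_slope = 1, spl_intercept = 30, fs = spec$fs)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Run the full analysis pipeline over a manifest
#'
#' Stages per subject: Q calibration from the gesture pair, inverse
#' filtering of the ambulatory recording, framing and gating, feature
#' extraction, window summaries and week-long statistics. Cohort stages:
#' paired t-tests with BH control, and (when enough pairs are present)
#' the nested-CV classifier. Every stage writes its artifact under
#' `out_dir` and the report records seeds, thresholds and rejection
#' counts.
#'
#' @param manifest manifest data.frame (see [simulate_manifest()]).
#' @param out_dir artifact directory.
#' @param cfg a `pipeline_config`.
#' @return report list (also written to `report.json`).
#' @export
run_pipeline <- function(manifest, out_dir, cfg = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acc_spec <- accelerometer_spec(cfg$acc$area_cm2, cfg$acc$mass_g)
  fr_cfg <- do.call(framing_config, cfg$framing)
  grid <- transfer_grid(q_bounds(), fs = cfg$fs, n_taps = cfg$n_taps,
                        spacing = cfg$grid_spacing)
  pso <- do.call(pso_config, cfg$pso)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  frame_rows <- list(); feat_rows <- list(); cal_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    amb <- stage("read", read_wav(m$acc_wav))
    gest <- stage("read", structure(
      list(mask = read_wav(m$mask_wav)$samples,
           acc = acc_signal(read_wav(m$cal_acc_wav)$samples, fs = m$fs),
           fs = m$fs, f0 = NULL, vowel = "a", loudness = "comfortable"),
      class = "calibration_gesture"))
    if (is.null(gest$f0)) {
      lags <- max(2L, floor(m$fs / 500)):min(ceiling(m$fs / 70),
                                             length(gest$mask) - 3L)
      gest$f0 <- m$fs / lags[which.max(.norm_acf(gest$mask, lags))]
    }
    cal <- stage("calibrate",
                 fit_q_parameters(list(gest), cfg = pso, grid = grid,
                                  acc = acc_spec, n_taps = cfg$n_taps))
    cal_rows[[i]] <- data.frame(subject = m$subject, t(cal$q$q),
                                d = cal$d, nwae = cal$nwae, seed = cal$seed)
    fir <- ibif_filter(cal$q, acc_spec, fs = m$fs, n_taps = cfg$n_taps,
                       branches = transfer_grid_lookup(grid, cal$q$q[4],
                                                       cal$q$q[5]))
    flow <- stage("ibif", estimate_glottal_flow(
      acc_signal(amb$samples, fs = amb$fs, subject = m$subject), fir))
    res <- stage("features", extract_features(
      flow, acc_signal(amb$samples, fs = amb$fs), fr_cfg,
      spl_calibration(m$spl_slope, m$spl_intercept)))
    fr <- res$frames
    fr$subject <- m$subject
    frame_rows[[i]] <- fr
    if (!is.null(res$features)) {
      fe <- res$features
      fe$subject <- m$subject; fe$pair <- m$pair; fe$group <- m$group
      # windows indexed by frame time
      fpw <- as.integer(round(cfg$window_s / fr_cfg$frame_s))
      fe$window <- (fe$index - 1L) %/% fpw + 1L
      fe$day <- 1L
      feat_rows[[i]] <- fe
    }
  }
  frames_tab <- do.call(rbind, frame_rows)
  feats_tab <- do.call(rbind, feat_rows)
  utils::write.csv(frames_tab, file.path(out_dir, "frames.csv"),
                   row.names = FALSE)
  utils::write.csv(feats_tab, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  cal_tab <- do.call(rbind, cal_rows)
  utils::write.csv(cal_tab, file.path(out_dir, "calibration.csv"),
                   row.names = FALSE)
  # week-long statistics and paired tests
  subjects <- unique(feats_tab$subject)
  week <- t(vapply(subjects, function(s)
    weeklong_statistics(feats_tab[feats_tab$subject == s, ]),
    numeric(77)))
  rownames(week) <- subjects
  meta <- manifest[match(subjects, manifest$subject), ]
  pats <- meta$subject[meta$group == "patient"][order(meta$pair[meta$group == "patient"])]
  ctls <- meta$subject[meta$group == "control"][order(meta$pair[meta$group == "control"])]
  report <- list(seed = cfg$seed, pso_seed = pso$seed,
                 n_subjects = length(subjects),
                 frames_total = nrow(frames_tab),
                 frames_accepted = sum(frames_tab$accepted),
                 frames_rejected_unvoiced = sum(!frames_tab$voiced),
                 frames_rejected_rms = sum(frames_tab$voiced &
                                             frames_tab$rms_reject),
                 frames_rejected_f0 = sum(frames_tab$voiced &
                                            !frames_tab$rms_reject &
                                            frames_tab$f0_reject))
  if (length(pats) >= 2 && length(pats) == length(ctls)) {
    tests <- stage("stats", paired_tests(week[pats, , drop = FALSE],
                                         week[ctls, , drop = FALSE]))
    fdr <- benjamini_hochberg(tests$p, m = ncol(week), alpha = cfg$alpha_fdr)
    utils::write.csv(tests, file.path(out_dir, "paired_tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(p_sorted = fdr$p_sorted, m = fdr$m, alpha = fdr$alpha, L = fdr$L),
      file.path(out_dir, "fdr.json"), auto_unbox = TRUE, digits = NA)
    report$n_bh_rejections <- sum(fdr$reject)
  }
  if (length(unique(feats_tab$pair)) >= cfg$classify_min_pairs) {
    win <- summarize_windows(feats_tab, min_frames = 2L)
    cvr <- stage("classify", nested_cv(assemble_features(win),
                                       seed = cfg$seed))
    report$classifier <- stats::setNames(as.list(cvr$summary$mean),
                                         cvr$summary$metric)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}
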