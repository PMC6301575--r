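## 154-feature window matrix, forward feature selection, L1 logistic
## regression and L1 squared-hinge SVM, leave-one-pair-out nested CV.

#' Assemble the 154-feature window matrix
#'
#' Concatenates the weekly- and daily-normalized versions of the 77
#' window statistics (7 statistics x 11 measures x 2 normalizations) in a
#' stable order: all weekly columns (suffix `_weekly`), then all daily
#' columns (`_daily`), measures in [measure_names()] order, statistics in
#' mean/median/p5/p95/sd/skew/kurt order.
#'
#' @param windows window summary table from [summarize_windows()] (all
#'   rows already passed the voicing gate).
#' @return object of class `feature_matrix`: list with `X` (numeric
#'   matrix), `y` (1 = patient, 0 = control), `pair`, `subject`, `window`.
#' @export
assemble_features <- function(windows) {
  stat_cols <- as.vector(outer(measure_names(), .stat_names(),
                               function(m, s) paste0(m, "_", s)))
  stat_cols <- stat_cols[order(rep(seq_along(measure_names()),
                                   times = length(.stat_names())))]
  missing <- setdiff(stat_cols, names(windows))
  if (length(missing))
    stop("assemble_features: missing statistic columns: ",
         paste(missing, collapse = ", "))
  wk <- z_normalize(windows, "weekly", stat_cols)$data
  dy <- z_normalize(windows, "daily", stat_cols)$data
  X <- cbind(as.matrix(wk[stat_cols]), as.matrix(dy[stat_cols]))
  colnames(X) <- c(paste0(stat_cols, "_weekly"), paste0(stat_cols, "_daily"))
  structure(list(X = X,
                 y = as.integer(windows$group == "patient"),
                 pair = windows$pair, subject = windows$subject,
                 window = windows$window),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features, %d subjects (%d pairs)\n",
              nrow(x$X), ncol(x$X), length(unique(x$subject)),
              length(unique(x$pair))))
  invisible(x)
}

# QDA 5-fold CV misclassification error for a candidate feature subset;
# ridge-regularized covariance fallback when qda() fails on a fold.
.qda_cv_error <- function(X, y, cols, folds) {
  errs <- vapply(unique(folds), function(f) {
    tr <- folds != f
    Xtr <- X[tr, cols, drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, cols, drop = FALSE]; yte <- y[!tr]
    pred <- tryCatch({
      fit <- MASS::qda(Xtr, grouping = factor(ytr))
      as.integer(as.character(stats::predict(fit, Xte)$class))
    }, error = function(e) {
      # singular class covariance: per-feature regularization fallback
      mu0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
      mu1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
      v <- apply(Xtr, 2, stats::var) + 1e-6
      d0 <- colSums((t(Xte) - mu0)^2 / v)
      d1 <- colSums((t(Xte) - mu1)^2 / v)
      as.integer(d1 < d0)
    })
    mean(pred != yte)
  }, numeric(1))
  mean(errs)
}

#' Greedy forward feature selection under a QDA cost
#'
#' Starts from the empty set and repeatedly adds the feature that most
#' reduces the 5-fold cross-validated QDA misclassification error,
#' stopping when the improvement over the incumbent drops below `tol`.
#' Fold assignment is deterministic given `seed`; the selection trace is
#' returned.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param n_folds inner folds (default 5).
#' @param tol stopping threshold on consecutive error improvement.
#' @param seed fold-assignment seed.
#' @param max_features optional cap on the selected-set size.
#' @return list with `selected` (column indices), `trace` (data.frame of
#'   step, feature, cv_error), `seed`.
#' @export
forward_feature_selection <- function(X, y, n_folds = 5, tol = 1e-6,
                                      seed = 1, max_features = ncol(X)) {
  X <- as.matrix(X)
  rs <- .seed_guard(seed)
  on.exit(rs())
  folds <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2))
    stop("forward_feature_selection: a fold lost one class")
  selected <- integer(0)
  best_err <- Inf
  trace <- list()
  repeat {
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (!length(cand) || length(selected) >= max_features) break
    errs <- vapply(cand, function(j)
      .qda_cv_error(X, y, c(selected, j), folds), numeric(1))
    j_best <- cand[which.min(errs)]
    new_err <- min(errs)
    if (!is.finite(tol) || best_err - new_err < tol) break
    selected <- c(selected, j_best)
    best_err <- new_err
    trace[[length(trace) + 1L]] <-
      data.frame(step = length(selected), feature = j_best,
                 cv_error = new_err)
    if (new_err == 0) break
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), feature = integer(0),
                    cv_error = numeric(0)),
       seed = seed)
}

#' L1-regularized logistic regression
#'
#' Minimizes the average negative Bernoulli log-likelihood plus
#' lambda * ||beta||_1 (intercept unpenalized); the lasso path is solved
#' by glmnet.
#'
#' @param X feature matrix (already standardized; `standardize = FALSE`).
#' @param y 0/1 labels.
#' @param lambda penalty weight (scalar).
#' @return object of class `l1_logistic`: `beta` (named, no intercept),
#'   `intercept`, `lambda`, `n_zero`, `converged`.
#' @export
fit_l1_logistic <- function(X, y, lambda) {
  X <- as.matrix(X)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  structure(list(beta = beta, intercept = as.numeric(fit$a0),
                 lambda = lambda, n_zero = sum(beta == 0),
                 converged = fit$npasses < 1e6),
            class = "l1_logistic")
}

#' @export
predict.l1_logistic <- function(object, newdata, type = c("prob", "link"), ...) {
  type <- match.arg(type)
  eta <- as.numeric(as.matrix(newdata) %*% object$beta + object$intercept)
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' Objective value of the L1 logistic program
#'
#' (1/N) sum of negative log-likelihood terms plus lambda * ||beta||_1;
#' used by tests to compare fitted solutions with brute-force minimizers.
#'
#' @param X,y data.
#' @param intercept,beta coefficients.
#' @param lambda penalty.
#' @return scalar objective value.
#' @export
l1_logistic_objective <- function(X, y, intercept, beta, lambda) {
  eta <- as.numeric(as.matrix(X) %*% beta + intercept)
  # numerically stable -loglik: log(1+exp(eta)) - y*eta
  ll <- ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta
  mean(ll) + lambda * sum(abs(beta))
}

#' L1-regularized squared-hinge SVM
#'
#' Minimizes sum_i max(0, 1 - y_i w'x_i)^2 + C ||w||_1 over w by FISTA
#' proximal gradient (soft-threshold prox, Lipschitz step from the top
#' eigenvalue of X'X); labels are mapped to -1/+1. There is no intercept
#' term, matching the penalized L2-loss support-vector program.
#'
#' @param X feature matrix.
#' @param y 0/1 (or -1/+1) labels.
#' @param C penalty weight.
#' @param max_iter iteration cap.
#' @param tol relative objective tolerance.
#' @return object of class `l1_svm`: `w` (named), `C`, `n_zero`,
#'   `objective`, `converged`.
#' @export
fit_l1_svm <- function(X, y, C, max_iter = 2000, tol = 1e-10) {
  X <- as.matrix(X)
  ys <- ifelse(y > 0, 1, -1)
  n <- nrow(X); p <- ncol(X)
  obj <- function(w) {
    m <- pmax(0, 1 - ys * as.numeric(X %*% w))
    sum(m^2) + C * sum(abs(w))
  }
  grad <- function(w) {
    m <- pmax(0, 1 - ys * as.numeric(X %*% w))
    -2 * as.numeric(t(X) %*% (ys * m))
  }
  # Lipschitz constant of the smooth part: 2 * lambda_max(X'X)
  v <- rep(1 / sqrt(p), p)
  for (i in 1:50) { v <- as.numeric(t(X) %*% (X %*% v)); v <- v / sqrt(sum(v^2)) }
  L <- 2 * sum((X %*% v)^2) / sum(v^2) * 1.01 + 1e-8
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  w <- numeric(p); z <- w; tk <- 1
  f_old <- obj(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w_new <- soft(z - grad(z) / L, C / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- w_new + (tk - 1) / tk_new * (w_new - w)
    w <- w_new; tk <- tk_new
    f_new <- obj(w)
    if (abs(f_old - f_new) <= tol * max(1, abs(f_old))) { converged <- TRUE; break }
    f_old <- f_new
  }
  names(w) <- colnames(X)
  structure(list(w = w, C = C, n_zero = sum(w == 0),
                 objective = obj(w), converged = converged),
            class = "l1_svm")
}

#' @export
predict.l1_svm <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w)
}

#' Objective value of the L1 squared-hinge SVM program
#' @param X,y data (y in 0/1 or -1/+1).
#' @param w weights.
#' @param C penalty.
#' @return scalar objective.
#' @export
l1_svm_objective <- function(X, y, w, C) {
  ys <- ifelse(y > 0, 1, -1)
  m <- pmax(0, 1 - ys * as.numeric(as.matrix(X) %*% w))
  sum(m^2) + C * sum(abs(w))
}

#' Classification metrics from scores and labels
#'
#' AUC by the rank (Mann-Whitney) statistic with midrank tie handling;
#' the remaining metrics from the confusion matrix at the threshold.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels 0/1 labels.
#' @param threshold decision threshold on the scores (default 0.5,
#'   suitable for probabilities).
#' @return named list: auc (NA when one class absent), accuracy, f_score,
#'   sensitivity, specificity, ppv, npv, threshold.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp); npv <- div(tn, tn + fn)
  f <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
       else 2 * ppv * sens / (ppv + sens)
  list(auc = auc, accuracy = (tp + tn) / length(labels), f_score = f,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       threshold = threshold)
}

# inner-CV lambda selection by mean AUC over pair-stratified folds
.inner_select <- function(X, y, pair, family, grid, n_folds, seed) {
  rs <- .seed_guard(seed)
  on.exit(rs())
  pairs <- unique(pair)
  fold_of <- stats::setNames(sample(rep(seq_len(n_folds), length.out = length(pairs))),
                             pairs)
  folds <- fold_of[as.character(pair)]
  aucs <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) next
    if (family == "l1lr") {
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 1, lambda = grid, standardize = FALSE)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response",
                           s = grid, exact = FALSE)
      for (g in seq_along(grid))
        aucs[f, g] <- classification_metrics(pr[, g], y[!tr])$auc
    } else {
      for (g in seq_along(grid)) {
        m <- fit_l1_svm(X[tr, , drop = FALSE], y[tr], C = grid[g],
                        max_iter = 500, tol = 1e-8)
        aucs[f, g] <- classification_metrics(
          predict(m, X[!tr, , drop = FALSE]), y[!tr])$auc
      }
    }
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  if (all(!is.finite(mean_auc))) return(grid[1])
  # one-standard-error rule: the strongest penalty whose mean validation
  # AUC is within one SE of the best (guards against noise-driven
  # selection of overfitting penalties in the inner loop)
  se <- apply(aucs, 2, stats::sd, na.rm = TRUE) /
    sqrt(pmax(colSums(is.finite(aucs)), 1))
  best <- which.max(mean_auc)
  ok <- which(mean_auc >= mean_auc[best] - se[best])
  grid[min(ok)]                 # grid is decreasing: min index = largest penalty
}

#' Default 20-point log-spaced penalty grid
#' @param X,y data used to anchor the full-shrinkage end (logistic case).
#' @param n grid size.
#' @return decreasing numeric grid.
#' @export
penalty_grid <- function(X, y, n = 20) {
  lmax <- max(abs(t(as.matrix(X)) %*% (y - mean(y)))) / length(y)
  # lower end 0.01 * lmax: near-unpenalized for p > n without the
  # separable-limit divergence of a fully unpenalized logistic fit
  exp(seq(log(lmax), log(lmax * 1e-2), length.out = n))
}

#' Leave-one-pair-out nested cross-validation
#'
#' Outer loop: each patient/control pair is held out once. Inner loop: the
#' training pairs are split into `inner_folds` pair-stratified folds and
#' the penalty maximizing the mean validation AUC is selected. The model
#' refit on all training windows is scored on the held-out pair at the
#' window level; each held-out subject additionally receives a call from
#' the proportion of its windows classified positive, compared against a
#' threshold chosen to maximize training-subject accuracy.
#'
#' By default the feature matrix is normalized once over all subjects
#' (the pooled weekly scheme); `normalize_within_train = TRUE` instead
#' recomputes both normalizations from the training windows only and
#' applies them to the held-out pair (the leakage-free variant). This
#' requires `windows` (the raw summary table).
#'
#' @param fm a `feature_matrix`, or NULL when `windows` is given with
#'   `normalize_within_train = TRUE`.
#' @param family "l1lr" or "l1svm".
#' @param grid penalty grid (default from [penalty_grid()]).
#' @param inner_folds inner fold count (default 5).
#' @param seed seed controlling fold assignments.
#' @param windows raw window table (needed for within-train normalization).
#' @param normalize_within_train recompute normalization per outer fold.
#' @return object of class `cv_report`: `folds` (per-fold metrics),
#'   `summary` (mean/sd), `subject_calls`, `models` (per-fold coefficient
#'   vectors), `lambda` (per-fold selected penalty), `seed`.
#' @export
nested_cv <- function(fm, family = c("l1lr", "l1svm"), grid = NULL,
                      inner_folds = 5, seed = 1, windows = NULL,
                      normalize_within_train = FALSE) {
  family <- match.arg(family)
  if (normalize_within_train && is.null(windows))
    stop("nested_cv: windows table required for within-train normalization")
  if (is.null(fm)) fm <- assemble_features(windows)
  X <- fm$X; y <- fm$y; pair <- fm$pair; subject <- fm$subject
  if (is.null(grid)) grid <- penalty_grid(X, y)
  pairs <- sort(unique(pair))
  fold_rows <- list(); models <- list(); lambdas <- numeric(0)
  subject_calls <- list()
  for (k in seq_along(pairs)) {
    te <- pair == pairs[k]
    if (!any(te) || length(unique(y[te])) < 1) next
    if (sum(te) == 0) next
    if (normalize_within_train) {
      wtr <- windows[!te, , drop = FALSE]
      wte <- windows[te, , drop = FALSE]
      fmtr <- assemble_features(wtr)
      Xtr <- fmtr$X
      Xte <- .apply_train_normalization(wtr, wte)
      ytr <- fmtr$y; ptr <- fmtr$pair
      yte <- as.integer(wte$group == "patient")
    } else {
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]; ptr <- pair[!te]
      Xte <- X[te, , drop = FALSE]; yte <- y[te]
    }
    if (length(unique(yte)) < 1 || nrow(Xte) == 0) next
    lam <- .inner_select(Xtr, ytr, ptr, family, grid, inner_folds,
                         seed = seed + k)
    if (family == "l1lr") {
      model <- fit_l1_logistic(Xtr, ytr, lam)
      str_scores <- predict(model, Xtr)
      ste <- predict(model, Xte)
      thr <- 0.5
    } else {
      model <- fit_l1_svm(Xtr, ytr, lam)
      str_scores <- predict(model, Xtr)
      ste <- predict(model, Xte)
      thr <- 0
    }
    met <- classification_metrics(ste, yte, threshold = thr)
    fold_rows[[length(fold_rows) + 1L]] <-
      cbind(data.frame(pair = pairs[k]), as.data.frame(met))
    coefs <- if (family == "l1lr") model$beta else model$w
    models[[length(models) + 1L]] <- coefs
    lambdas <- c(lambdas, lam)
    # subject-level call: proportion of positive windows vs threshold
    # maximizing training-subject accuracy
    sub_tr <- if (normalize_within_train) windows$subject[!te] else subject[!te]
    prop_tr <- tapply(as.integer(str_scores > thr), sub_tr, mean)
    lab_tr <- tapply(ytr, sub_tr, function(v) v[1])
    cands <- sort(unique(c(0, prop_tr, 1)))
    acc <- vapply(cands, function(tt) mean((prop_tr > tt) == (lab_tr == 1)),
                  numeric(1))
    t_sub <- cands[which.max(acc)]
    sub_te <- if (normalize_within_train) windows$subject[te] else subject[te]
    prop_te <- tapply(as.integer(ste > thr), sub_te, mean)
    lab_te <- tapply(yte, sub_te, function(v) v[1])
    subject_calls[[length(subject_calls) + 1L]] <-
      data.frame(pair = pairs[k], subject = names(prop_te),
                 prop_positive = as.numeric(prop_te),
                 call = as.integer(prop_te > t_sub),
                 label = as.integer(lab_te), threshold = t_sub)
  }
  if (!length(fold_rows)) stop("nested_cv: no evaluable fold")
  folds <- do.call(rbind, fold_rows)
  mcols <- c("auc", "accuracy", "f_score", "sensitivity", "specificity",
             "ppv", "npv")
  summ <- data.frame(metric = mcols,
                     mean = vapply(mcols, function(m) mean(folds[[m]], na.rm = TRUE),
                                   numeric(1)),
                     sd = vapply(mcols, function(m) stats::sd(folds[[m]], na.rm = TRUE),
                                 numeric(1)))
  structure(list(folds = folds, summary = summ,
                 subject_calls = do.call(rbind, subject_calls),
                 models = models, lambda = lambdas, family = family,
                 seed = seed),
            class = "cv_report")
}

# apply training-derived weekly/daily normalization to held-out windows
.apply_train_normalization <- function(wtr, wte) {
  stat_cols <- as.vector(outer(measure_names(), .stat_names(),
                               function(m, s) paste0(m, "_", s)))
  stat_cols <- stat_cols[order(rep(seq_along(measure_names()),
                                   times = length(.stat_names())))]
  Xw <- sapply(stat_cols, function(col) {
    mu <- mean(wtr[[col]]); s <- stats::sd(wtr[[col]])
    if (!is.finite(s) || s == 0) rep(0, nrow(wte)) else (wte[[col]] - mu) / s
  })
  # daily strata of the held-out subjects are disjoint from training:
  # normalize within the held-out subject-days themselves
  dy <- z_normalize(wte, "daily", stat_cols)$data
  Xw <- matrix(Xw, nrow = nrow(wte))
  X <- cbind(Xw, as.matrix(dy[stat_cols]))
  colnames(X) <- c(paste0(stat_cols, "_weekly"), paste0(stat_cols, "_daily"))
  X
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds\n", x$family, nrow(x$folds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Beta-magnitude ablation curve
#'
#' Ranks features by the magnitude of their coefficients in a model fit
#' on all windows (ties broken by column order), then repeatedly removes
#' the smallest-magnitude feature and reruns the nested CV, recording the
#' metric summary at each feature count.
#'
#' @param fm a `feature_matrix`.
#' @param family "l1lr" or "l1svm".
#' @param grid penalty grid.
#' @param seed seed (as in [nested_cv()]).
#' @param min_features stop after reaching this many features (default 1).
#' @param inner_folds inner folds for the nested CV.
#' @return data.frame: n_features, removed (name), mean/sd of each metric.
#' @export
ablate_by_beta <- function(fm, family = c("l1lr", "l1svm"), grid = NULL,
                           seed = 1, min_features = 1, inner_folds = 5) {
  family <- match.arg(family)
  X <- fm$X
  if (is.null(grid)) grid <- penalty_grid(X, fm$y)
  lam <- .inner_select(X, fm$y, fm$pair, family, grid, inner_folds, seed)
  coefs <- if (family == "l1lr") fit_l1_logistic(X, fm$y, lam)$beta
           else fit_l1_svm(X, fm$y, lam)$w
  ord <- order(abs(coefs), seq_along(coefs))   # ascending |beta|, ties by column
  keep <- seq_len(ncol(X))
  removed <- NA_character_
  rows <- list()
  repeat {
    sub <- fm
    sub$X <- X[, keep, drop = FALSE]
    rep_k <- nested_cv(sub, family = family, grid = grid,
                       inner_folds = inner_folds, seed = seed)
    s <- rep_k$summary
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(n_features = length(keep), removed = removed),
      stats::setNames(as.data.frame(t(s$mean)), paste0(s$metric, "_mean")),
      stats::setNames(as.data.frame(t(s$sd)), paste0(s$metric, "_sd")))
    if (length(keep) <= min_features) break
    drop_j <- ord[ord %in% keep][1]
    removed <- colnames(X)[drop_j]
    keep <- setdiff(keep, drop_j)
  }
  do.call(rbind, rows)
}

#' Consensus features and odds ratios across CV folds
#'
#' Features with a nonzero coefficient in every fold model, their
#' across-fold mean and sd, and odds ratios exp(mean beta) with a normal
#' confidence interval exp(mean +/- 1.96 sd/sqrt(n_folds)) built from the
#' across-fold dispersion.
#'
#' @param report a `cv_report`.
#' @return data.frame: feature, n_nonzero, beta_mean, beta_sd,
#'   odds_ratio, or_lo, or_hi, sorted by decreasing beta_mean.
#' @export
consensus_and_odds <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  B <- do.call(rbind, report$models)
  nz <- colSums(B != 0)
  n_folds <- nrow(B)
  keep <- which(nz == n_folds)
  if (!length(keep))
    return(data.frame(feature = character(0), n_nonzero = integer(0),
                      beta_mean = numeric(0), beta_sd = numeric(0),
                      odds_ratio = numeric(0), or_lo = numeric(0),
                      or_hi = numeric(0)))
  mu <- colMeans(B[, keep, drop = FALSE])
  sdv <- apply(B[, keep, drop = FALSE], 2, stats::sd)
  half <- 1.96 * sdv / sqrt(n_folds)
  out <- data.frame(feature = colnames(B)[keep], n_nonzero = nz[keep],
                    beta_mean = mu, beta_sd = sdv,
                    odds_ratio = exp(mu), or_lo = exp(mu - half),
                    or_hi = exp(mu + half))
  out[order(-out$beta_mean), ]
}
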