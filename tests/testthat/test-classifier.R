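# small cohort shared across classifier tests
co_small <- synth_cohort(cohort_spec(n_pairs = 8, days_per_subject = 2,
                                     windows_per_day = 3,
                                     frames_per_window = 40, seed = 21))
win_small <- summarize_windows(co_small, min_frames = 30)
fm_small <- assemble_features(win_small)

test_that("the assembled matrix has 154 columns in a stable order", {
  expect_identical(ncol(fm_small$X), 154L)
  expect_identical(sum(grepl("_weekly$", colnames(fm_small$X))), 77L)
  expect_identical(sum(grepl("_daily$", colnames(fm_small$X))), 77L)
  expect_identical(colnames(fm_small$X)[1], "ACFL_mean_weekly")
  expect_identical(colnames(fm_small$X)[78], "ACFL_mean_daily")
  expect_true(all(fm_small$y %in% 0:1))
})

test_that("the 30-voiced-frame gate excludes sparse windows", {
  co <- co_small
  # thin one window of one subject below the gate
  key <- co$subject == co$subject[1] & co$window == 1
  co2 <- rbind(co[key, ][1:29, ], co[!key, ])
  win2 <- summarize_windows(co2, min_frames = 30L)
  expect_false(any(win2$subject == co$subject[1] & win2$window == 1))
  co3 <- rbind(co[key, ][1:30, ], co[!key, ])
  win3 <- summarize_windows(co3, min_frames = 30L)
  expect_true(any(win3$subject == co$subject[1] & win3$window == 1))
})

test_that("forward feature selection finds separating structure", {
  set.seed(31)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(ifelse(y == 1, 2, -2) + 0.3 * rnorm(n),
             matrix(rnorm(n * 5), n, 5))
  colnames(X) <- paste0("f", 1:6)
  sel <- forward_feature_selection(X, y, seed = 2)
  expect_identical(sel$selected[1], 1L)
  # duplicated informative column: only one copy enters
  Xd <- cbind(X[, 1], X[, 1], X[, 2:6])
  seld <- forward_feature_selection(Xd, y, seed = 2)
  expect_identical(sum(seld$selected %in% 1:2), 1L)
  # an infinite threshold stops immediately with an empty set
  sel0 <- forward_feature_selection(X, y, tol = Inf, seed = 2)
  expect_length(sel0$selected, 0L)
})

test_that("L1 logistic regression shrinks fully and fits separable data", {
  set.seed(32)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2)
  y <- as.integer(X[, 1] > 0)
  big <- fit_l1_logistic(X, y, lambda = 5)
  expect_true(all(big$beta == 0))
  small <- fit_l1_logistic(X, y, lambda = 1e-4)
  expect_equal(mean((predict(small, X) > 0.5) == (y == 1)), 1)
})

test_that("the fitted L1 logistic objective matches a brute-force minimizer", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2)
  y <- as.integer(X[, 1] + 0.5 * rnorm(n) > 0)
  for (lam in c(0.02, 0.1)) {
    m <- fit_l1_logistic(X, y, lam)
    f_fit <- l1_logistic_objective(X, y, m$intercept, m$beta, lam)
    nm <- optim(c(0, 0, 0),
                function(p) l1_logistic_objective(X, y, p[1], p[2:3], lam),
                control = list(maxit = 50000, reltol = 1e-15))
    nm <- optim(nm$par,
                function(p) l1_logistic_objective(X, y, p[1], p[2:3], lam),
                control = list(maxit = 50000, reltol = 1e-15))
    expect_lt(abs(f_fit - nm$value), 1e-6)
  }
})

test_that("the L1 squared-hinge SVM solves its program and is sparse", {
  set.seed(34)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2)
  y <- as.integer(X[, 1] + 0.3 * rnorm(n) > 0)
  s <- fit_l1_svm(X, y, C = 2)
  nm <- optim(c(0, 0), function(w) l1_svm_objective(X, y, w, 2),
              control = list(maxit = 50000, reltol = 1e-15))
  nm <- optim(nm$par, function(w) l1_svm_objective(X, y, w, 2),
              control = list(maxit = 50000, reltol = 1e-15))
  expect_lt(abs(s$objective - nm$value), 1e-6)
  # huge penalty: all-zero weights
  s0 <- fit_l1_svm(X, y, C = 1e5)
  expect_true(all(s0$w == 0))
  expect_identical(s0$n_zero, 2L)
})

test_that("classification metrics match trivial and pairwise oracles", {
  m1 <- classification_metrics(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                               c(1, 1, 1, 0, 0, 0))
  expect_equal(m1$auc, 1)
  expect_equal(m1$accuracy, 1)
  expect_equal(m1$f_score, 1)
  sc <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  lb <- c(1, 1, 0, 1, 0, 0)
  brute <- mean(outer(sc[lb == 1], sc[lb == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(classification_metrics(sc, lb)$auc, brute)
  # single-class input: AUC undefined, the rest computed
  one <- classification_metrics(c(0.2, 0.7), c(1, 1), threshold = 0.5)
  expect_true(is.na(one$auc))
  expect_equal(one$accuracy, 0.5)
  # monotone transformation leaves the AUC unchanged
  expect_equal(classification_metrics(exp(3 * sc), lb)$auc, brute)
  # independent cross-check against an established ROC implementation
  set.seed(36)
  sc2 <- rnorm(40)
  lb2 <- rbinom(40, 1, 0.5)
  expect_equal(classification_metrics(sc2, lb2)$auc,
               as.numeric(pROC::auc(pROC::roc(lb2, sc2, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("nested CV keeps pairs together and scores separable data perfectly", {
  fm <- fm_small
  # overwrite one column with the label: perfect separability
  fm$X[, 1] <- ifelse(fm$y == 1, 3, -3) + 0.01 * rnorm(nrow(fm$X))
  cv <- nested_cv(fm, seed = 4)
  expect_identical(nrow(cv$folds), length(unique(fm$pair)))
  expect_equal(cv$summary$mean[cv$summary$metric == "auc"], 1, tolerance = 1e-9)
  # subject calls exist for both members of each pair
  expect_identical(nrow(cv$subject_calls), 2L * length(unique(fm$pair)))
})

test_that("nested CV supports the leakage-free normalization variant", {
  cv <- nested_cv(NULL, windows = win_small, normalize_within_train = TRUE,
                  seed = 5)
  expect_identical(nrow(cv$folds), length(unique(win_small$pair)))
  expect_true(all(cv$summary$mean[!is.na(cv$summary$mean)] >= 0))
})

test_that("the SVM family runs through nested CV", {
  fm <- fm_small
  fm$X <- fm$X[, 1:10]
  cv <- nested_cv(fm, family = "l1svm", grid = c(50, 5, 0.5), seed = 6)
  expect_identical(nrow(cv$folds), length(unique(fm$pair)))
})

test_that("beta ablation removes smallest coefficients first, one at a time", {
  set.seed(35)
  fm <- fm_small
  fm$X <- fm$X[, 1:6]
  fm$X[, 3] <- ifelse(fm$y == 1, 1.5, -1.5) + 0.5 * rnorm(nrow(fm$X))
  tab <- ablate_by_beta(fm, min_features = 2, seed = 7)
  expect_identical(tab$n_features, seq(6L, 2L, by = -1L))
  # the strongly informative feature survives the longest removals
  expect_false("V3" %in% tab$removed[1:2])
})

test_that("consensus features and odds ratios follow the fold models", {
  fake <- structure(list(models = list(
    c(a = 1.0, b = 0.5, c = 0.0),
    c(a = 1.2, b = 0.4, c = 0.2),
    c(a = 0.8, b = 0.6, c = 0.1)), family = "l1lr",
    folds = data.frame(pair = 1:3)), class = "cv_report")
  cons <- consensus_and_odds(fake)
  expect_identical(sort(cons$feature), c("a", "b"))     # c zeroed in fold 1
  a <- cons[cons$feature == "a", ]
  expect_equal(a$odds_ratio, exp(1.0))
  # zero mean coefficient gives odds ratio 1
  fake0 <- fake
  fake0$models <- list(c(a = 0.4, b = 0), c(a = -0.4, b = 0))
  c0 <- consensus_and_odds(fake0)
  expect_equal(c0$odds_ratio[c0$feature == "a"], 1)
  # a strong synthetic effect keeps consensus membership and OR > 1
  fm <- fm_small
  fm$X[, 2] <- ifelse(fm$y == 1, 2, -2) + 0.5 * rnorm(nrow(fm$X))
  cv <- nested_cv(fm, seed = 8)
  cons2 <- consensus_and_odds(cv)
  feat <- colnames(fm$X)[2]
  expect_true(feat %in% cons2$feature)
  expect_gt(cons2$odds_ratio[cons2$feature == feat], 1)
})
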