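test_that("CV splits partition subjects with balanced folds", {
  sp <- make_cv_splits(10, "kfold", k = 5, seed = 1)
  tests <- lapply(sp, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:10)
  expect_true(all(lengths(tests) == 2))
  for (f in sp) expect_length(intersect(f$train, f$test), 0)
  lo <- make_cv_splits(10, "loocv", seed = 1)
  expect_length(lo, 10)
  expect_true(all(lengths(lapply(lo, `[[`, "test")) == 1))
  expect_identical(make_cv_splits(10, "kfold", 5, 7),
                   make_cv_splits(10, "kfold", 5, 7))
  expect_error(make_cv_splits(4, "kfold", k = 5, seed = 1),
               class = "srcdcm_config_error")
  # uneven n: fold sizes differ by at most one
  sz <- lengths(lapply(make_cv_splits(13, "kfold", 5, 2), `[[`, "test"))
  expect_lte(diff(range(sz)), 1)
})

test_that("feature selection recovers planted edges and falls back", {
  tr <- fx_cohort60()
  posts <- fx_posts60()
  cfg <- prediction_config(n_repetitions = 1, feature_source = "M-EC",
                           seed = 5)
  planted <- planted_positions(tr, "B")
  hits <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    idx <- sample(60, 48)
    sel <- select_features(posts[idx], tr$scores$rt_like[idx], cfg)
    chosen <- sel$mask$param_idx[sel$mask$mask]
    if (mean(planted %in% chosen) >= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 8L)   # >= 80% of loops keep >= 50% of planted edges

  # shuffled covariate: masks stay small
  sizes <- vapply(1:10, function(s) {
    set.seed(400 + s)
    sel <- select_features(posts, sample(tr$scores$rt_like), cfg)
    if (sel$fallback) 0L else sum(sel$mask$mask)
  }, 0L)
  expect_lte(median(sizes), 0.1 * 81)

  # engineered empty mask engages the fallback
  tr0 <- sample_cohort_truth(12, seed = 31,
                             spec = list(beta_A = 0, beta_B = 0))
  sel0 <- select_features(pseudo_posteriors(tr0, 0.05, 1),
                          tr0$scores$rt_like, cfg)
  if (sel0$fallback) expect_equal(sum(sel0$mask$mask), 1L)
})

test_that("extract_features indexes posterior means exactly", {
  posts <- fx_posts60()[1:10]
  spec <- posts[[1]]$spec
  mask <- structure(list(mask = c(TRUE, FALSE, TRUE, TRUE),
                         param_idx = c(5L, 6L, 90L, 140L),
                         names = spec$table$name[c(5, 6, 90, 140)]),
                    class = "edge_mask")
  X <- extract_features(posts, mask)
  expect_equal(dim(X), c(10L, 3L))
  for (i in c(1, 7))
    expect_equal(unname(X[i, ]),
                 unname(posts[[i]]$mean[c(5L, 90L, 140L)]))
  bad <- mask; bad$param_idx <- c(5L, 6L, 9999L, 140L)
  expect_error(extract_features(posts, bad),
               class = "srcdcm_alignment_error")
})

test_that("zero-penalty regression equals the OLS oracle", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(20, 0, 0.1)
  fit <- fit_predict_regularized(X, y, X, "lasso", seed = 1, lambda = 0)
  xs <- scale(X)
  ols <- lm.fit(cbind(1, xs), y)$coefficients
  expect_lt(max(abs(fit$coef - ols)), 1e-4)
  expect_lt(max(abs(fit$pred - cbind(1, xs) %*% ols)), 1e-4)
})

test_that("LASSO zeroes pure-noise columns at the selected penalty", {
  zeroed <- vapply(1:10, function(s) {
    set.seed(500 + s)
    X <- matrix(rnorm(1000), 100, 10)
    y <- 5 * X[, 1] + rnorm(100)
    fit <- fit_predict_regularized(X, y, X[1:2, , drop = FALSE], "lasso",
                                   seed = s)
    all(fit$coef[3:11] == 0)   # intercept + 10 coefs; noise cols 2..10
  }, TRUE)
  expect_gte(sum(zeroed), 9L)
})

test_that("regression is deterministic and validates inputs", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] + rnorm(20, 0, 0.2)
  a <- fit_predict_regularized(X, y, X, "ridge", seed = 3)
  b <- fit_predict_regularized(X, y, X, "ridge", seed = 3)
  expect_identical(a$pred, b$pred)
  expect_error(fit_predict_regularized(X, rep(1, 20), X, "lasso", 1),
               class = "srcdcm_degenerate_target_error")
})

test_that("oracle features predict almost perfectly", {
  set.seed(13)
  y <- rnorm(40)
  Xall <- cbind(y, matrix(rnorm(120), 40, 3))
  cfg <- prediction_config(n_repetitions = 3, seed = 9)
  res <- run_prediction(
    NULL, y, cfg,
    feature_selector = function(tr, ty)
      list(mask = structure(list(mask = rep(TRUE, 4), param_idx = 1:4,
                                 names = paste0("f", 1:4)),
                            class = "edge_mask"), fallback = FALSE),
    feature_extractor = function(mask) Xall)
  expect_gt(res$mean_r, 0.99)
  expect_true(all(abs(res$r_per_repetition) <= 1))
  expect_equal(length(res$r_per_repetition), 3L)
})

test_that("the CV loop never touches test-fold information", {
  tr <- fx_cohort60()
  posts <- fx_posts60()
  cfg <- prediction_config(n_repetitions = 1, feature_source = "M-EC",
                           seed = 17)
  folds <- make_cv_splits(60, cfg$cv_scheme, cfg$k,
                          substream_seed(cfg$seed, "split", 1))
  trn <- folds[[1]]$train
  tst <- folds[[1]]$test
  y1 <- tr$scores$rt_like
  y2 <- y1
  y2[tst] <- y2[tst] + 100   # mutate test-fold targets only
  run_fold <- function(y) {
    sel <- select_features(posts[trn], y[trn], cfg)
    X <- extract_features(posts, sel$mask)
    fit <- fit_predict_regularized(X[trn, , drop = FALSE], y[trn],
                                   X[tst, , drop = FALSE], cfg$regressor,
                                   seed = substream_seed(cfg$seed,
                                                         "inner", 1, 1))
    list(mask = sel$mask$mask, coef = fit$coef, pred = fit$pred)
  }
  a <- run_fold(y1)
  b <- run_fold(y2)
  expect_identical(a$mask, b$mask)
  expect_identical(a$coef, b$coef)
  expect_identical(a$pred, b$pred)
})

test_that("permutation machinery has correct rank logic", {
  tr <- sample_cohort_truth(30, seed = 41)
  posts <- pseudo_posteriors(tr, 0.02, 42)
  cfg <- prediction_config(n_repetitions = 2, n_permutations = 19,
                           feature_source = "M-EC", seed = 43)
  res <- permutation_test(posts, tr$scores$rt_like, cfg)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_equal(res$p_value,
               (1 + sum(res$null_distribution >= res$mean_r)) /
                 (1 + length(res$null_distribution)))
  # an observed value below the null median must give p > 0.5
  fake <- res
  fake$mean_r <- min(res$null_distribution) - 1
  p_fake <- (1 + sum(fake$null_distribution >= fake$mean_r)) /
    (1 + length(fake$null_distribution))
  expect_gt(p_fake, 0.5)
})

test_that("Cohen's d matches hand computation", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(5, 6), c(1, 3)), -cohens_d(c(1, 3), c(5, 6)))
  expect_error(cohens_d(c(1, 1), c(1, 1)),
               class = "srcdcm_degenerate_error")
  expect_error(cohens_d(1, c(1, 2)), class = "srcdcm_config_error")
})

test_that("feature frequencies count selections across loops", {
  mk <- function(sel) structure(list(
    mask = seq_len(5) %in% sel, param_idx = 1:5,
    names = paste0("e", 1:5)), class = "edge_mask")
  masks <- c(replicate(79, mk(c(1, 2)), simplify = FALSE),
             replicate(21, mk(c(2, 3)), simplify = FALSE))
  ff <- feature_frequency(masks)
  expect_equal(unname(ff$frequency[c("e1", "e2", "e3")]),
               c(0.79, 1.0, 0.21))
  expect_false("e1" %in% ff$high_frequency_set)   # 79/100 excluded
  expect_true("e2" %in% ff$high_frequency_set)
  masks80 <- c(replicate(80, mk(1), simplify = FALSE),
               replicate(20, mk(2), simplify = FALSE))
  expect_true("e1" %in% feature_frequency(masks80)$high_frequency_set)
  expect_equal(ff$mean_mask_size, 2)
})
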