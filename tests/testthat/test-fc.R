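test_that("FC matrices are Pearson correlations with fixed edge order", {
  set.seed(2)
  M <- matrix(rnorm(500), 100, 5)
  colnames(M) <- paste0("n", 1:5)
  M[, 2] <- M[, 1]
  fc <- compute_fc(M)
  expect_equal(fc$mat[1, 2], 1)
  expect_equal(diag(fc$mat), rep(1, 5), ignore_attr = TRUE)
  expect_equal(fc$mat, t(fc$mat))
  expect_length(fc$edges, 10)
  # brute-force covariance/sd oracle on a 5 x 3 toy table
  toy <- matrix(c(1, 4, 2, 8, 5, 7, 3, 6, 9, 2, 5, 1, 4, 8, 6), 5, 3)
  fc2 <- compute_fc(rbind(toy, toy[1:2, ] + 1e-3))
  brute <- function(a, b) {
    x <- rbind(toy, toy[1:2, ] + 1e-3)
    ca <- x[, a] - mean(x[, a]); cb <- x[, b] - mean(x[, b])
    sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  for (a in 1:2) for (b in (a + 1):3)
    expect_equal(fc2$mat[a, b], brute(a, b), tolerance = 1e-12)
  # independent white noise: small correlations at T = 2000
  set.seed(3)
  W <- matrix(rnorm(2000 * 4), 2000, 4)
  expect_lt(max(abs(compute_fc(W)$edges)), 0.1)
  # invariance to per-node affine rescaling (positive gains)
  S <- sweep(sweep(W, 2, c(2, 3, 0.5, 10), "*"), 2, c(1, -2, 3, 4), "+")
  expect_equal(compute_fc(S)$mat, compute_fc(W)$mat, tolerance = 1e-12)
  # constant node is named in the error
  Wc <- W; Wc[, 3] <- 2
  err <- tryCatch(compute_fc(Wc), error = function(e) e)
  expect_s3_class(err, "srcdcm_degenerate_node_error")
  expect_match(conditionMessage(err), "3")
})

test_that("task-residual FC removes shared task variance", {
  enc <- fx_encoding(4L)
  Tn <- floor(enc$total_duration / TRdef) + 1
  reg <- srcdcm:::task_regressors(enc, TRdef, Tn)
  set.seed(4)
  # signals = shared task regressors + independent noise
  reg <- scale(reg)   # unit-variance task regressors
  load <- matrix(runif(2 * 4, 0.5, 2), 2, 4)
  M <- reg %*% load + matrix(rnorm(Tn * 4, 0, 0.3), Tn, 4)
  colnames(M) <- paste0("n", 1:4)
  ts <- structure(list(data = M, TR = TRdef, node_labels = colnames(M),
                       subject_id = "s1"), class = "roi_timeseries")
  full <- compute_fc(ts)
  resid <- task_residual_fc(ts, enc)
  expect_gt(mean(abs(full$edges)), mean(abs(resid$edges)))
  expect_lt(max(abs(resid$edges)), 0.2)
  # residuals orthogonal to every regressor column
  X <- cbind(1, reg)
  R <- M - X %*% qr.solve(X, M)
  expect_lt(max(abs(crossprod(X, R))), 1e-8)
  # zero task input: residual FC equals full FC exactly
  enc0 <- enc
  enc0$u[] <- 0
  resid0 <- task_residual_fc(ts, enc0)
  expect_equal(resid0$mat, full$mat, tolerance = 1e-10)
  # rank-deficient regressors are rejected
  enc2 <- enc
  enc2$u[, 2] <- enc2$u[, 1]
  expect_error(task_residual_fc(ts, enc2), class = "srcdcm_design_error")
})

test_that("CPM selection keeps top tail edges deterministically", {
  set.seed(5)
  E <- 36
  Xe <- matrix(rnorm(40 * E), 40, E)
  y <- Xe[, 1] - Xe[, 2] + rnorm(40, 0, 0.5)
  m <- cpm_select(Xe, y, 0.10)
  expect_lte(sum(m$mask), 8)          # 4 + 4 before union
  expect_gte(sum(m$mask), 4)
  expect_true(m$mask[1] && m$mask[2])  # planted edges selected
  r <- apply(Xe, 2, cor, y)
  sel_pos <- order(-r, seq_len(E))[1:4]
  sel_neg <- order(r, seq_len(E))[1:4]
  expect_setequal(which(m$mask), union(sel_pos, sel_neg))
  # all-positive correlations: negative tail = least positive edges
  y2 <- rowSums(Xe) + rnorm(40, 0, 0.1)
  m2 <- cpm_select(Xe, y2, 0.10)
  r2 <- apply(Xe, 2, cor, y2)
  expect_true(all(order(r2, seq_len(E))[1:4] %in% which(m2$mask)))
  # selection bias sanity: selected edges correlate more than unselected
  y3 <- rnorm(40)
  m3 <- cpm_select(Xe, y3, 0.10)
  r3 <- abs(apply(Xe, 2, cor, y3))
  expect_gt(mean(r3[m3$mask]), mean(r3[!m3$mask]))
  expect_error(cpm_select(Xe[, 0, drop = FALSE], y),
               class = "srcdcm_config_error")
})

test_that("FC prediction flows through the shared machinery", {
  tr <- sample_cohort_truth(20, seed = 3)
  enc <- fx_encoding(4L)
  ts <- simulate_cohort_bold(tr, enc, TR = TRdef, seed = 4)
  # oracle: target equal to one edge's value
  fcs <- lapply(ts, compute_fc)
  y <- vapply(fcs, function(f) f$edges[7], 0)
  cfg <- prediction_config(n_repetitions = 2, feature_source = "FC-full",
                           seed = 6)
  res <- run_fc_prediction(ts, y, cfg)
  expect_gt(res$mean_r, 0.95)
  # residual-kind runs end-to-end
  cfg2 <- prediction_config(n_repetitions = 1,
                            feature_source = "FC-residual", seed = 7)
  res2 <- run_fc_prediction(ts, tr$scores$rt_like, cfg2, enc = enc)
  expect_true(is.finite(res2$mean_r))
  # masks never empty, never exceed 2 * ceil(0.1 E)
  sizes <- vapply(res$masks_per_loop, function(m) sum(m$mask), 0L)
  expect_true(all(sizes >= 1 & sizes <= 8))
})
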