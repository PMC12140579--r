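#' Cross-validated phenotype prediction from connectivity features
#'
#' The workflow: subjects are split into k folds; within each training
#' fold a PEB (optionally BMR) analysis selects connectivity parameters
#' whose covariate effect has PP > 0.95; the selected subject-level
#' posterior means are the features of a LASSO- (or ridge-) regularized
#' linear regression whose penalty is chosen by inner 5-fold CV; pooled
#' test predictions yield one Pearson correlation per repetition.
#' Permutation nulls shuffle the targets and rerun the whole loop,
#' feature selection included.
#'
#' @name predict
NULL

#' Prediction configuration
#'
#' @param cv_scheme "kfold" or "loocv"
#' @param k number of folds (default 5)
#' @param n_repetitions random re-splits (default 100; forced to 1 for
#'   LOOCV, whose single split is deterministic)
#' @param n_permutations label-shuffled iterations (default 500)
#' @param regressor "lasso" or "ridge"
#' @param feature_source "I-EC" (A matrix), "M-EC" (B matrix),
#'   "combined" (both, masked by separate PEB fits), "FC-full" or
#'   "FC-residual"
#' @param pp_threshold PP threshold for feature masking (default 0.95)
#' @param use_bmr select features from a BMR search instead of raw PEB
#' @param seed master seed; all randomness derives from it
#' @return list of class \code{prediction_config}
#' @export
prediction_config <- function(cv_scheme = c("kfold", "loocv"), k = 5L,
                              n_repetitions = 100L, n_permutations = 500L,
                              regressor = c("lasso", "ridge"),
                              feature_source = c("M-EC", "I-EC",
                                                 "combined", "FC-full",
                                                 "FC-residual"),
                              pp_threshold = 0.95, use_bmr = FALSE,
                              seed = 1L) {
  cv_scheme <- match.arg(cv_scheme)
  regressor <- match.arg(regressor)
  feature_source <- match.arg(feature_source)
  assert_that(n_repetitions >= 1L && n_permutations >= 0L,
              "srcdcm_config_error", "repetition counts must be positive")
  if (cv_scheme == "loocv") n_repetitions <- 1L
  structure(list(cv_scheme = cv_scheme, k = as.integer(k),
                 n_repetitions = as.integer(n_repetitions),
                 n_permutations = as.integer(n_permutations),
                 regressor = regressor, feature_source = feature_source,
                 pp_threshold = pp_threshold, use_bmr = use_bmr,
                 seed = as.integer(seed)),
            class = "prediction_config")
}

#' Cross-validation splits
#'
#' @param n_subjects sample size
#' @param scheme "kfold" or "loocv"
#' @param k folds (ignored for LOOCV)
#' @param seed integer seed
#' @return list of folds, each \code{list(train, test)}; test sets
#'   partition the subjects and fold sizes differ by at most one
#' @export
make_cv_splits <- function(n_subjects, scheme = c("kfold", "loocv"),
                           k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "loocv") k <- n_subjects
  assert_that(k <= n_subjects, "srcdcm_config_error",
              "k = %d exceeds n = %d subjects", k, n_subjects)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = n_subjects))
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Select features on a training set
#'
#' PEB (or BMR) on the training subjects only; the mask is the covariate
#' column thresholded at PP > threshold.  If no parameter passes, the
#' single highest-PP parameter is used and the fallback recorded.
#'
#' @param posteriors training-set subject posteriors
#' @param train_scores training-set covariate values
#' @param config a \code{prediction_config}
#' @param which parameter subset override ("A", "B", "AB"); defaults to
#'   the matrix implied by \code{feature_source}
#' @return list(mask = \code{edge_mask}, fallback = logical)
#' @export
select_features <- function(posteriors, train_scores, config,
                            which = NULL) {
  which <- which %||% switch(config$feature_source,
                             "I-EC" = "A", "M-EC" = "B", "combined" = "AB",
                             stop_srcdcm("srcdcm_config_error",
                                         "EC selection asked for FC source"))
  design <- build_design_matrix(train_scores)
  peb <- fit_peb(posteriors, design, which = which)
  if (config$use_bmr) {
    bs <- bmr_search(peb, pp_threshold = config$pp_threshold)
    mask <- bs$mask
    pp <- bs$pp
  } else {
    mask <- pp_mask(peb, "covariate", config$pp_threshold)
    pp <- peb$pp[, "covariate"]
  }
  fallback <- !any(mask$mask)
  if (fallback) mask$mask[which.max(pp)] <- TRUE
  list(mask = mask, fallback = fallback)
}

#' Extract masked features from subject posteriors
#'
#' @param posteriors list of \code{dcm_posterior}
#' @param mask an \code{edge_mask}
#' @return matrix (subjects x selected parameters) of posterior means
#' @export
extract_features <- function(posteriors, mask) {
  assert_that(any(mask$mask), "srcdcm_config_error", "empty mask")
  sel <- mask$param_idx[mask$mask]
  spec <- posteriors[[1]]$spec
  assert_that(max(sel) <= spec$n_free, "srcdcm_alignment_error",
              "mask does not fit the parameter layout")
  X <- matrix(vapply(posteriors, function(p) unname(p$mean[sel]),
                     numeric(length(sel))),
              nrow = length(posteriors), ncol = length(sel),
              byrow = TRUE)
  colnames(X) <- spec$table$name[sel]
  X
}

#' Regularized regression with inner-CV penalty selection
#'
#' Features are z-scored by training statistics; the penalty is chosen by
#' inner 5-fold cross-validation over a 30-point logarithmic grid
#' (glmnet's path).  \code{lambda = 0} bypasses the inner CV and solves
#' ordinary least squares (used as an oracle check).
#'
#' @param train_x,train_y training design and targets
#' @param test_x test design
#' @param regressor "lasso" or "ridge"
#' @param seed seed for the inner-CV fold assignment
#' @param lambda optional fixed penalty
#' @return list(pred = test predictions, lambda, coef)
#' @export
fit_predict_regularized <- function(train_x, train_y, test_x,
                                    regressor = c("lasso", "ridge"),
                                    seed = 1L, lambda = NULL) {
  regressor <- match.arg(regressor)
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x, ncol = ncol(train_x))
  assert_that(nrow(train_x) >= 2L && ncol(train_x) >= 1L,
              "srcdcm_config_error", "need >= 2 subjects and >= 1 feature")
  assert_that(sd(train_y) > 0, "srcdcm_degenerate_target_error",
              "constant training target")
  mu <- colMeans(train_x)
  sg <- apply(train_x, 2, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(train_x, 2, mu), 2, sg, "/")
  ts <- sweep(sweep(test_x, 2, mu), 2, sg, "/")

  if (!is.null(lambda) && lambda == 0) {
    fit <- lm.fit(cbind(1, xs), train_y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- as.vector(cbind(1, ts) %*% beta)
    return(list(pred = pred, lambda = 0, coef = beta))
  }

  padded <- ncol(xs) == 1L    # glmnet needs >= 2 columns
  if (padded) {
    xs <- cbind(xs, 0)
    ts <- cbind(ts, 0)
  }
  alpha <- if (regressor == "lasso") 1 else 0
  if (is.null(lambda)) {
    set.seed(seed)
    nfold <- min(5L, nrow(xs))
    foldid <- sample(rep(seq_len(nfold), length.out = nrow(xs)))
    cvfit <- glmnet::cv.glmnet(xs, train_y, alpha = alpha, nlambda = 30,
                               foldid = foldid, standardize = FALSE,
                               grouped = nrow(xs) >= 3 * nfold)
    # one-standard-error rule: the strongest penalty within one SE of
    # the CV optimum, guarding against overfitting spurious features
    lambda <- cvfit$lambda.1se
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(xs, train_y, alpha = alpha, standardize = FALSE)
  }
  pred <- as.vector(predict(fit, newx = ts, s = lambda))
  cf <- as.vector(coef(fit, s = lambda))
  if (padded) cf <- cf[-length(cf)]
  list(pred = pred, lambda = lambda, coef = cf)
}

#' Run the cross-validated prediction workflow
#'
#' @param posteriors list of subject \code{dcm_posterior} (or
#'   pseudo-posteriors)
#' @param targets numeric vector aligned with \code{posteriors}
#' @param config a \code{prediction_config}
#' @param feature_selector optional custom selector
#'   \code{function(train_idx, train_targets)} returning
#'   \code{list(mask, fallback)}; default is PEB/BMR on posteriors
#' @param feature_extractor optional \code{function(mask)} returning the
#'   full subjects x features matrix for a mask
#' @return object of class \code{prediction_result}:
#'   \code{$r_per_repetition}, \code{$mean_r}, \code{$predictions}
#'   (subject, repetition, predicted, empirical), \code{$masks_per_loop},
#'   \code{$notes}
#' @export
run_prediction <- function(posteriors, targets, config,
                           feature_selector = NULL,
                           feature_extractor = NULL) {
  ns <- length(targets)
  if (!is.null(posteriors))
    assert_that(length(posteriors) == ns, "srcdcm_alignment_error",
                "targets not aligned with posteriors")
  feature_selector <- feature_selector %||% function(train_idx, tr_y)
    select_features(posteriors[train_idx], tr_y, config)
  feature_extractor <- feature_extractor %||% function(mask)
    extract_features(posteriors, mask)

  r_rep <- rep(NA_real_, config$n_repetitions)
  preds <- list()
  masks <- list()
  notes <- character()
  for (rep_i in seq_len(config$n_repetitions)) {
    split_seed <- substream_seed(config$seed, "split", rep_i)
    folds <- make_cv_splits(ns, config$cv_scheme, config$k, split_seed)
    pred <- rep(NA_real_, ns)
    ok <- TRUE
    informative <- FALSE   # any fold with a nonzero feature coefficient
    for (f in seq_along(folds)) {
      tr <- folds[[f]]$train
      te <- folds[[f]]$test
      res <- tryCatch({
        sel <- feature_selector(tr, targets[tr])
        if (sel$fallback)
          notes <- c(notes, sprintf("rep %d fold %d: empty-mask fallback",
                                    rep_i, f))
        Xall <- feature_extractor(sel$mask)
        if (any(apply(Xall[tr, , drop = FALSE], 2, sd) == 0))
          notes <- c(notes, sprintf("rep %d fold %d: zero-variance feature",
                                    rep_i, f))
        fit <- fit_predict_regularized(
          Xall[tr, , drop = FALSE], targets[tr],
          Xall[te, , drop = FALSE], config$regressor,
          seed = substream_seed(config$seed, "inner", rep_i, f))
        masks[[length(masks) + 1L]] <- sel$mask
        if (any(fit$coef[-1] != 0)) informative <- TRUE
        fit$pred
      }, srcdcm_error = function(e) e)
      if (inherits(res, "error")) {
        notes <- c(notes, sprintf("rep %d fold %d skipped: %s", rep_i, f,
                                  conditionMessage(res)))
        ok <- FALSE
        break
      }
      pred[te] <- res
    }
    if (!ok) next
    # pooled accuracy as the pooled within-fold correlation: both
    # predictions and targets are centered within each test fold before
    # correlating.  A fold's regression intercept is its training-fold
    # mean, which anti-correlates with the held-out targets under
    # exchangeability; raw pooling therefore biases shuffled-target
    # nulls to r well below 0, while two-sided centering is unbiased and
    # scores a perfect predictor at exactly 1.  Singleton folds (LOOCV)
    # cannot be centered and are pooled raw.
    pc <- pred
    tc <- targets
    if (all(lengths(lapply(folds, `[[`, "test")) >= 2L)) {
      for (f in folds) {
        pc[f$test] <- pc[f$test] - mean(pc[f$test])
        tc[f$test] <- tc[f$test] - mean(tc[f$test])
      }
    }
    if (!informative || sd(pc) == 0 || sd(tc) == 0) {
      # every fold collapsed to its intercept: predictions carry no
      # subject information, so the repetition is scored at chance
      notes <- c(notes, sprintf("rep %d: uninformative model (r := 0)",
                                rep_i))
      r_rep[rep_i] <- 0
    } else r_rep[rep_i] <- cor(pc, tc)
    preds[[rep_i]] <- data.frame(subject = seq_len(ns),
                                 repetition = rep_i, predicted = pred,
                                 empirical = targets)
  }
  structure(list(r_per_repetition = r_rep,
                 mean_r = mean(r_rep, na.rm = TRUE),
                 predictions = do.call(rbind, preds),
                 masks_per_loop = masks, config = config, notes = notes),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "Prediction (%s, %s, %s): mean r = %.3f over %d repetitions%s\n",
    x$config$feature_source, x$config$cv_scheme, x$config$regressor,
    x$mean_r, sum(!is.na(x$r_per_repetition)),
    if (!is.null(x$p_value)) sprintf(", p = %.4f", x$p_value) else ""))
  invisible(x)
}

#' Label-shuffled permutation test
#'
#' Each iteration shuffles the targets once and runs one full CV round
#' (feature selection inside); the observed statistic is the mean
#' accuracy of the unpermuted run.  p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations).  Both the mean-vs-null p and the per-repetition
#' exceedance fraction are reported.
#'
#' @inheritParams run_prediction
#' @param observed an existing \code{prediction_result} for the true
#'   targets (computed if NULL)
#' @return the observed \code{prediction_result} augmented with
#'   \code{$null_distribution}, \code{$p_value},
#'   \code{$exceedance_per_repetition}
#' @export
permutation_test <- function(posteriors, targets, config,
                             observed = NULL, feature_selector = NULL,
                             feature_extractor = NULL) {
  observed <- observed %||% run_prediction(posteriors, targets, config,
                                           feature_selector,
                                           feature_extractor)
  one_cfg <- config
  one_cfg$n_repetitions <- 1L
  null_r <- rep(NA_real_, config$n_permutations)
  for (b in seq_len(config$n_permutations)) {
    set.seed(substream_seed(config$seed, "perm", b))
    ty <- sample(targets)
    one_cfg$seed <- substream_seed(config$seed, "permrun", b)
    pr <- run_prediction(posteriors, ty, one_cfg, feature_selector,
                         feature_extractor)
    null_r[b] <- pr$mean_r
  }
  null_r <- null_r[is.finite(null_r)]
  obs <- observed$mean_r
  observed$null_distribution <- null_r
  observed$p_value <- (1 + sum(null_r >= obs)) / (1 + length(null_r))
  rr <- observed$r_per_repetition
  observed$exceedance_per_repetition <-
    vapply(rr[is.finite(rr)], function(r)
      (1 + sum(null_r >= r)) / (1 + length(null_r)), 0)
  observed
}

#' Cohen's d between two accuracy distributions
#'
#' (mean1 - mean2) / pooled sd, pooled over both samples with n - 1
#' denominators.
#'
#' @param dist1,dist2 numeric vectors (each length >= 2)
#' @return scalar d
#' @export
cohens_d <- function(dist1, dist2) {
  assert_that(length(dist1) >= 2L && length(dist2) >= 2L,
              "srcdcm_config_error", "need >= 2 values per distribution")
  n1 <- length(dist1); n2 <- length(dist2)
  sp2 <- ((n1 - 1) * var(dist1) + (n2 - 1) * var(dist2)) / (n1 + n2 - 2)
  assert_that(sp2 > 0, "srcdcm_degenerate_error", "zero pooled variance")
  (mean(dist1) - mean(dist2)) / sqrt(sp2)
}

#' Feature-selection frequency across CV loops
#'
#' @param masks_per_loop list of \code{edge_mask} from a prediction run
#' @param high_threshold inclusive frequency threshold (default 0.80)
#' @return list with \code{$frequency} (named, per parameter),
#'   \code{$high_frequency_set} (names with frequency >= threshold),
#'   \code{$mean_mask_size}
#' @export
feature_frequency <- function(masks_per_loop, high_threshold = 0.80) {
  assert_that(length(masks_per_loop) >= 1L, "srcdcm_config_error",
              "need at least one mask")
  nm <- masks_per_loop[[1]]$names
  counts <- setNames(numeric(length(nm)), nm)
  sizes <- numeric(length(masks_per_loop))
  for (i in seq_along(masks_per_loop)) {
    m <- masks_per_loop[[i]]
    counts[m$names[m$mask]] <- counts[m$names[m$mask]] + 1
    sizes[i] <- sum(m$mask)
  }
  freq <- counts / length(masks_per_loop)
  list(frequency = freq,
       high_frequency_set = names(freq)[freq >= high_threshold],
       mean_mask_size = mean(sizes))
}
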