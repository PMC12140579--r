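#' Bayesian model reduction
#'
#' Given a Gaussian prior and the Gaussian posterior obtained under it,
#' the evidence of any model with a modified (reduced) prior follows
#' analytically, without refitting: switching a parameter off means
#' shrinking its reduced prior variance toward zero.
#'
#' @name bmr
NULL

as_prec <- function(v, p) {
  m <- if (is.matrix(v)) v else diag(as.numeric(v), p)
  ch <- tryCatch(chol(m), error = function(e)
    stop_srcdcm("srcdcm_numerical_error",
                "covariance not positive definite"))
  list(prec = chol2inv(ch), logdet_prec = -2 * sum(log(diag(ch))))
}

#' Change in log evidence under a reduced prior
#'
#' Computes dF = log Z(reduced) - log Z(full) from the full-model
#' posterior N(mu, Sigma), the full prior N(m0, S0) and the reduced prior
#' N(mr, Sr), via the Gaussian identity
#' dF = 1/2 (log|P| + log|Pr| - log|P0| - log|Pn|)
#'    + 1/2 (b' Pn^-1 b - mu'P mu - mr'Pr mr + m0'P0 m0),
#' with precisions P, P0, Pr, reduced-posterior precision
#' Pn = P + Pr - P0 and b = P mu + Pr mr - P0 m0.
#'
#' @param post_mean,post_cov full-model posterior (vector, matrix or
#'   variance vector)
#' @param prior_mean,prior_cov full prior
#' @param red_mean,red_cov reduced prior ("switched off" = tiny variance)
#' @return scalar dF (0 when the reduced prior equals the full prior)
#' @export
reduced_log_evidence <- function(post_mean, post_cov, prior_mean,
                                 prior_cov, red_mean, red_cov) {
  p <- length(post_mean)
  Pq <- as_prec(post_cov, p)
  P0 <- as_prec(prior_cov, p)
  Pr <- as_prec(red_cov, p)
  Pn <- Pq$prec + Pr$prec - P0$prec
  chn <- tryCatch(chol(Pn), error = function(e)
    stop_srcdcm("srcdcm_numerical_error",
                "reduced posterior precision not positive definite"))
  b <- Pq$prec %*% post_mean + Pr$prec %*% red_mean - P0$prec %*% prior_mean
  quad <- sum(backsolve(chn, b, transpose = TRUE)^2)
  c_term <- sum(post_mean * (Pq$prec %*% post_mean)) +
    sum(red_mean * (Pr$prec %*% red_mean)) -
    sum(prior_mean * (P0$prec %*% prior_mean))
  logdet_Pn <- 2 * sum(log(diag(chn)))
  0.5 * (Pq$logdet_prec + Pr$logdet_prec - P0$logdet_prec - logdet_Pn) +
    0.5 * (quad - c_term)
}

#' Reduce a prior by switching parameters off
#' @param prior_mean,prior_cov full prior (vector mean; matrix or
#'   variance vector)
#' @param off indices to switch off
#' @param off_var variance assigned to switched-off parameters
#' @return list(mean, cov)
#' @export
reduce_prior <- function(prior_mean, prior_cov, off, off_var = 1e-8) {
  p <- length(prior_mean)
  S <- if (is.matrix(prior_cov)) prior_cov else diag(as.numeric(prior_cov), p)
  m <- prior_mean
  m[off] <- 0
  S[off, ] <- 0
  S[, off] <- 0
  diag(S)[off] <- off_var
  list(mean = m, cov = S)
}

bmr_model_evidence <- function(gauss, off, off_var) {
  if (length(off) == 0L) return(0)
  red <- reduce_prior(gauss$prior_mean, gauss$prior_cov, off, off_var)
  reduced_log_evidence(gauss$mean, gauss$cov, gauss$prior_mean,
                       gauss$prior_cov, red$mean, red$cov)
}

#' Search over reduced models
#'
#' Explores the family of models obtained by switching subsets of
#' parameters off.  For a \code{peb_result} the per-parameter
#' factorization makes the exhaustive search exact and linear in the
#' number of parameters.  For a generic Gaussian (list with \code{mean},
#' \code{cov}, \code{prior_mean}, \code{prior_cov}) subsets are
#' enumerated exhaustively up to \code{max_exhaustive_params} free
#' parameters, beyond which greedy backward pruning is used.
#'
#' @param obj a \code{peb_result} or a generic Gaussian list
#' @param strategy "auto", "exhaustive" or "greedy"
#' @param max_exhaustive_params exhaustive enumeration cap (default 16)
#' @param pp_threshold mask threshold on the model-averaged PP
#' @param off_var reduced prior variance for switched-off parameters
#' @param column for \code{peb_result} input: which design column to
#'   prune (default "covariate")
#' @return list with \code{$winner_off} (indices switched off in the
#'   best model), \code{$winner_dF}, \code{$pp} (Bayesian-model-averaged
#'   per-parameter PP), \code{$mask} (an \code{edge_mask} for PEB input,
#'   logical vector otherwise), \code{$n_models}
#' @export
bmr_search <- function(obj, strategy = c("auto", "exhaustive", "greedy"),
                       max_exhaustive_params = 16L, pp_threshold = 0.95,
                       off_var = 1e-8, column = "covariate") {
  strategy <- match.arg(strategy)
  if (inherits(obj, "peb_result")) {
    col <- match.arg(column, c("covariate", "mean"))
    ci <- if (col == "covariate") 2L else 1L
    p <- nrow(obj$effect_means)
    # evidence change when parameter j alone is switched off; recovered
    # from the stored PP = sigmoid(F_on - F_off) of the factorized blocks
    ppc <- pmin(pmax(obj$pp[, ci], 1e-12), 1 - 1e-12)
    dF_off <- log(1 / ppc - 1)
    # dF_off = F(off) - F(on); best model switches off where positive
    off <- which(dF_off > 0)
    pp <- 1 / (1 + exp(dF_off))
    mask <- structure(list(mask = pp > pp_threshold,
                           param_idx = obj$param_idx, names = obj$names,
                           matrix_kind = obj$which, design_column = col,
                           provenance = list(method = "BMR",
                                             threshold = pp_threshold,
                                             covariate =
                                               obj$design$covariate_name)),
                      class = "edge_mask")
    return(list(winner_off = off, winner_dF = sum(dF_off[off]), pp = pp,
                mask = mask, n_models = 2^min(p, 30)))
  }

  gauss <- obj
  p <- length(gauss$mean)
  cand <- seq_len(p)
  if (strategy == "auto")
    strategy <- if (p <= max_exhaustive_params) "exhaustive" else "greedy"
  models <- list()
  if (strategy == "exhaustive") {
    assert_that(p <= max_exhaustive_params, "srcdcm_config_error",
                "exhaustive search limited to %d parameters",
                max_exhaustive_params)
    for (code in 0:(2^p - 1)) {
      off <- cand[bitwAnd(code, bitwShiftL(1L, cand - 1L)) != 0L]
      models[[length(models) + 1L]] <-
        list(off = off, F = bmr_model_evidence(gauss, off, off_var))
    }
  } else {
    off <- integer()
    Fcur <- 0
    models[[1L]] <- list(off = off, F = Fcur)
    repeat {
      rest <- setdiff(cand, off)
      if (length(rest) == 0L) break
      Fs <- vapply(rest, function(j)
        bmr_model_evidence(gauss, c(off, j), off_var), 0)
      for (k in seq_along(rest))
        models[[length(models) + 1L]] <-
          list(off = c(off, rest[k]), F = Fs[k])
      best <- which.max(Fs)
      if (Fs[best] <= Fcur) break
      off <- c(off, rest[best])
      Fcur <- Fs[best]
    }
  }
  Fv <- vapply(models, `[[`, 0, "F")
  w <- exp(Fv - max(Fv))
  w <- w / sum(w)
  pp <- vapply(cand, function(j)
    sum(w[vapply(models, function(m) !(j %in% m$off), TRUE)]), 0)
  best <- which.max(Fv)
  list(winner_off = models[[best]]$off, winner_dF = Fv[best], pp = pp,
       mask = pp > pp_threshold, n_models = length(models))
}
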