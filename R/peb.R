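#' Parametric empirical Bayes over subject DCM posteriors
#'
#' Second-level Bayesian GLM relating subject-level connectivity
#' posteriors to a two-column design matrix (group mean + one
#' mean-centered covariate).  Each connectivity parameter is modeled
#' independently: subject posterior means are the data, subject posterior
#' variances enter as known first-level uncertainty, and a single
#' between-subject variance component per parameter is profiled by
#' marginal likelihood.  Per-parameter posterior probabilities (PP) come
#' from Bayesian model comparison of the with-effect vs. without-effect
#' reduced models, PP = 1 / (1 + exp(-dF)).
#'
#' @name peb
NULL

#' Build the two-column PEB design matrix
#'
#' Column 1 is all ones (group mean); column 2 is the covariate centered
#' within the provided (training) sample.
#'
#' @param scores numeric covariate values, one per subject
#' @param covariate_name label for the covariate column
#' @return object of class \code{peb_design}: \code{$X}
#'   (n_subjects x 2), \code{$covariate_name}
#' @export
build_design_matrix <- function(scores, covariate_name = "covariate") {
  assert_that(length(scores) >= 2L, "srcdcm_config_error",
              "need >= 2 subjects")
  assert_that(all(is.finite(scores)), "srcdcm_degenerate_design_error",
              "non-finite covariate values")
  centered <- scores - mean(scores)
  assert_that(sd(scores) > 0, "srcdcm_degenerate_design_error",
              "constant covariate")
  X <- cbind(mean = 1, covariate = centered)
  structure(list(X = X, covariate_name = covariate_name),
            class = "peb_design")
}

# Marginal log evidence of the per-parameter GLM, integrating beta out:
# y ~ N(0, X Vb X' + diag(s2 + gamma)).  O(n) via Woodbury (q columns).
peb_evidence <- function(y, X, s2, vb, gamma) {
  keep <- vb > 0
  n <- length(y)
  di <- 1 / (s2 + gamma)
  if (!any(keep)) {
    ld <- -sum(log(di))
    return(-0.5 * (n * log(2 * pi) + ld + sum(y^2 * di)))
  }
  Xk <- X[, keep, drop = FALSE]
  vbk <- vb[keep]
  Xd <- Xk * di
  M <- diag(1 / vbk, length(vbk)) + crossprod(Xk, Xd)
  ch <- chol(M)
  b <- crossprod(Xd, y)
  quad <- sum(y^2 * di) - sum(backsolve(ch, b, transpose = TRUE)^2)
  ld <- -sum(log(di)) + 2 * sum(log(diag(ch))) + sum(log(vbk))
  -0.5 * (n * log(2 * pi) + ld + quad)
}

peb_posterior_beta <- function(y, X, s2, vb, gamma) {
  di <- 1 / (s2 + gamma)
  Xd <- X * di
  M <- diag(1 / vb, length(vb)) + crossprod(X, Xd)
  Sigma <- solve(M)
  mu <- Sigma %*% crossprod(Xd, y)
  list(mean = as.vector(mu), cov = Sigma)
}

#' Fit the group-level PEB model
#'
#' @param posteriors list of \code{dcm_posterior} (all sharing one
#'   parameter layout); subjects flagged \code{excluded} are dropped with
#'   their design rows
#' @param design a \code{peb_design} whose rows align with
#'   \code{posteriors}
#' @param which parameter subset: "A" (intrinsic), "B" (modulatory),
#'   "AB" (both)
#' @param beta_prior_var optional length-2 prior variances for the two
#'   design columns; default: the parameter-class prior variance for both
#' @return object of class \code{peb_result}: \code{$effect_means}
#'   (p x 2), \code{$effect_vars} (p x 2 posterior variances), \code{$pp}
#'   (p x 2 posterior probabilities), \code{$gamma} (between-subject
#'   variances), \code{$free_energy}, \code{$param_idx} (indices into the
#'   layout), \code{$names}, \code{$spec}, \code{$design}
#' @export
fit_peb <- function(posteriors, design, which = c("B", "A", "AB"),
                    beta_prior_var = NULL) {
  which <- match.arg(which)
  assert_that(length(posteriors) == nrow(design$X),
              "srcdcm_alignment_error",
              "design has %d rows but %d posteriors given",
              nrow(design$X), length(posteriors))
  spec <- posteriors[[1]]$spec
  for (p in posteriors)
    assert_that(identical(p$spec$table$name, spec$table$name),
                "srcdcm_alignment_error",
                "posteriors do not share a parameter layout")
  keep_sub <- !vapply(posteriors, function(p) isTRUE(p$excluded), TRUE)
  posteriors <- posteriors[keep_sub]
  X <- design$X[keep_sub, , drop = FALSE]
  X[, 2] <- X[, 2] - mean(X[, 2])   # re-center within retained subjects
  ns <- length(posteriors)
  assert_that(ns >= 3L, "srcdcm_degenerate_design_error",
              "fewer than 3 usable subjects")

  idx <- param_indices(spec, which)
  p <- length(idx)
  mu_mat <- vapply(posteriors, function(q) unname(q$mean[idx]),
                   numeric(p))
  s2_mat <- vapply(posteriors, function(q) pmax(diag(q$cov)[idx], 0),
                   numeric(p))
  class_var <- dcm_priors(spec)$var[idx]

  eff_mean <- matrix(NA_real_, p, 2L)
  eff_var <- matrix(NA_real_, p, 2L)
  pp <- matrix(NA_real_, p, 2L)
  gam <- numeric(p)
  Ftot <- 0
  for (j in seq_len(p)) {
    y <- mu_mat[j, ]
    s2 <- s2_mat[j, ]
    vb <- beta_prior_var %||% rep(class_var[j], 2L)
    fgam <- function(lg) peb_evidence(y, X, s2, vb, exp(lg))
    og <- optimize(fgam, c(-20, 5), maximum = TRUE)
    g <- exp(og$maximum)
    Ffull <- og$objective
    post <- peb_posterior_beta(y, X, s2, vb, g)
    eff_mean[j, ] <- post$mean
    eff_var[j, ] <- diag(post$cov)
    for (cc in 1:2) {
      vb_off <- vb
      vb_off[cc] <- 0
      dF <- Ffull - peb_evidence(y, X, s2, vb_off, g)
      pp[j, cc] <- 1 / (1 + exp(-dF))
    }
    gam[j] <- g
    Ftot <- Ftot + Ffull
  }
  dimnames(eff_mean) <- dimnames(eff_var) <- dimnames(pp) <-
    list(spec$table$name[idx], c("mean", "covariate"))
  structure(list(effect_means = eff_mean, effect_vars = eff_var, pp = pp,
                 gamma = gam, free_energy = Ftot, param_idx = idx,
                 names = spec$table$name[idx], which = which, spec = spec,
                 design = design, n_subjects = ns),
            class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf(
    "PEB (%s, %d subjects, covariate '%s'): %d params, %d with covariate PP > 0.95\n",
    x$which, x$n_subjects, x$design$covariate_name, nrow(x$pp),
    sum(x$pp[, 2] > 0.95)))
  invisible(x)
}

#' Threshold PEB posterior probabilities into a feature mask
#'
#' Strict inequality: a parameter with PP exactly at the threshold is
#' excluded.
#'
#' @param peb a \code{peb_result}
#' @param column "covariate" (default) or "mean"
#' @param threshold PP threshold in (0, 1); default 0.95
#' @return object of class \code{edge_mask}: \code{$mask} (logical over
#'   the PEB's parameter subset), \code{$param_idx}, \code{$names},
#'   \code{$provenance}
#' @export
pp_mask <- function(peb, column = c("covariate", "mean"),
                    threshold = 0.95) {
  column <- match.arg(column)
  assert_that(threshold > 0 && threshold < 1, "srcdcm_config_error",
              "threshold must lie in (0, 1)")
  m <- peb$pp[, column] > threshold
  structure(list(mask = unname(m), param_idx = peb$param_idx,
                 names = peb$names, matrix_kind = peb$which,
                 design_column = column,
                 provenance = list(method = "PEB", threshold = threshold,
                                   covariate = peb$design$covariate_name)),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("Edge mask (%s, %s column, %s): %d / %d selected\n",
              x$matrix_kind, x$design_column, x$provenance$method,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Export an edge mask as a from/to edge list
#' @param mask an \code{edge_mask}
#' @return data.frame(from_node, to_node, matrix_kind, name)
#' @export
mask_edge_list <- function(mask) {
  sel <- which(mask$mask)
  spec_tab <- NULL
  nm <- mask$names[sel]
  parts <- regmatches(nm, regexec("^([ABC][a-z]*):(.*)->(.*)$", nm))
  data.frame(
    name = nm,
    from_node = vapply(parts, function(p)
      if (length(p) == 4) p[3] else NA_character_, ""),
    to_node = vapply(parts, function(p)
      if (length(p) == 4) p[4] else NA_character_, ""),
    matrix_kind = vapply(parts, function(p)
      if (length(p) == 4) p[2] else NA_character_, ""))
}
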