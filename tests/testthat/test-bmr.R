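test_that("reduced log evidence matches scalar Gaussian algebra", {
  # identity reduction
  expect_equal(reduced_log_evidence(0.8, 0.04, 0, 0.5, 0, 0.5), 0,
               tolerance = 1e-12)
  # 1-D case against a numerical-integration oracle:
  # Z_r / Z = E_q[p_r(theta) / p_0(theta)]
  for (vr in c(0.05, 0.2)) {
    dF <- reduced_log_evidence(0.8, 0.04, 0.1, 0.5, -0.1, vr)
    g <- function(th) dnorm(th, 0.8, sqrt(0.04)) *
      dnorm(th, -0.1, sqrt(vr)) / dnorm(th, 0.1, sqrt(0.5))
    num <- log(integrate(g, -6, 6, rel.tol = 1e-13)$value)
    expect_equal(dF, num, tolerance = 1e-8)
  }
  # pruning a tightly-estimated nonzero parameter loses much evidence
  expect_lt(reduced_log_evidence(0.8, 4e-4, 0, 0.5, 0, 1e-8), -100)
  expect_error(reduced_log_evidence(0, matrix(c(1, 2, 2, 1), 2), c(0, 0),
                                    diag(2), c(0, 0), diag(2)),
               class = "srcdcm_numerical_error")
})

# a data-informed 3-parameter posterior: theta true = (0.5, 0, -0.4)
toy3 <- function() {
  set.seed(5)
  X <- matrix(rnorm(300), 100, 3)
  y <- X %*% c(0.5, 0, -0.4) + rnorm(100, 0, 0.3)
  v0 <- 0.3
  Sigma <- solve(crossprod(X) / 0.09 + diag(1 / v0, 3))
  mu <- Sigma %*% (crossprod(X, y) / 0.09)
  list(mean = as.vector(mu), cov = Sigma, prior_mean = rep(0, 3),
       prior_cov = diag(v0, 3))
}

test_that("exhaustive BMR prunes exactly the null parameter", {
  gauss <- toy3()
  bs <- bmr_search(gauss, "exhaustive")
  expect_equal(bs$winner_off, 2L)
  expect_equal(bs$n_models, 8L)
  expect_true(bs$pp[1] > 0.95 && bs$pp[3] > 0.95 && bs$pp[2] < 0.95)
  # matches brute-force enumeration of all 8 submodels
  brute <- vapply(0:7, function(code) {
    off <- which(bitwAnd(code, c(1L, 2L, 4L)) != 0L)
    if (!length(off)) return(0)
    red <- reduce_prior(gauss$prior_mean, gauss$prior_cov, off)
    reduced_log_evidence(gauss$mean, gauss$cov, gauss$prior_mean,
                         gauss$prior_cov, red$mean, red$cov)
  }, 0)
  expect_equal(bs$winner_dF, max(brute), tolerance = 1e-10)
  w <- exp(brute - max(brute)); w <- w / sum(w)
  on2 <- bitwAnd(0:7, 2L) == 0L
  expect_equal(bs$pp[2], sum(w[on2]), tolerance = 1e-10)
})

test_that("a fully supported model keeps all parameters", {
  gauss <- toy3()
  gauss$mean[2] <- 0.6   # make every parameter well supported
  bs <- bmr_search(gauss, "exhaustive")
  expect_length(bs$winner_off, 0)
  expect_true(all(bs$pp > 0.95))
})

test_that("greedy search agrees with exhaustive on random instances", {
  set.seed(77)
  agree <- 0L
  for (i in 1:50) {
    p <- 8L
    L <- matrix(rnorm(p * p, 0, 0.1), p, p)
    Sigma <- crossprod(L) + diag(0.02, p)
    mu <- rnorm(p, 0, 0.25) * rbinom(p, 1, 0.6)
    gauss <- list(mean = mu, cov = Sigma, prior_mean = rep(0, p),
                  prior_cov = diag(0.3, p))
    ex <- bmr_search(gauss, "exhaustive")
    gr <- bmr_search(gauss, "greedy")
    if (setequal(ex$winner_off, gr$winner_off)) agree <- agree + 1L
  }
  expect_gte(agree, 45L)  # >= 90% of 50 seeded draws
})

test_that("BMR on a PEB result shares the PP definition with pp_mask", {
  tr <- fx_cohort60()
  posts <- fx_posts60()
  peb <- fit_peb(posts, build_design_matrix(tr$scores$rt_like, "rt"),
                 which = "B")
  bs <- bmr_search(peb)
  expect_equal(unname(bs$pp), unname(peb$pp[, "covariate"]),
               tolerance = 1e-9)
  expect_equal(unname(bs$mask$mask),
               unname(peb$pp[, "covariate"] > 0.95))
  expect_equal(bs$mask$provenance$method, "BMR")
  # parameters switched off are exactly those with PP < 0.5
  expect_setequal(unname(bs$winner_off),
                  unname(which(peb$pp[, "covariate"] < 0.5)))
})

test_that("analytic reduction matches direct re-inversion within 0.5 nats", {
  enc <- fx_encoding(6L)
  th <- theta2()           # A:n2->n1 is truly zero
  pm <- theta_to_params(th, spec2())
  clean <- predict_bold(pm, hemo_params(), enc, TRdef)
  nsd <- pmax(apply(clean, 2, sd), 0.25 * max(apply(clean, 2, sd))) / 3
  set.seed(7)
  y <- clean + matrix(rnorm(length(clean)), nrow(clean)) %*% diag(nsd, 2)
  lam <- 1 / nsd^2
  pri <- dcm_priors(spec2())
  post <- invert_dcm(y, enc, pri, options = list(
    TR = TRdef, lambda_fixed = lam, tol = 1e-6))
  k <- which(spec2()$table$name == "A:n2->n1")
  red <- reduce_prior(pri$mean, pri$var, k)
  dF_analytic <- reduced_log_evidence(post$mean, post$cov, pri$mean,
                                      diag(pri$var), red$mean, red$cov)
  pri_red <- pri
  pri_red$var[k] <- 1e-8
  post_red <- invert_dcm(y, enc, pri_red, options = list(
    TR = TRdef, lambda_fixed = lam, tol = 1e-6))
  dF_reinv <- post_red$free_energy - post$free_energy
  expect_lt(abs(dF_analytic - dF_reinv), 0.5)
})
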