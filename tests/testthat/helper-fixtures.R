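# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

TRdef <- 2.03

# short paradigm + event encoding shared by the heavier tests
fx_paradigm <- function(blocks = 6L, seed = 3L) {
  fixture(sprintf("par_%d_%d", blocks, seed),
          generate_paradigm(seed, list(n_blocks = blocks)))
}

fx_encoding <- function(blocks = 6L, seed = 3L, design = "event") {
  fixture(sprintf("enc_%d_%d_%s", blocks, seed, design),
          encode_inputs(fx_paradigm(blocks, seed), design, dt = TRdef / 16))
}

# two-node toy model: A coupling n1 -> n2, driving input into n1
spec2 <- function() fixture("spec2", make_param_spec(2L, c("n1", "n2"), 1L))

theta2 <- function(a12 = 0.3, b12 = 0.3, c1 = 0.5) {
  sp <- spec2()
  th <- setNames(rep(0, sp$n_free), sp$table$name)
  th["A:n1->n2"] <- a12
  th["B:n1->n2"] <- b12
  th["C:driving->n1"] <- c1
  th
}

# noisy two-node subject with per-node noise floored as in the generator
sim2 <- function(th, enc, snr = 3, seed = 1L) {
  pm <- theta_to_params(th, spec2())
  clean <- predict_bold(pm, hemo_params(), enc, TRdef)
  nsd <- pmax(apply(clean, 2, sd), 0.25 * max(apply(clean, 2, sd))) / snr
  set.seed(seed)
  clean + matrix(rnorm(length(clean)), nrow(clean)) %*% diag(nsd, 2)
}

# default pseudo-posterior cohort reused by PEB / prediction tests
fx_cohort60 <- function() fixture("coh60", sample_cohort_truth(60, seed = 11))
fx_posts60 <- function() fixture("posts60",
                                 pseudo_posteriors(fx_cohort60(), 0.02, 12))

# positions (in the free-parameter vector) of planted effect edges
planted_positions <- function(truth, which = c("B", "A")) {
  which <- match.arg(which)
  ix <- truth$spec$idx
  if (which == "B") ix$B_pos[ix$B_lin %in% truth$effect_edges_B]
  else ix$A_pos[ix$A_lin %in% truth$effect_edges_A]
}
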