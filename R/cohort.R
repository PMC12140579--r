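#' Synthetic subject cohorts with planted score-connectivity structure
#'
#' Stand-in for the unavailable empirical cohort: each subject owns
#' ground-truth A/B/C matrices whose entries covary linearly with two
#' subject scores.  An RT-like score (truncated Normal(0.55 s, 0.08 s) on
#' [0.15, 1.5]) is planted in the task-modulated B matrix and an age-like
#' score (Uniform(18, 85) years) in the intrinsic A matrix - the
#' dissociation the downstream prediction analysis is meant to recover.
#' BOLD is generated by the same forward model the inversion uses, plus
#' i.i.d. Gaussian observation noise scaled to a target SNR.
#'
#' @name cohort
NULL

default_cohort_spec <- function() {
  list(n_effect_edges = 4L,
       beta_B = 2.0,          # Hz per second of RT-like score
       beta_A = 0.005,        # Hz per year of age-like score
       mean_B_effect = 0.3,   # group-mean B on effect edges
       n_base_B = 4L,         # extra nonzero group-mean B edges
       mean_B_base = 0.25,
       # group-mean A: sparse strong couplings over a weak background
       strong_edge_prob = 0.25,
       strong_mean = 0.20, strong_sd = 0.05,
       sd_A_off = 0.02,       # background off-diagonal spread
       param_noise_sd = 0.03, # i.i.d. per-edge subject noise (Hz)
       self_log_sd = 0.0625,  # subject spread of self-connection log scale
       C_gain = 0.5, C_noise_sd = 0.05,
       target_snr = 3,        # sd(signal) / noise_sd
       rt_mean = 0.55, rt_sd = 0.08, rt_lo = 0.15, rt_hi = 1.5,
       age_lo = 18, age_hi = 85,
       max_retries = 50L)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

sample_offdiag_edges <- function(n, k, exclude = NULL) {
  all_edges <- which(diag(n) == 0)          # linear indices, i != j
  if (!is.null(exclude)) all_edges <- setdiff(all_edges, exclude)
  sample(all_edges, k)
}

#' Sample ground-truth cohort parameters
#'
#' @param n_subjects number of subjects (>= 2)
#' @param spec named list overriding \code{default_cohort_spec()} entries
#'   (effect sizes, edge counts, noise levels, score distributions)
#' @param seed integer seed
#' @param node_labels node names (default: the 9 SRC ROIs)
#' @param driving_nodes nodes receiving the driving input
#' @return object of class \code{cohort_truth}: per-subject
#'   \code{dcm_params} in \code{$params}, scores table \code{$scores}
#'   (subject_id, rt_like, age_like), group means, effect matrices
#'   \code{$beta_A}/\code{$beta_B}, effect edge sets (linear indices into
#'   the n x n matrices, row = target), and the parameter layout
#'   \code{$spec}.
#' @export
sample_cohort_truth <- function(n_subjects = 60L, spec = list(), seed = 1L,
                                node_labels = src_nodes(),
                                driving_nodes = c("IPS_L", "IPS_R")) {
  assert_that(n_subjects >= 2L, "srcdcm_config_error",
              "need at least 2 subjects")
  cs <- modifyList(default_cohort_spec(), spec)
  n <- length(node_labels)
  set.seed(seed)
  pspec <- make_param_spec(n, node_labels, driving_nodes)
  drv <- pspec$driving_nodes

  # group-mean A: a sparse set of strong couplings (random sign) over a
  # weak background, redrawn until the baseline dynamics are stable
  draw_gm_A <- function() {
    A <- matrix(rnorm(n * n, 0, cs$sd_A_off), n, n)
    strong <- matrix(runif(n * n) < cs$strong_edge_prob, n, n)
    A[strong] <- rnorm(sum(strong), cs$strong_mean, cs$strong_sd) *
      sample(c(-1, 1), sum(strong), replace = TRUE)
    diag(A) <- -0.5
    A
  }
  gm_A <- draw_gm_A()
  st <- stability_check(gm_A)
  tries <- 0L
  while (!st$stable && tries < cs$max_retries) {
    gm_A <- draw_gm_A()
    st <- stability_check(gm_A)
    tries <- tries + 1L
  }
  assert_that(st$stable, "srcdcm_spec_error",
              "could not draw a stable group-mean A")
  effect_edges_A <- sample_offdiag_edges(n, cs$n_effect_edges)
  effect_edges_B <- sample_offdiag_edges(n, cs$n_effect_edges,
                                         exclude = effect_edges_A)
  base_B <- sample_offdiag_edges(n, cs$n_base_B,
                                 exclude = c(effect_edges_A, effect_edges_B))
  gm_B <- matrix(0, n, n)
  gm_B[effect_edges_B] <- cs$mean_B_effect
  gm_B[base_B] <- cs$mean_B_base
  beta_A <- matrix(0, n, n); beta_A[effect_edges_A] <- cs$beta_A
  beta_B <- matrix(0, n, n); beta_B[effect_edges_B] <- cs$beta_B

  scores <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
    rt_like = rtrunc_norm(n_subjects, cs$rt_mean, cs$rt_sd, cs$rt_lo,
                          cs$rt_hi),
    age_like = runif(n_subjects, cs$age_lo, cs$age_hi))
  rt_c <- scores$rt_like - mean(scores$rt_like)
  age_c <- scores$age_like - mean(scores$age_like)

  off <- which(diag(n) == 0)
  params <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ok <- FALSE
    for (try in seq_len(cs$max_retries)) {
      A <- gm_A + beta_A * age_c[i]
      A[off] <- A[off] + rnorm(length(off), 0, cs$param_noise_sd)
      diag(A) <- -0.5 * exp(rnorm(n, 0, cs$self_log_sd))
      if (stability_check(A)$stable) { ok <- TRUE; break }
    }
    assert_that(ok, "srcdcm_spec_error",
                "subject %d: no stable A after %d retries", i,
                cs$max_retries)
    B <- gm_B + beta_B * rt_c[i]
    B[off] <- B[off] + rnorm(length(off), 0, cs$param_noise_sd)
    diag(B) <- 0
    C <- matrix(0, n, 2L)
    C[drv, 1L] <- cs$C_gain + rnorm(length(drv), 0, cs$C_noise_sd)
    params[[i]] <- dcm_params(A, B, C, node_labels)
  }
  structure(list(n_subjects = n_subjects, node_labels = node_labels,
                 params = params, scores = scores,
                 group_mean_A = gm_A, group_mean_B = gm_B,
                 beta_A = beta_A, beta_B = beta_B,
                 effect_edges_A = effect_edges_A,
                 effect_edges_B = effect_edges_B,
                 cohort_spec = cs, spec = pspec, seed = seed),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d nodes; rt_like planted on %d B edges, age_like on %d A edges\n",
    x$n_subjects, length(x$node_labels), length(x$effect_edges_B),
    length(x$effect_edges_A)))
  invisible(x)
}

#' Simulate one subject's ROI BOLD time series
#'
#' Integrates the subject's ground-truth dynamics under the stimulus
#' encoding, samples BOLD at the scan times, and adds i.i.d. Gaussian
#' observation noise per node.
#'
#' @param truth_i a \code{dcm_params} (one subject's ground truth)
#' @param enc a \code{stim_encoding}
#' @param hemo a \code{hemo_params}
#' @param TR repetition time (s); default 2.03
#' @param noise_sd observation-noise standard deviation (scalar or one
#'   value per node); if \code{NULL}, set per node as sd(noise-free
#'   node signal) / SNR, floored at one quarter of the strongest node's
#'   level so silent nodes are not given unrealistically clean data
#' @param seed integer seed for the noise draw
#' @param target_snr used when \code{noise_sd} is NULL (default 3)
#' @param subject_id label carried in the output
#' @return object of class \code{roi_timeseries}: \code{$data} (T x n),
#'   \code{$TR}, \code{$node_labels}, \code{$subject_id},
#'   \code{$noise_sd}
#' @export
simulate_subject_bold <- function(truth_i, enc, hemo = hemo_params(),
                                  TR = 2.03, noise_sd = NULL, seed = 1L,
                                  target_snr = 3, subject_id = "sub-001") {
  st <- stability_check(truth_i$A)
  assert_that(st$stable, "srcdcm_dynamics_error",
              "unstable A (leading eigenvalue %.3f)", st$leading)
  clean <- predict_bold(truth_i, hemo, enc, TR)
  if (is.null(noise_sd)) {
    node_sd <- apply(clean, 2, sd)
    noise_sd <- pmax(node_sd, 0.25 * max(node_sd)) / target_snr
  }
  set.seed(seed)
  noisy <- clean + matrix(rnorm(length(clean), 0, 1), nrow(clean)) %*%
    diag(rep(noise_sd, length.out = ncol(clean)), ncol(clean))
  structure(list(data = noisy, TR = TR,
                 node_labels = truth_i$node_labels,
                 subject_id = subject_id, noise_sd = noise_sd,
                 signal_sd = sd(as.vector(clean))),
            class = "roi_timeseries")
}

#' Simulate BOLD for a whole cohort
#' @param truth a \code{cohort_truth}
#' @param enc a \code{stim_encoding}
#' @param hemo a \code{hemo_params}
#' @param TR repetition time (s)
#' @param seed master seed; per-subject noise uses sub-stream seeds
#' @return list of \code{roi_timeseries}
#' @export
simulate_cohort_bold <- function(truth, enc, hemo = hemo_params(),
                                 TR = 2.03, seed = 1L) {
  lapply(seq_len(truth$n_subjects), function(i)
    simulate_subject_bold(truth$params[[i]], enc, hemo, TR,
                          noise_sd = NULL,
                          seed = substream_seed(seed, "bold", i),
                          target_snr = truth$cohort_spec$target_snr,
                          subject_id = truth$scores$subject_id[i]))
}

#' Pseudo-posteriors from cohort ground truth
#'
#' Builds first-level posterior stand-ins directly from the generating
#' truth: posterior mean = true parameter vector plus i.i.d. Gaussian
#' estimation noise, posterior covariance = sd^2 I.  Used to exercise the
#' group-level (PEB) and prediction machinery at scale without running
#' per-subject variational inversions.
#'
#' @param truth a \code{cohort_truth}
#' @param sd estimation-noise standard deviation (default 0.02)
#' @param seed integer seed
#' @return list of \code{dcm_posterior}-like objects
#' @export
pseudo_posteriors <- function(truth, sd = 0.02, seed = 1L) {
  set.seed(seed)
  spec <- truth$spec
  lapply(seq_len(truth$n_subjects), function(i) {
    th <- params_to_theta(truth$params[[i]], spec)
    th <- th + rnorm(length(th), 0, sd)
    structure(list(mean = th,
                   cov = diag(sd^2, spec$n_free),
                   free_energy = NA_real_, explained_variance = 1,
                   excluded = FALSE, converged = TRUE, spec = spec),
              class = "dcm_posterior")
  })
}

#' Write / read a cohort directory
#'
#' Layout: \code{<sub>_ts.tsv} per subject (tab-delimited, header of node
#' labels), \code{scores.csv} (subject_id, rt_like, age_like),
#' \code{meta.json} (TR, node labels, subject ids) and optionally
#' \code{truth.json}.
#'
#' @param ts_list list of \code{roi_timeseries}
#' @param scores scores data.frame
#' @param directory output directory
#' @param truth optional \code{cohort_truth} to serialize alongside
#' @return \code{read_cohort} returns list(ts, scores, meta).
#' @export
write_cohort <- function(ts_list, scores, directory, truth = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (ts in ts_list)
    write_timeseries(ts, file.path(directory,
                                   paste0(ts$subject_id, "_ts.tsv")))
  write.csv(scores, file.path(directory, "scores.csv"), row.names = FALSE)
  meta <- list(TR = ts_list[[1]]$TR,
               node_labels = ts_list[[1]]$node_labels,
               subject_ids = vapply(ts_list, `[[`, "", "subject_id"))
  jsonlite::write_json(meta, file.path(directory, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- list(seed = truth$seed, cohort_spec = truth$cohort_spec,
               node_labels = truth$node_labels,
               effect_edges_A = truth$effect_edges_A,
               effect_edges_B = truth$effect_edges_B,
               group_mean_A = truth$group_mean_A,
               group_mean_B = truth$group_mean_B,
               beta_A = truth$beta_A, beta_B = truth$beta_B,
               theta = lapply(truth$params, function(p)
                 unname(params_to_theta(p, truth$spec))))
    jsonlite::write_json(tr, file.path(directory, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  meta_path <- file.path(directory, "meta.json")
  assert_that(file.exists(meta_path), "srcdcm_format_error",
              "missing meta.json sidecar (TR unknown) in %s", directory)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  assert_that(!is.null(meta$TR), "srcdcm_format_error",
              "meta.json lacks TR")
  scores <- read.csv(file.path(directory, "scores.csv"))
  ts <- lapply(meta$subject_ids, function(sid) {
    p <- file.path(directory, paste0(sid, "_ts.tsv"))
    read_timeseries(p, TR = meta$TR, subject_id = sid)
  })
  list(ts = ts, scores = scores, meta = meta)
}
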