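#' Integrate the bilinear neural state equation
#'
#' Advances dz/dt = (A + sum_k B_k u_k(t)) z + C u(t) on the microtime
#' grid of the encoding with an exact matrix-exponential step per grid
#' interval (inputs are piecewise constant), so linear test cases are
#' reproduced to machine precision.
#'
#' @param params a \code{dcm_params}
#' @param enc a \code{stim_encoding} (or a plain matrix u, with \code{dt})
#' @param z0 initial state (default zeros)
#' @param dt microtime step; defaults to the encoding's step
#' @return matrix (n_timepoints x n_nodes) of neural states
#' @export
integrate_neural <- function(params, enc, z0 = NULL, dt = NULL) {
  u <- if (inherits(enc, "stim_encoding")) enc$u else enc
  dt <- dt %||% (if (inherits(enc, "stim_encoding")) enc$dt else
    stop_srcdcm("srcdcm_config_error", "dt required for raw input matrix"))
  n <- params$n_nodes
  z0 <- z0 %||% rep(0, n)
  assert_that(all(is.finite(z0)) && length(z0) == n, "srcdcm_shape_error",
              "z0 must be finite of length %d", n)
  B <- b_cube(params)
  z <- cpp_integrate_neural(params$A, B, pad_C(params, ncol(u)), u, dt, z0)
  if (anyNA(z)) {
    st <- stability_check(params$A)
    stop_srcdcm("srcdcm_instability_error",
                "neural trajectory diverged (leading eigenvalue %.3f)",
                st$leading)
  }
  colnames(z) <- params$node_labels
  z
}

# B as a cube aligned with input columns: input 1 (driving) unmodulated,
# inputs 2.. carry the B matrices.
b_cube <- function(params, n_inputs = NULL) {
  Bl <- params$B
  n <- params$n_nodes
  m <- n_inputs %||% (length(Bl) + 1L)
  arr <- array(0, c(n, n, m))
  for (k in seq_along(Bl)) if (k + 1L <= m) arr[, , k + 1L] <- Bl[[k]]
  arr
}

pad_C <- function(params, m) {
  C <- params$C
  if (ncol(C) < m) C <- cbind(C, matrix(0, nrow(C), m - ncol(C)))
  C[, seq_len(m), drop = FALSE]
}

#' Balloon-model hemodynamic observation
#'
#' Maps neural states to BOLD via the extended balloon model
#' (vasodilatory signal, blood flow, venous volume, deoxyhemoglobin),
#' integrated by RK4 on the same grid; output is the deviation from
#' hemodynamic baseline, so z = 0 yields BOLD = 0.
#'
#' @param z matrix (n_timepoints x n_nodes) of neural states
#' @param hemo a \code{hemo_params}
#' @param dt grid step in seconds
#' @return matrix of BOLD deviations, same shape as \code{z}
#' @export
hemodynamic_forward <- function(z, hemo = hemo_params(), dt) {
  assert_that(all(is.finite(z)), "srcdcm_numerical_error",
              "neural trajectory contains non-finite values")
  y <- cpp_hemo_forward(as.matrix(z), dt, hemo$kappa, hemo$gamma, hemo$tau,
                        hemo$alpha, hemo$E0, hemo$V0)
  if (anyNA(y))
    stop_srcdcm("srcdcm_numerical_error",
                "balloon model reached a nonphysical state")
  y
}

scan_indices <- function(n_scans, TR, dt, n_grid) {
  idx <- round((seq_len(n_scans) - 1L) * TR / dt) + 1L
  pmin(idx, n_grid)
}

#' Model-predicted BOLD at scan times
#'
#' Composition of \code{integrate_neural} and \code{hemodynamic_forward},
#' decimated to the scan grid (times 0, TR, 2 TR, ...).
#'
#' @inheritParams integrate_neural
#' @param hemo a \code{hemo_params}
#' @param TR repetition time in seconds
#' @param n_scans number of scans; defaults to covering the encoding
#' @return matrix (n_scans x n_nodes)
#' @export
predict_bold <- function(params, hemo = hemo_params(), enc, TR,
                         n_scans = NULL) {
  n_scans <- n_scans %||% (floor(enc$total_duration / TR) + 1L)
  idx <- scan_indices(n_scans, TR, enc$dt, nrow(enc$u))
  y <- cpp_dcm_forward(params$A, b_cube(params, ncol(enc$u)),
                       pad_C(params, ncol(enc$u)), enc$u, enc$dt,
                       hemo$kappa, hemo$gamma, hemo$tau, hemo$alpha,
                       hemo$E0, hemo$V0, idx)
  if (anyNA(y))
    stop_srcdcm("srcdcm_instability_error",
                "forward model diverged; check stability of A")
  colnames(y) <- params$node_labels
  y
}

#' Fraction of data variance explained by a model prediction
#'
#' 1 - var(y - y_hat) / var(y), computed per node and averaged, clipped
#' below at zero.  Subjects below 0.10 are flagged for exclusion by the
#' inversion wrapper.
#'
#' @param y observed matrix (T x n)
#' @param y_hat predicted matrix (T x n)
#' @return scalar in [0, 1]
#' @export
explained_variance <- function(y, y_hat) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  assert_that(all(dim(y) == dim(y_hat)), "srcdcm_shape_error",
              "y and y_hat must have identical shapes")
  v <- apply(y, 2, var)
  assert_that(all(v > 0), "srcdcm_degenerate_data_error",
              "zero-variance node series")
  ev <- 1 - apply(y - y_hat, 2, var) / v
  max(0, mean(ev))
}
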