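#' DCM parameter containers and vectorization
#'
#' Connectivity matrices follow the state equation
#' dz/dt = (A + sum_k B_k u_k(t)) z + C u(t): rows index the target node
#' and columns the source node, so A[i, j] is the influence of node j on
#' node i.  Text export transposes to the documented row = "From",
#' column = "To" layout (see \code{\link{write_connectivity_tsv}}).
#'
#' Self-connections are parameterized on a log scale, A_ii = -0.5 exp(a_i),
#' which keeps the baseline dynamics stable for any real a_i.
#'
#' @name dcm-model
NULL

#' Default node labels of the 9-node SRC network
#' @export
src_nodes <- function() {
  c("AMCC", "IPS_L", "IPS_R", "PMC_L", "PMC_R",
    "DLPFC_L", "DLPFC_R", "AI_L", "AI_R")
}

#' Construct DCM parameters
#'
#' @param A n x n intrinsic coupling matrix (Hz), row = target
#' @param B n x n modulatory matrix (Hz) or list of such, one per input
#'   beyond the first (the driving input carries no modulation)
#' @param C n x m driving-gain matrix (m = number of inputs)
#' @param node_labels character vector of node names
#' @return object of class \code{dcm_params}
#' @export
dcm_params <- function(A, B, C, node_labels = NULL) {
  n <- nrow(A)
  assert_that(ncol(A) == n, "srcdcm_shape_error", "A must be square")
  if (is.matrix(B)) B <- list(B)
  for (Bk in B)
    assert_that(all(dim(Bk) == c(n, n)), "srcdcm_shape_error",
                "B must be n x n")
  assert_that(nrow(C) == n, "srcdcm_shape_error", "C must have n rows")
  labels <- node_labels %||% paste0("node", seq_len(n))
  structure(list(A = A, B = B, C = C, n_nodes = n,
                 node_labels = labels,
                 input_labels = paste0("u", seq_len(ncol(C)))),
            class = "dcm_params")
}

#' Hemodynamic (balloon model) constants
#'
#' Canonical values shared across nodes: signal decay kappa (1/s),
#' autoregulatory feedback gamma (1/s), mean transit time tau (s), vessel
#' stiffness alpha, resting oxygen extraction E0, resting venous volume
#' fraction V0.
#'
#' @param kappa,gamma,tau,alpha,E0,V0 scalars, see description
#' @return object of class \code{hemo_params}
#' @export
hemo_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                        alpha = 0.32, E0 = 0.4, V0 = 0.04) {
  assert_that(all(c(kappa, gamma, tau, V0) > 0) && alpha > 0 &&
                alpha < 1 && E0 > 0 && E0 < 1, "srcdcm_config_error",
              "hemodynamic constants out of range")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0), class = "hemo_params")
}

#' Free-parameter layout of the full-connection model
#'
#' Enumerates the free parameters of a full-connection bilinear DCM:
#' all A off-diagonals, all self-connection log-scalings, all entries of
#' the modulatory B matrix, and the driving-input gains C restricted to
#' the driving nodes (bilateral IPS by default).
#'
#' @param n_nodes number of network nodes
#' @param node_labels node names (length n_nodes)
#' @param driving_nodes indices (or names) of nodes receiving the driving
#'   input
#' @return object of class \code{dcm_param_spec}: a data.frame-backed
#'   layout with fields \code{table} (kind, row, col, name), \code{n_free},
#'   and prior mean/variance vectors.
#' @export
make_param_spec <- function(n_nodes = 9L, node_labels = src_nodes(),
                            driving_nodes = c("IPS_L", "IPS_R")) {
  assert_that(length(node_labels) == n_nodes, "srcdcm_shape_error",
              "need %d node labels", n_nodes)
  if (is.character(driving_nodes))
    driving_nodes <- match(driving_nodes, node_labels)
  assert_that(!anyNA(driving_nodes), "srcdcm_config_error",
              "driving node not found among labels")
  n <- n_nodes
  rows <- list()
  for (j in seq_len(n)) for (i in seq_len(n)) if (i != j)
    rows[[length(rows) + 1L]] <- data.frame(kind = "A", row = i, col = j)
  for (i in seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(kind = "Aself", row = i, col = i)
  for (j in seq_len(n)) for (i in seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(kind = "B", row = i, col = j)
  for (i in driving_nodes)
    rows[[length(rows) + 1L]] <- data.frame(kind = "C", row = i, col = 1L)
  tab <- do.call(rbind, rows)
  lab <- function(i) node_labels[i]
  tab$name <- ifelse(tab$kind == "C",
                     sprintf("C:driving->%s", lab(tab$row)),
                     sprintf("%s:%s->%s", sub("self", "", tab$kind),
                             lab(tab$col), lab(tab$row)))
  tab$name[tab$kind == "Aself"] <- sprintf("Aself:%s",
                                           lab(tab$row[tab$kind == "Aself"]))
  # cached linear-index maps for fast theta <-> matrix conversion
  lin <- tab$row + (tab$col - 1L) * n
  idx <- list(A_pos = which(tab$kind == "A"),
              Aself_pos = which(tab$kind == "Aself"),
              B_pos = which(tab$kind == "B"),
              C_pos = which(tab$kind == "C"))
  idx$A_lin <- lin[idx$A_pos]
  idx$Aself_lin <- lin[idx$Aself_pos]
  idx$B_lin <- lin[idx$B_pos]
  idx$C_row <- tab$row[idx$C_pos]
  structure(list(table = tab, n_free = nrow(tab), n_nodes = n,
                 node_labels = node_labels, driving_nodes = driving_nodes,
                 idx = idx),
            class = "dcm_param_spec")
}

#' Shrinkage priors over the free parameters
#'
#' A off-diagonal ~ N(0, 1/64); self log-scaling a ~ N(0, 1/256) with
#' A_ii = -0.5 exp(a); B ~ N(0, 1/16); C ~ N(0, 1).  A variance of zero
#' switches the parameter off (used by Bayesian model reduction).  The
#' modulatory prior is deliberately tighter than the conventional unit
#' variance: in an event-related design the 0.2-s modulation windows
#' leave most B directions barely identified, and a unit-variance prior
#' lets them absorb observation noise (posterior spread far exceeding any
#' plausible modulation) instead of shrinking them to zero.
#'
#' @param spec a \code{dcm_param_spec}
#' @param var_A,var_Aself,var_B,var_C per-class prior variances
#' @return object of class \code{dcm_priors}: \code{$mean}, \code{$var}
#'   vectors over the free parameters plus the spec.
#' @export
dcm_priors <- function(spec, var_A = 1 / 64, var_Aself = 1 / 256,
                       var_B = 1 / 16, var_C = 1) {
  v <- c(A = var_A, Aself = var_Aself, B = var_B, C = var_C)
  assert_that(all(v >= 0), "srcdcm_config_error",
              "prior variances must be >= 0")
  structure(list(mean = rep(0, spec$n_free),
                 var = unname(v[spec$table$kind]),
                 spec = spec), class = "dcm_priors")
}

#' Map a free-parameter vector to connectivity matrices (and back)
#'
#' @param theta numeric vector of length \code{spec$n_free}
#' @param spec a \code{dcm_param_spec}
#' @return \code{theta_to_params}: a \code{dcm_params};
#'   \code{params_to_theta}: a named numeric vector.
#' @export
theta_to_params <- function(theta, spec) {
  n <- spec$n_nodes
  ix <- spec$idx
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  C <- matrix(0, n, 2L)
  A[ix$A_lin] <- theta[ix$A_pos]
  A[ix$Aself_lin] <- -0.5 * exp(theta[ix$Aself_pos])
  B[ix$B_lin] <- theta[ix$B_pos]
  C[cbind(ix$C_row, 1L)] <- theta[ix$C_pos]
  dcm_params(A, B, C, spec$node_labels)
}

#' @rdname theta_to_params
#' @param params a \code{dcm_params} whose layout matches \code{spec}
#' @export
params_to_theta <- function(params, spec) {
  ix <- spec$idx
  B1 <- if (is.matrix(params$B)) params$B else params$B[[1]]
  theta <- numeric(spec$n_free)
  theta[ix$A_pos] <- params$A[ix$A_lin]
  aii <- params$A[ix$Aself_lin]
  assert_that(all(aii < 0), "srcdcm_config_error",
              "self-connections must be < 0")
  theta[ix$Aself_pos] <- log(-aii / 0.5)
  theta[ix$B_pos] <- B1[ix$B_lin]
  theta[ix$C_pos] <- params$C[cbind(ix$C_row, 1L)]
  names(theta) <- spec$table$name
  theta
}

#' Indices of a parameter class within the free-parameter vector
#' @param spec a \code{dcm_param_spec}
#' @param which one of "A" (off-diagonals + self), "B", "AB", "C"
#' @return integer vector of indices
#' @export
param_indices <- function(spec, which = c("AB", "A", "B", "C")) {
  which <- match.arg(which)
  kinds <- switch(which, A = c("A", "Aself"), B = "B",
                  AB = c("A", "Aself", "B"), C = "C")
  which(spec$table$kind %in% kinds)
}

#' Export a connectivity matrix as tab-delimited text
#'
#' Written with row = "From" (source) and column = "To" (target); since
#' matrices are stored row = target internally, the export transposes.
#'
#' @param mat n x n matrix, row = target (internal convention)
#' @param path output file
#' @param node_labels node names
#' @export
write_connectivity_tsv <- function(mat, path, node_labels = src_nodes()) {
  out <- t(mat)
  dimnames(out) <- list(From = node_labels, To = node_labels)
  df <- data.frame(From = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stability of the baseline dynamics
#'
#' @param A square intrinsic coupling matrix
#' @return list with \code{$stable} (all eigenvalue real parts < 0) and
#'   \code{$leading} (largest real part)
#' @export
stability_check <- function(A) {
  assert_that(is.matrix(A) && nrow(A) == ncol(A), "srcdcm_shape_error",
              "A must be a square matrix")
  re <- Re(eigen(A, only.values = TRUE)$values)
  list(stable = all(re < 0), leading = max(re))
}
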