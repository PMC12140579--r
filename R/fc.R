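#' Functional connectivity comparison arm
#'
#' Full task-evoked FC is the pairwise Pearson correlation of the ROI
#' time series; task-residual FC correlates the residuals after
#' regressing out the task timing (by default the model inputs convolved
#' with a canonical double-gamma HRF and decimated to scan resolution,
#' plus an intercept).  CPM-style selection keeps the top-10% most
#' positively and most negatively target-correlated edges in the
#' training set; masked edges feed the same regression/CV machinery as
#' the EC features (edges are used individually, not summed).
#'
#' @name fc
NULL

#' Pearson-correlation FC matrix
#'
#' @param ts a \code{roi_timeseries} (or plain T x n matrix)
#' @return object of class \code{fc_matrix}: \code{$mat} (n x n,
#'   symmetric, unit diagonal), \code{$edges} (upper-triangle vector),
#'   \code{$edge_names}, \code{$kind}
#' @export
compute_fc <- function(ts) {
  M <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  assert_that(nrow(M) >= 3L, "srcdcm_config_error", "need T >= 3")
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    lbl <- colnames(M) %||% as.character(seq_len(ncol(M)))
    stop_srcdcm("srcdcm_degenerate_node_error",
                "constant series at node %s", lbl[which(sds == 0)[1]])
  }
  C <- cor(M)
  fc_from_matrix(C, kind = "full",
                 subject_id = if (inherits(ts, "roi_timeseries"))
                   ts$subject_id else NA_character_)
}

fc_from_matrix <- function(C, kind, subject_id = NA_character_) {
  n <- nrow(C)
  ut <- upper.tri(C)
  lbl <- colnames(C) %||% paste0("node", seq_len(n))
  pairs <- which(ut, arr.ind = TRUE)
  structure(list(mat = C, edges = C[ut],
                 edge_names = sprintf("%s--%s", lbl[pairs[, 1]],
                                      lbl[pairs[, 2]]),
                 kind = kind, subject_id = subject_id),
            class = "fc_matrix")
}

#' Canonical double-gamma hemodynamic response function
#' @param t time points (s)
#' @return HRF values (peak ~5 s, undershoot ~15 s, unit peak-area scale)
#' @export
canonical_hrf <- function(t) {
  dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
}

task_regressors <- function(enc, TR, n_scans, raw_boxcar = FALSE) {
  u <- enc$u
  if (!raw_boxcar) {
    hl <- canonical_hrf(seq(0, 32, by = enc$dt))
    u <- apply(u, 2, function(col)
      convolve(col, rev(hl), type = "open")[seq_len(nrow(u))] * enc$dt)
  }
  idx <- scan_indices(n_scans, TR, enc$dt, nrow(u))
  R <- u[idx, , drop = FALSE]
  R[, apply(R, 2, sd) > 0, drop = FALSE]
}

#' Task-residual FC
#'
#' @param ts a \code{roi_timeseries}
#' @param enc the stimulus encoding of the session
#' @param raw_boxcar regress raw input boxcars instead of HRF-convolved
#'   regressors
#' @return an \code{fc_matrix} of kind "residual"
#' @export
task_residual_fc <- function(ts, enc, raw_boxcar = FALSE) {
  M <- ts$data
  R <- task_regressors(enc, ts$TR, nrow(M), raw_boxcar)
  X <- cbind(1, R)
  assert_that(qr(X)$rank == ncol(X), "srcdcm_design_error",
              "rank-deficient task regressor matrix")
  resid <- M - X %*% qr.solve(X, M)
  C <- cor(resid)
  dimnames(C) <- list(ts$node_labels, ts$node_labels)
  fc_from_matrix(C, kind = "residual", ts$subject_id)
}

#' CPM-style edge selection
#'
#' Ranks edges by their training-set correlation with the target and
#' keeps the top ceiling(top_frac * E) most positive plus the top
#' ceiling(top_frac * E) most negative (by signed value), merged into one
#' mask.  Ties break deterministically by edge index.
#'
#' @param edge_x matrix (training subjects x edges)
#' @param train_y training targets
#' @param top_frac fraction per tail (default 0.10)
#' @param edge_names optional edge labels
#' @return an \code{edge_mask} over the edge vector
#' @export
cpm_select <- function(edge_x, train_y, top_frac = 0.10,
                       edge_names = NULL) {
  E <- ncol(edge_x)
  assert_that(E >= 1L, "srcdcm_config_error", "no edges to select from")
  k <- ceiling(top_frac * E)
  r <- suppressWarnings(apply(edge_x, 2, function(e)
    if (sd(e) == 0) 0 else cor(e, train_y)))
  ord_pos <- order(-r, seq_len(E))
  ord_neg <- order(r, seq_len(E))
  sel <- union(ord_pos[seq_len(k)], ord_neg[seq_len(k)])
  mask <- rep(FALSE, E)
  mask[sel] <- TRUE
  structure(list(mask = mask, param_idx = seq_len(E),
                 names = edge_names %||% paste0("edge", seq_len(E)),
                 matrix_kind = "FC", design_column = "covariate",
                 provenance = list(method = "CPM", top_frac = top_frac)),
            class = "edge_mask")
}

#' FC-based prediction through the shared CV machinery
#'
#' @param ts_list list of \code{roi_timeseries}, one per subject
#' @param targets numeric vector aligned with subjects
#' @param config a \code{prediction_config} with an FC feature source
#' @param enc stimulus encoding (needed for \code{"FC-residual"})
#' @param top_frac CPM tail fraction
#' @return a \code{prediction_result}
#' @export
run_fc_prediction <- function(ts_list, targets, config, enc = NULL,
                              top_frac = 0.10) {
  kind <- switch(config$feature_source,
                 "FC-full" = "full", "FC-residual" = "residual",
                 stop_srcdcm("srcdcm_config_error",
                             "feature_source must be FC-full/FC-residual"))
  fcs <- lapply(ts_list, function(ts) {
    if (kind == "full") compute_fc(ts) else task_residual_fc(ts, enc)
  })
  edge_x <- t(vapply(fcs, `[[`, numeric(length(fcs[[1]]$edges)), "edges"))
  colnames(edge_x) <- fcs[[1]]$edge_names
  selector <- function(train_idx, tr_y)
    list(mask = cpm_select(edge_x[train_idx, , drop = FALSE], tr_y,
                           top_frac, fcs[[1]]$edge_names),
         fallback = FALSE)
  extractor <- function(mask)
    edge_x[, mask$mask, drop = FALSE]
  run_prediction(NULL, targets, config, feature_selector = selector,
                 feature_extractor = extractor)
}

#' Export an FC matrix as tab-delimited text
#' @param fc an \code{fc_matrix}
#' @param path output file
#' @export
write_fc_tsv <- function(fc, path) {
  df <- data.frame(node = rownames(fc$mat) %||%
                     paste0("node", seq_len(nrow(fc$mat))), fc$mat,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
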