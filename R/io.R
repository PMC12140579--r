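#' Tab-delimited ROI time-series files
#'
#' T rows x n columns with a header of node labels; numerics are written
#' with 12 significant digits so round-trips are stable in tests.
#'
#' @param ts a \code{roi_timeseries}
#' @param path output file
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(signif(ts$data, 12))
  names(df) <- ts$node_labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param TR repetition time in seconds (from the cohort sidecar)
#' @param subject_id subject label
#' @return a \code{roi_timeseries}
#' @export
read_timeseries <- function(path, TR, subject_id = basename(path)) {
  df <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(df)
  assert_that(is.numeric(mat) && !anyNA(mat), "srcdcm_format_error",
              "non-numeric or missing entries in %s", path)
  structure(list(data = mat, TR = TR, node_labels = colnames(mat),
                 subject_id = subject_id), class = "roi_timeseries")
}

default_config <- function() {
  list(seed = 1L,
       design_kind = "event",
       paradigm = list(n_blocks = 24L, trials_min = 13L, trials_max = 16L,
                       iti_min = 2, iti_max = 4.5, rest_min = 15,
                       rest_max = 19),
       TR = 2.03,
       cohort = list(n_subjects = 60L, target_snr = 3),
       dcm = list(max_iter = 128L, tol = 1e-4),
       peb = list(pp_threshold = 0.95, which = "B"),
       predict = list(cv_scheme = "kfold", k = 5L, n_repetitions = 100L,
                      n_permutations = 500L, regressor = "lasso",
                      feature_source = "M-EC", pp_threshold = 0.95,
                      use_bmr = FALSE, target = "rt_like"),
       paths = list(out_dir = "."),
       log_level = "info")
}

validate_keys <- function(x, template, path = "") {
  for (k in names(x)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(template))
      stop_srcdcm("srcdcm_config_error", "unknown config key: %s", full)
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(x[[k]]))
      validate_keys(x[[k]], template[[k]], full)
  }
  invisible(TRUE)
}

#' Load and validate a JSON run configuration
#'
#' Unknown keys are rejected by name; missing keys are filled with the
#' documented defaults (5-fold CV, 100 repetitions, 500 permutations,
#' PP threshold 0.95, TR = 2.03 s, the full 24-block paradigm).
#'
#' @param path JSON file
#' @return validated config list of class \code{srcdcm_config}
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), "srcdcm_config_error",
              "config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tmpl <- default_config()
  validate_keys(raw, tmpl)
  cfg <- modifyList(tmpl, raw)
  assert_that(cfg$design_kind %in% c("event", "block"),
              "srcdcm_config_error", "design_kind must be event or block")
  structure(cfg, class = c("srcdcm_config", "list"))
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", substream_seed(0L, as.character(s)))
}

#' Write a machine-readable run manifest
#'
#' Records the config hash, seed, package version, per-stage timings,
#' warnings, and every subject excluded by the < 10% explained-variance
#' rule with its reason.
#'
#' @param path output JSON path
#' @param cfg the run config
#' @param timings named list of stage timings (seconds)
#' @param exclusions data.frame(subject_id, reason) or NULL
#' @param warnings character vector
#' @export
write_manifest <- function(path, cfg, timings = list(),
                           exclusions = NULL, warnings = character()) {
  jsonlite::write_json(
    list(config_hash = config_hash(cfg), seed = cfg$seed,
         package_version =
           as.character(utils::packageVersion("srcdcm")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         timings = timings,
         exclusions = exclusions %||%
           data.frame(subject_id = character(), reason = character()),
         warnings = warnings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
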