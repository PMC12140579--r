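#' SRC task paradigm generation and encoding
#'
#' The spatial stimulus-response-compatibility (SRC) task alternates blocks
#' of spatially compatible ("Pro") and incompatible ("Anti") two-choice
#' reaction trials.  The default protocol: 24 blocks (12 per condition,
#' pseudorandom order), 13-16 trials per block, 0.2-s lateralized stimuli
#' with left/right sides equiprobable, inter-trial onset intervals uniform
#' on [2, 4.5] s, inter-block rests uniform on [15, 19] s, and a 2-s
#' instruction preceding each block.
#'
#' @name paradigm
NULL

default_protocol <- function() {
  list(n_blocks = 24L, trials_min = 13L, trials_max = 16L,
       trial_duration = 0.2, iti_min = 2, iti_max = 4.5,
       rest_min = 15, rest_max = 19, instruction_duration = 2,
       trailing_gap = 2)
}

#' Generate an SRC task paradigm
#'
#' @param seed integer seed; the paradigm is deterministic given the seed.
#' @param overrides named list overriding protocol parameters
#'   (\code{n_blocks}, \code{trials_min}, \code{trials_max}, \code{iti_min},
#'   \code{iti_max}, \code{rest_min}, \code{rest_max}).  \code{n_blocks}
#'   must stay even so conditions balance.
#' @return an object of class \code{src_paradigm} with \code{$blocks}
#'   (condition, instruction_onset, block_onset, block_duration),
#'   \code{$trials} (onset, duration, side, condition, block) and
#'   \code{$total_duration} in seconds.
#' @export
generate_paradigm <- function(seed, overrides = list()) {
  proto <- modifyList(default_protocol(), overrides)
  assert_that(proto$n_blocks %% 2L == 0L && proto$n_blocks >= 2L,
              "srcdcm_config_error",
              "n_blocks must be even and >= 2, got %d", proto$n_blocks)
  assert_that(proto$trials_min <= proto$trials_max &&
                proto$trials_min >= 1L, "srcdcm_config_error",
              "empty trial count range [%d, %d]",
              proto$trials_min, proto$trials_max)
  set.seed(seed)
  nb <- proto$n_blocks
  conditions <- sample(rep(c("Pro", "Anti"), nb / 2L))

  blocks <- data.frame(condition = conditions, instruction_onset = NA_real_,
                       block_onset = NA_real_, block_duration = NA_real_,
                       stringsAsFactors = FALSE)
  trials <- vector("list", nb)
  t_cur <- 0
  for (b in seq_len(nb)) {
    blocks$instruction_onset[b] <- t_cur
    onset0 <- t_cur + proto$instruction_duration
    n_tr <- sample(seq(proto$trials_min, proto$trials_max), 1L)
    itis <- runif(n_tr - 1L, proto$iti_min, proto$iti_max)
    onsets <- onset0 + c(0, cumsum(itis))
    sides <- sample(c("left", "right"), n_tr, replace = TRUE)
    trials[[b]] <- data.frame(onset = onsets,
                              duration = proto$trial_duration,
                              side = sides, condition = conditions[b],
                              block = b, stringsAsFactors = FALSE)
    blocks$block_onset[b] <- onset0
    blocks$block_duration[b] <- (onsets[n_tr] - onset0) + proto$trailing_gap
    t_cur <- onset0 + blocks$block_duration[b] +
      runif(1L, proto$rest_min, proto$rest_max)
  }
  structure(list(blocks = blocks,
                 trials = do.call(rbind, trials),
                 total_duration = t_cur,
                 protocol = proto, seed = seed),
            class = "src_paradigm")
}

#' @export
print.src_paradigm <- function(x, ...) {
  cat(sprintf("SRC paradigm: %d blocks (%d Anti / %d Pro), %d trials, %.1f s\n",
              nrow(x$blocks), sum(x$blocks$condition == "Anti"),
              sum(x$blocks$condition == "Pro"), nrow(x$trials),
              x$total_duration))
  invisible(x)
}

#' Encode a paradigm as DCM model inputs
#'
#' Builds the binary (non-mean-centered) input matrix u on a microtime
#' grid: column 1 is the driving input (all events), column 2 the
#' modulatory input (Anti condition only).  In the event dialect each
#' trial contributes a 0.2-s boxcar over [onset, onset + duration); in the
#' block dialect each block contributes a boxcar over its full duration.
#'
#' @param p an \code{src_paradigm}
#' @param design_kind \code{"event"} or \code{"block"}
#' @param dt microtime step in seconds; must be positive and at most the
#'   trial duration (0.2 s) so event boxcars are resolved.
#' @return an object of class \code{stim_encoding} with \code{$u}
#'   (n_timepoints x 2 binary matrix), \code{$dt}, \code{$design_kind},
#'   \code{$input_labels} and \code{$total_duration}.
#' @export
encode_inputs <- function(p, design_kind = c("event", "block"), dt) {
  design_kind <- match.arg(design_kind)
  assert_that(dt > 0 && dt <= p$protocol$trial_duration + 1e-12,
              "srcdcm_resolution_error",
              "dt = %g s cannot resolve %g-s events", dt,
              p$protocol$trial_duration)
  nt <- ceiling(p$total_duration / dt) + 1L
  tg <- (seq_len(nt) - 1L) * dt
  u <- matrix(0, nt, 2L, dimnames = list(NULL, c("driving", "anti")))
  mark <- function(col, onset, duration) {
    on <- tg >= onset - 1e-12 & tg < onset + duration - 1e-12
    u[on, col] <<- 1
  }
  if (design_kind == "event") {
    for (i in seq_len(nrow(p$trials)))
      mark(1L, p$trials$onset[i], p$trials$duration[i])
    anti <- p$trials[p$trials$condition == "Anti", , drop = FALSE]
    for (i in seq_len(nrow(anti)))
      mark(2L, anti$onset[i], anti$duration[i])
  } else {
    for (b in seq_len(nrow(p$blocks)))
      mark(1L, p$blocks$block_onset[b], p$blocks$block_duration[b])
    ab <- p$blocks[p$blocks$condition == "Anti", , drop = FALSE]
    for (b in seq_len(nrow(ab)))
      mark(2L, ab$block_onset[b], ab$block_duration[b])
  }
  structure(list(u = u, dt = dt, design_kind = design_kind,
                 input_labels = c("driving", "anti"),
                 total_duration = p$total_duration),
            class = "stim_encoding")
}

#' Behavioral prediction target: mean Anti-condition reaction time
#'
#' Trials with RT < 150 ms or RT > 1500 ms are excluded (strict
#' inequalities: boundary values are retained); the target is the mean RT
#' over the remaining Anti-condition trials.
#'
#' @param rt numeric vector of reaction times (s), aligned with
#'   \code{p$trials}
#' @param p the paradigm the responses belong to
#' @return list with \code{$target} (mean Anti RT, s) and \code{$valid}
#'   (logical mask over all trials)
#' @export
behavioral_target <- function(rt, p) {
  assert_that(length(rt) == nrow(p$trials), "srcdcm_alignment_error",
              "rt has %d entries but paradigm has %d trials",
              length(rt), nrow(p$trials))
  valid <- !(rt < 0.150 | rt > 1.500)
  keep <- valid & p$trials$condition == "Anti"
  assert_that(any(keep), "srcdcm_degenerate_subject_error",
              "no valid Anti-condition trials")
  list(target = mean(rt[keep]), valid = valid)
}

#' Read/write FSL 3-column EV timing files
#'
#' One row per event: onset, duration, amplitude, whitespace-delimited.
#'
#' @param events data.frame with columns onset, duration, amplitude
#' @param path file path
#' @return \code{read_ev3} returns the events data.frame.
#' @export
write_ev3 <- function(events, path) {
  assert_that(all(c("onset", "duration", "amplitude") %in% names(events)),
              "srcdcm_format_error", "events need onset/duration/amplitude")
  lines <- sprintf("%.12g\t%.12g\t%.12g", events$onset, events$duration,
                   events$amplitude)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ev3
#' @export
read_ev3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- matrix(NA_real_, length(lines), 3L)
  for (i in seq_along(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
    if (length(f) != 3L || anyNA(f))
      stop_srcdcm("srcdcm_format_error", "line %d: expected 3 numbers", i)
    if (f[2] < 0)
      stop_srcdcm("srcdcm_format_error", "line %d: negative duration", i)
    out[i, ] <- f
  }
  if (is.unsorted(out[, 1]))
    stop_srcdcm("srcdcm_format_error", "onsets are not monotone")
  data.frame(onset = out[, 1], duration = out[, 2], amplitude = out[, 3])
}

#' Export paradigm inputs as FSL 3-column EV files
#'
#' Writes one EV file per model input column: all events (driving) and the
#' Anti-condition events (modulatory), in the chosen dialect.
#'
#' @inheritParams encode_inputs
#' @param dir output directory
#' @return character vector of the files written
#' @export
write_paradigm_ev3 <- function(p, dir, design_kind = c("event", "block")) {
  design_kind <- match.arg(design_kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (design_kind == "event") {
    all_ev <- data.frame(onset = p$trials$onset,
                         duration = p$trials$duration, amplitude = 1)
    anti <- p$trials$condition == "Anti"
    anti_ev <- all_ev[anti, , drop = FALSE]
  } else {
    all_ev <- data.frame(onset = p$blocks$block_onset,
                         duration = p$blocks$block_duration, amplitude = 1)
    anti_ev <- all_ev[p$blocks$condition == "Anti", , drop = FALSE]
  }
  paths <- file.path(dir, c("ev_driving.txt", "ev_anti.txt"))
  write_ev3(all_ev[order(all_ev$onset), ], paths[1])
  write_ev3(anti_ev[order(anti_ev$onset), ], paths[2])
  paths
}

#' Serialize a paradigm to/from JSON
#' @param p an \code{src_paradigm}
#' @param path file path
#' @return \code{read_paradigm_json} returns the \code{src_paradigm}.
#' @export
write_paradigm_json <- function(p, path) {
  jsonlite::write_json(list(blocks = p$blocks, trials = p$trials,
                            total_duration = p$total_duration,
                            protocol = p$protocol, seed = p$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_paradigm_json
#' @export
read_paradigm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(blocks = as.data.frame(x$blocks),
                 trials = as.data.frame(x$trials),
                 total_duration = x$total_duration,
                 protocol = x$protocol, seed = x$seed),
            class = "src_paradigm")
}
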