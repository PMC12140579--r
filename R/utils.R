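#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one run seed; components derive
#' their own seeds through this hash so that, e.g., repetition 3 of a CV run
#' is reproducible independently of repetition 2.
#'
#' @param seed integer master seed
#' @param ... further integers or strings tagging the sub-stream
#' @return an integer in [0, 2^31 - 1]
#' @export
substream_seed <- function(seed, ...) {
  tags <- c(as.character(seed), vapply(list(...), as.character, ""))
  h <- 2166136261
  for (s in tags) {
    for (b in utf8ToInt(s)) {
      h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
      # FNV-1a multiply, kept in double to avoid integer overflow
      h <- (h * 16777619) %% 2^31
    }
  }
  as.integer(h %% .Machine$integer.max)
}

stop_srcdcm <- function(class, msg, ...) {
  stop(structure(class = c(class, "srcdcm_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) stop_srcdcm(class, msg, ...)
  invisible(TRUE)
}
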