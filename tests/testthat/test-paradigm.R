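test_that("default paradigm matches the SRC protocol", {
  p <- generate_paradigm(1)
  expect_equal(nrow(p$blocks), 24L)
  expect_equal(sum(p$blocks$condition == "Anti"), 12L)
  expect_equal(sum(p$blocks$condition == "Pro"), 12L)
  expect_gte(nrow(p$trials), 312L)  # 24 x 13
  expect_lte(nrow(p$trials), 384L)  # 24 x 16
  expect_identical(generate_paradigm(1), p)  # deterministic
})

test_that("paradigm invariants hold across seeds", {
  for (seed in 1:5) {
    p <- generate_paradigm(seed, list(n_blocks = 8L))
    expect_equal(sum(p$blocks$condition == "Anti"), 4L)
    counts <- table(p$trials$block)
    expect_true(all(counts >= 13 & counts <= 16))
    expect_true(all(p$trials$duration == 0.2))
    for (b in unique(p$trials$block)) {
      on <- p$trials$onset[p$trials$block == b]
      if (length(on) > 1) {
        d <- diff(on)
        expect_true(all(d >= 2 & d <= 4.5))
        expect_true(all(d > 0.2))  # trial windows never overlap
      }
    }
    # instruction precedes block onset by 2 s; rests within [15, 19]
    expect_equal(p$blocks$block_onset - p$blocks$instruction_onset,
                 rep(2, 8))
    ends <- p$blocks$block_onset + p$blocks$block_duration
    rests <- c(p$blocks$instruction_onset[-1], p$total_duration) - ends
    expect_true(all(rests >= 15 & rests <= 19))
    expect_setequal(unique(p$trials$side), c("left", "right"))
  }
})

test_that("invalid overrides are rejected", {
  expect_error(generate_paradigm(1, list(n_blocks = 7L)),
               class = "srcdcm_config_error")
  expect_error(generate_paradigm(1, list(trials_min = 5L, trials_max = 4L)),
               class = "srcdcm_config_error")
})

test_that("event encoding marks 0.2-s trial boxcars", {
  # single trial at onset 10.0 s
  p <- structure(list(
    blocks = data.frame(condition = "Pro", instruction_onset = 8,
                        block_onset = 10, block_duration = 2.2),
    trials = data.frame(onset = 10.0, duration = 0.2, side = "left",
                        condition = "Pro", block = 1L),
    total_duration = 20, protocol = list(trial_duration = 0.2)),
    class = "src_paradigm")
  enc <- encode_inputs(p, "event", dt = 0.1)
  tg <- (seq_len(nrow(enc$u)) - 1) * 0.1
  expect_equal(enc$u[, 1], as.numeric(tg >= 10 - 1e-9 & tg < 10.2 - 1e-9))
  expect_true(all(enc$u %in% c(0, 1)))
  expect_equal(enc$u[, 2], rep(0, nrow(enc$u)))  # Pro only
})

test_that("encoding dialects satisfy their invariants", {
  p <- generate_paradigm(4, list(n_blocks = 4L))
  ev <- encode_inputs(p, "event", dt = 0.05)
  # modulatory support is a subset of driving support
  expect_true(all(ev$u[ev$u[, 2] == 1, 1] == 1))
  # block dialect: integral of driving boxcars = total block duration
  bl <- encode_inputs(p, "block", dt = 0.05)
  expect_lt(abs(sum(bl$u[, 1]) * 0.05 - sum(p$blocks$block_duration)),
            2 * 0.05 * nrow(p$blocks))  # grid quantization bound
  # round-trip: event boxcar onsets recover trial onsets within dt
  d <- diff(c(0, ev$u[, 1]))
  onsets <- ((which(d == 1)) - 1) * 0.05
  expect_equal(length(onsets), nrow(p$trials))
  expect_true(all(abs(sort(onsets) - sort(p$trials$onset)) <= 0.05))
  expect_error(encode_inputs(p, "event", dt = 0.3),
               class = "srcdcm_resolution_error")
})

test_that("behavioral target filters reaction times strictly", {
  p <- generate_paradigm(2, list(n_blocks = 2L))
  rt <- rep(0.5, nrow(p$trials))
  expect_equal(behavioral_target(rt, p)$target, 0.5)
  # the four-trial filter example: {0.10, 0.40, 0.60, 1.60} -> 0.50
  anti <- which(p$trials$condition == "Anti")[1:4]
  rt2 <- rep(0.3, nrow(p$trials))
  rt2[anti] <- c(0.10, 0.40, 0.60, 1.60)
  rt2[setdiff(which(p$trials$condition == "Anti"), anti)] <- NA
  keepable <- !is.na(rt2)
  p2 <- p
  p2$trials <- p$trials[keepable, ]
  out <- behavioral_target(rt2[keepable], p2)
  expect_equal(out$target, 0.50)
  expect_false(out$valid[which(p2$trials$condition == "Anti")[1]])
  # boundary values retained (strict inequalities)
  rt3 <- rep(0.150, nrow(p$trials))
  rt3[p$trials$condition == "Anti"] <- c(0.150, 1.500,
                                         rep(0.5, sum(p$trials$condition ==
                                                        "Anti") - 2))
  bt <- behavioral_target(rt3, p)
  expect_true(all(bt$valid))
  # no valid Anti trials -> degenerate subject
  rt4 <- rep(0.5, nrow(p$trials))
  rt4[p$trials$condition == "Anti"] <- 2.0
  expect_error(behavioral_target(rt4, p),
               class = "srcdcm_degenerate_subject_error")
})

test_that("EV3 and paradigm JSON round-trip", {
  p <- generate_paradigm(6, list(n_blocks = 4L))
  d <- withr::local_tempdir()
  paths <- write_paradigm_ev3(p, d, "event")
  ev <- read_ev3(paths[1])
  expect_equal(nrow(ev), nrow(p$trials))
  expect_equal(sort(ev$onset), sort(p$trials$onset), tolerance = 1e-10)
  expect_true(all(ev$duration == 0.2) && all(ev$amplitude == 1))
  # single-row dialect check
  f <- file.path(d, "one.txt")
  writeLines("10.0\t0.2\t1", f)
  one <- read_ev3(f)
  expect_equal(unlist(one), c(onset = 10, duration = 0.2, amplitude = 1))
  writeLines(c("1 0.2 1", "2 -1 1"), f)
  expect_error(read_ev3(f), class = "srcdcm_format_error")
  writeLines(c("5 0.2 1", "2 0.2 1"), f)
  expect_error(read_ev3(f), class = "srcdcm_format_error")

  jf <- file.path(d, "p.json")
  write_paradigm_json(p, jf)
  p2 <- read_paradigm_json(jf)
  expect_equal(p2$trials$onset, p$trials$onset)
  expect_equal(p2$total_duration, p$total_duration)
  expect_equal(p2$blocks$condition, p$blocks$condition)
})
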