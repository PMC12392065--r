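test_that("notch filter removes 50 Hz and bandpass preserves mid-band power", {
  fs <- 1926
  # steady-state attenuation: long sine, central half (edge transients of the
  # narrow notch decay with time constant 2Q/omega0 ~ 0.2 s)
  t <- seq_len(10 * fs) / fs
  mains <- sin(2 * pi * 50 * t)
  out <- emg_notch50(mains, fs)
  mid <- seq(round(2.5 * fs), round(7.5 * fs))
  expect_lt(emg_rms(out[mid]) / emg_rms(mains[mid]), 0.032)  # >= 30 dB down

  mid <- sin(2 * pi * 200 * t)
  bp <- emg_bandpass(mid, fs = fs)
  expect_equal(emg_rms(bp), emg_rms(mid), tolerance = 0.05)

  expect_identical(emg_bandpass(rep(0, 100), fs = fs), rep(0, 100))
  expect_error(emg_bandpass(mid, band = c(30, 1000), fs = fs), "Nyquist")
  expect_error(emg_notch50(mains, fs = 80), "Nyquist")
})

test_that("bandpass attenuates out-of-band components", {
  fs <- 1926
  t <- seq_len(2 * fs) / fs
  low <- sin(2 * pi * 5 * t)   # below the 30 Hz edge
  expect_lt(emg_rms(emg_bandpass(low, fs = fs)), 0.05 * emg_rms(low))
})

test_that("rms and peak-to-peak match closed forms", {
  expect_equal(emg_rms(rep(-3, 10)), 3)
  expect_equal(emg_peak_to_peak(rep(-3, 10)), 0)
  t <- seq(0, 1, length.out = 4001)[-1]
  s <- 2.5 * sin(2 * pi * 10 * t)
  expect_equal(emg_peak_to_peak(s), 5, tolerance = 1e-4)
  expect_equal(emg_rms(s), 2.5 / sqrt(2), tolerance = 1e-3)
  expect_equal(emg_rms(c(-1, 3)), sqrt(5))
  expect_equal(emg_peak_to_peak(c(-1, 3)), 4)
  expect_error(emg_rms(numeric(0)), "non-empty")
})

test_that("block baseline is the median of the last nine rest trials", {
  rest <- tibble::tibble(cue = "rest",
                         mep_thumb = seq(0.5, 1.4, by = 0.1),
                         mep_index = 1, mep_little = 2)
  bl <- block_baseline(rest)
  expect_equal(bl$mep$mep_thumb, 1.0)  # median of 0.6..1.4
  expect_equal(bl$mep$mep_little, 2)
  # first trial discarded: a huge first MEP cannot move the baseline
  rest$mep_thumb[1] <- 100
  expect_equal(block_baseline(rest)$mep$mep_thumb, 1.0)
  expect_error(block_baseline(rest[1:9, ]), "exactly 10")
  rest$mep_index <- 0
  expect_true(block_baseline(rest)$degenerate)
})

test_that("normalization divides by the baseline and rejects degenerate blocks", {
  rest <- tibble::tibble(cue = "rest", mep_thumb = 2, mep_index = 4,
                         mep_little = 1)[rep(1, 10), ]
  bl <- block_baseline(rest)
  tr <- tibble::tibble(cue = "thumb", mep_thumb = 3, mep_index = 4, mep_little = 0.5)
  out <- normalize_trials(tr, bl)
  expect_equal(out$mepn_thumb, 1.5)
  expect_equal(out$mepn_index, 1)
  expect_equal(out$mepn_little, 0.5)
  bad <- bl; bad$degenerate <- TRUE
  expect_error(normalize_trials(tr, bad), "degenerate")
})

test_that("normalization and ratios are invariant to rescaling raw amplitudes", {
  set.seed(41)
  sched <- schedule_session(4, n_blocks = 2)
  trials <- simulate_nf_stream(subject_params(), sched)
  scaled <- trials
  for (col in grep("^mep_", names(trials), value = TRUE)) {
    scaled[[col]] <- scaled[[col]] * 3.7
  }
  a <- add_trial_ratios(normalize_stream(trials))
  b <- add_trial_ratios(normalize_stream(scaled))
  expect_equal(b$mepn_thumb, a$mepn_thumb)
  expect_equal(b$mep_ratio, a$mep_ratio)
})

test_that("exclusion applies the 7 uV rule first, then the per-muscle SD rule", {
  # planted violations: one absolute, one 4-SD outlier; background variation
  # bounded well inside 2.5 SD so only the plants can fire
  trials <- flat_bg_trials(100, value = 2)
  trials$bg_right_index <- 2 + 0.3 * cos(seq_len(100))
  mu <- mean(trials$bg_right_index[-c(5, 50)])
  s <- sd(trials$bg_right_index[-c(5, 50)])
  trials$bg_right_index[5] <- 7.5          # rule 1
  trials$bg_right_index[50] <- mu + 4 * s  # rule 2 (well under 7)
  out <- exclude_trials(trials)
  expect_equal(which(out$exclude_reason == "abs_7uV"), 5L)
  expect_true(50L %in% which(out$exclude_reason == "sd_2.5"))
  # brute-force the SD rule on the rule-1 survivors
  kept <- trials$bg_right_index[-5]
  lim <- mean(kept) + 2.5 * sd(kept)
  expect_setequal(which(out$exclude_reason == "sd_2.5"),
                  setdiff(which(trials$bg_right_index > lim |
                                trials$bg_right_index < mean(kept) - 2.5 * sd(kept)), 5L))
})

test_that("identical bgEMG excludes nothing and exclusion is idempotent", {
  flat <- exclude_trials(flat_bg_trials(30, value = 2))
  expect_false(any(flat$excluded))
  set.seed(43)
  trials <- flat_bg_trials(80, value = 2)
  trials$bg_left_little <- abs(rnorm(80, 3, 1))
  trials$bg_left_little[10] <- 9
  once <- exclude_trials(trials)
  kept <- dplyr::filter(once, !.data$excluded)
  again <- exclude_trials(dplyr::select(kept, -"excluded", -"exclude_reason"))
  expect_false(any(again$exclude_reason == "abs_7uV", na.rm = TRUE))
})

test_that("target ratios follow their definitions and orderings", {
  expect_equal(mep_target_ratio(norm_trial("thumb", 1.5, 1.0, 0.8)), 1.5)
  expect_equal(mep_target_ratio(norm_trial("thumb", 1, 1, 1)), 1)
  expect_equal(mep_target_ratio(norm_trial("thumb", 0.5, 1.0, 1.0)), 0.5)
  expect_equal(mean_nontarget_ratio(norm_trial("thumb", 1.5, 1.0, 0.8)),
               1.5 / 0.9)
  expect_error(mep_target_ratio(norm_trial("rest", 1, 1, 1)), "cue")
  # max-based ratio never exceeds the mean-based one (max >= mean)
  set.seed(44)
  for (i in 1:200) {
    v <- runif(3, 0.05, 2)
    tr <- norm_trial(sample(fingers, 1), v[1], v[2], v[3])
    expect_lte(mep_target_ratio(tr), mean_nontarget_ratio(tr) + 1e-12)
  }
})

test_that("session summary averages kept imagery trials and errors when empty", {
  tr <- norm_trial("thumb", 1.5, 1.0, 0.8)
  tr$excluded <- FALSE; tr$exclude_reason <- NA_character_
  out <- session_summary(tr)
  expect_equal(out$mep_ratio, 1.5)
  expect_equal(out$n_kept, 1L)
  tr$excluded <- TRUE
  expect_error(session_summary(tr), "no imagery trials")
})

test_that("zero-noise pipeline recovers the generative gain ratio exactly", {
  set.seed(45)
  sub <- subject_params(mep_cv = 0, contamination_rate = 0,
                        facilitation_target = 1.5, suppression_nontarget = 0.8)
  trials <- simulate_nf_stream(sub, schedule_session("feedback_free"))
  trials <- add_trial_ratios(exclude_trials(normalize_stream(trials)))
  res <- session_summary(trials)
  expect_equal(res$mep_ratio, 1.5 / 0.8)
  expect_equal(res$mep_ratio_mean, 1.5 / 0.8)
  # post-training session gain propagates multiplicatively
  set.seed(46)
  sub2 <- subject_params(mep_cv = 0, contamination_rate = 0, session_gain = 1.2)
  post <- simulate_nf_stream(sub2, schedule_session("feedback_free"), session = "post")
  post <- add_trial_ratios(exclude_trials(normalize_stream(post)))
  expect_equal(session_summary(post)$mep_ratio,
               1.3 * 1.2 / 0.9)
})
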