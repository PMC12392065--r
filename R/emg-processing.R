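# Offline EMG processing: zero-phase filtering, rms / peak-to-peak
# quantification, block-baseline normalization, trial exclusion rules, and
# the MEP target-ratio statistics.

#' EMG window and filter specification
#'
#' Captures the offline EMG processing conventions: background EMG is taken
#' from 5–105 ms before the TMS pulse and the MEP from 15–60 ms after it;
#' both are bandpass filtered 30–800 Hz, and a 50 Hz notch is applied to the
#' background window only.
#'
#' @param fs Sampling rate, Hz. Must exceed twice the upper band edge.
#' @param band Bandpass edges, Hz.
#' @param bg_window Background-EMG window relative to the pulse, ms
#'   (negative = before the pulse).
#' @param mep_window MEP window relative to the pulse, ms.
#' @param notch_hz Mains notch frequency applied to background EMG, Hz.
#' @return An object of class `emg_window_spec`.
#' @export
emg_window_spec <- function(fs = 1926, band = c(30, 800),
                            bg_window = c(-105, -5), mep_window = c(15, 60),
                            notch_hz = 50) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2) abort("upper band edge must be below the Nyquist frequency")
  stopifnot(bg_window[1] < bg_window[2], mep_window[1] < mep_window[2])
  if (bg_window[2] > mep_window[1]) abort("bg and MEP windows must not overlap")
  structure(list(fs = fs, band = band, bg_window = bg_window,
                 mep_window = mep_window, notch_hz = notch_hz),
            class = "emg_window_spec")
}

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' ([signal::filtfilt()]), so the effective magnitude response is the square
#' of the single-pass response and the phase is zero.
#'
#' @param trace Numeric vector of EMG samples.
#' @param band Passband edges in Hz (default 30–800).
#' @param fs Sampling rate, Hz.
#' @return Filtered trace, same length.
#' @export
emg_bandpass <- function(trace, band = c(30, 800), fs = 1926) {
  if (any(band >= fs / 2)) abort("band edges must be below the Nyquist frequency")
  if (any(band <= 0) || band[1] >= band[2]) abort("`band` must be increasing and positive")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, trace))
}

#' Zero-phase 50 Hz notch filter
#'
#' Second-order IIR (biquad) notch at 50 Hz with quality factor `q`,
#' applied forward-backward. Attenuates a pure 50 Hz component by well over
#' 30 dB while leaving the rest of the band essentially untouched.
#'
#' @param trace Numeric vector of EMG samples.
#' @param fs Sampling rate, Hz.
#' @param freq Notch centre frequency, Hz.
#' @param q Quality factor (centre frequency / -3 dB bandwidth).
#' @return Filtered trace, same length.
#' @export
emg_notch50 <- function(trace, fs = 1926, freq = 50, q = 30) {
  if (freq >= fs / 2) abort("notch frequency must be below the Nyquist frequency")
  # RBJ audio-EQ biquad notch
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  as.numeric(signal::filtfilt(flt, trace))
}

#' Root mean square of a window
#' @param window Non-empty numeric vector.
#' @return `sqrt(mean(window^2))`.
#' @export
emg_rms <- function(window) {
  if (length(window) == 0) abort("`window` must be non-empty")
  sqrt(mean(window^2))
}

#' Peak-to-peak amplitude of a window
#' @param window Non-empty numeric vector.
#' @return `max(window) - min(window)`.
#' @export
emg_peak_to_peak <- function(window) {
  if (length(window) == 0) abort("`window` must be non-empty")
  max(window) - min(window)
}

#' Per-block rest baseline
#'
#' Computes the per-muscle normalization baseline of a neurofeedback block
#' from its 10 leading rest trials: the first rest trial is discarded (MEPs
#' on the first pulse are inflated by the novelty of the stimulation) and
#' the baseline is the median of the remaining nine, per muscle. The same
#' rule yields the background-EMG baseline.
#'
#' @param rest_trials Tibble of exactly 10 rest trials in delivery order,
#'   with the `mep_*` and `bg_*` columns of a trial table.
#' @return An object of class `block_baseline`: named lists `mep` and `bg`
#'   of per-muscle medians, and `degenerate` flagging non-positive medians.
#' @examples
#' trials <- tibble::tibble(cue = "rest", mep_thumb = 1:10 / 10,
#'   mep_index = 1, mep_little = 1)
#' block_baseline(trials)$mep$mep_thumb  # median of 0.2..1.0 = 0.6
#' @export
block_baseline <- function(rest_trials) {
  if (nrow(rest_trials) != 10) {
    abort("`rest_trials` must contain exactly 10 rest trials in order")
  }
  if (!all(rest_trials$cue == "rest")) abort("all baseline trials must be rest trials")
  kept <- rest_trials[-1, , drop = FALSE]
  med <- function(cols) lapply(kept[cols], median)
  mcols <- intersect(mep_cols(), names(kept))
  bcols <- intersect(bg_cols(), names(kept))
  mep <- med(mcols)
  bg <- if (length(bcols)) med(bcols) else list()
  degenerate <- any(unlist(mep) <= 0) || any(unlist(bg) <= 0)
  structure(list(mep = mep, bg = bg, degenerate = degenerate),
            class = "block_baseline")
}

#' Normalize trials to their block baseline
#'
#' Divides each trial's raw per-muscle MEP amplitude (and background-EMG
#' rms) by the block's rest-trial baseline, yielding the unitless normalized
#' values the feedback and all performance statistics are based on.
#' Degenerate baselines (a non-positive median) abort rather than propagate
#' infinities.
#'
#' @param trials Trial table with `mep_*` (and optionally `bg_*`) columns.
#' @param baseline A [block_baseline()].
#' @return `trials` with `mepn_*` (and `bgn_*`) columns appended.
#' @export
normalize_trials <- function(trials, baseline) {
  stopifnot(inherits(baseline, "block_baseline"))
  if (baseline$degenerate) {
    abort("degenerate baseline (non-positive median); block cannot be normalized")
  }
  for (col in names(baseline$mep)) {
    trials[[sub("^mep_", "mepn_", col)]] <- trials[[col]] / baseline$mep[[col]]
  }
  for (col in names(baseline$bg)) {
    trials[[sub("^bg_", "bgn_", col)]] <- trials[[col]] / baseline$bg[[col]]
  }
  trials
}

#' Normalize a multi-block trial stream
#'
#' Splits a trial table by block, derives each block's baseline from its
#' first 10 rest trials, and normalizes all trials in that block.
#'
#' @param trials Trial table with a `block` column; each block must start
#'   with its 10 rest trials.
#' @return The normalized trial table.
#' @export
normalize_stream <- function(trials) {
  trials |>
    dplyr::group_by(.data$block) |>
    dplyr::group_modify(function(df, key) {
      rest <- df[df$cue == "rest", , drop = FALSE][seq_len(10), , drop = FALSE]
      normalize_trials(df, block_baseline(rest))
    }) |>
    dplyr::ungroup()
}

#' Flag trials with contaminated background EMG
#'
#' Applies the two exclusion rules in their fixed order: (1) flag any trial
#' in which any muscle's background-EMG rms exceeds `abs_limit` (7 µV); then
#' (2) on the trials surviving rule 1, compute each muscle's mean and SD of
#' bgEMG rms and flag trials falling outside mean ± `sd_limit` SD (2.5) for
#' any muscle. The SD-rule population is the set of same-session trials that
#' survived rule 1, per muscle.
#'
#' @param trials Trial table with `bg_*` columns.
#' @param abs_limit Absolute bgEMG limit, µV.
#' @param sd_limit SD multiple for the second rule.
#' @return `trials` with logical `excluded` and character `exclude_reason`
#'   (`NA`, `"abs_7uV"` or `"sd_2.5"`) columns.
#' @export
exclude_trials <- function(trials, abs_limit = 7, sd_limit = 2.5) {
  cols <- intersect(bg_cols(), names(trials))
  if (length(cols) == 0) abort("no `bg_*` columns found")
  bg <- as.matrix(trials[cols])
  rule1 <- apply(bg > abs_limit, 1, any)
  keep <- !rule1
  rule2 <- rep(FALSE, nrow(trials))
  if (any(keep)) {
    mu <- colMeans(bg[keep, , drop = FALSE])
    sdev <- apply(bg[keep, , drop = FALSE], 2, sd)
    # SD = 0 (all identical) excludes nothing for that muscle
    lo <- mu - sd_limit * sdev
    hi <- mu + sd_limit * sdev
    out <- sweep(bg, 2, lo, "<") | sweep(bg, 2, hi, ">")
    out[, sdev == 0] <- FALSE
    rule2 <- keep & apply(out, 1, any)
  }
  trials$excluded <- rule1 | rule2
  trials$exclude_reason <- dplyr::case_when(rule1 ~ "abs_7uV",
                                            rule2 ~ "sd_2.5",
                                            TRUE ~ NA_character_)
  trials
}

# Pull the three normalized right-hand values (prefix "mepn_" or
# "bgn_right_") for one trial row as a named vector.
norm_triplet <- function(trial, prefix) {
  cols <- paste0(prefix, FINGERS)
  v <- unlist(trial[cols])
  names(v) <- FINGERS
  v
}

target_ratio_vec <- function(cue, values, type = c("max", "mean")) {
  type <- match.arg(type)
  nontarget <- values[setdiff(FINGERS, cue)]
  denom <- if (type == "max") max(nontarget) else mean(nontarget)
  if (denom <= 0) return(NA_real_)
  unname(values[[cue]] / denom)
}

#' MEP target ratio of a trial
#'
#' The per-trial motor-imagery performance statistic: the normalized MEP of
#' the cued target finger divided by the *higher* of the two nontarget
#' normalized MEPs. Values above 1 indicate finger-selective upregulation of
#' corticospinal excitability, 1 reflects no modulation, and values below 1
#' finger-selective downregulation.
#'
#' @param trial One-row tibble (or list) with `cue` and `mepn_*` columns.
#' @return The ratio (unitless); `NA` if the nontarget denominator is not
#'   positive (degenerate trial).
#' @examples
#' mep_target_ratio(tibble::tibble(cue = "thumb", mepn_thumb = 1.5,
#'   mepn_index = 1, mepn_little = 0.8))  # 1.5
#' @export
mep_target_ratio <- function(trial) {
  cue <- trial$cue
  assert_finger(cue, "cue")
  target_ratio_vec(cue, norm_triplet(trial, "mepn_"), "max")
}

#' Mean-nontarget MEP ratio of a trial
#'
#' Control variant of [mep_target_ratio()]: the target's normalized MEP
#' divided by the *average* of the two nontarget normalized MEPs. Because
#' the max of two values is at least their mean, this ratio is always at
#' least the max-based one, with equality when the nontargets are equal.
#'
#' @inheritParams mep_target_ratio
#' @return The ratio (unitless).
#' @export
mean_nontarget_ratio <- function(trial) {
  cue <- trial$cue
  assert_finger(cue, "cue")
  target_ratio_vec(cue, norm_triplet(trial, "mepn_"), "mean")
}

# Background-EMG analogue, on the right-hand normalized bgEMG.
bg_target_ratio <- function(trial, type = "max") {
  target_ratio_vec(trial$cue, norm_triplet(trial, "bgn_right_"), type)
}

#' Per-trial ratios for a trial table
#'
#' Vectorised convenience: appends `mep_ratio`, `mep_ratio_mean` and (when
#' normalized bgEMG columns are present) `bg_ratio` columns to every imagery
#' trial; rest trials get `NA`.
#'
#' @param trials Normalized trial table.
#' @return `trials` with ratio columns appended.
#' @export
add_trial_ratios <- function(trials) {
  has_bg <- all(paste0("bgn_right_", FINGERS) %in% names(trials))
  one <- function(i) {
    tr <- trials[i, ]
    if (!tr$cue %in% FINGERS) return(c(NA_real_, NA_real_, NA_real_))
    c(mep_target_ratio(tr), mean_nontarget_ratio(tr),
      if (has_bg) bg_target_ratio(tr) else NA_real_)
  }
  m <- vapply(seq_len(nrow(trials)), one, numeric(3))
  trials$mep_ratio <- m[1, ]
  trials$mep_ratio_mean <- m[2, ]
  if (has_bg) trials$bg_ratio <- m[3, ]
  trials
}

#' Session summary of motor-imagery performance
#'
#' Averages the per-trial MEP target ratio (and the bgEMG target ratio,
#' used downstream as a covariate for subtle muscle contractions) over the
#' non-excluded imagery trials of a session. The arithmetic mean is the
#' default; a geometric mean is available since ratios live on a log scale.
#'
#' @param trials Normalized trial table with exclusion flags (see
#'   [exclude_trials()]); ratio columns are added if missing.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return One-row tibble: `mep_ratio`, `mep_ratio_mean`, `bg_ratio`,
#'   `n_kept`, `n_excluded_abs`, `n_excluded_sd`.
#' @export
session_summary <- function(trials, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!"excluded" %in% names(trials)) trials <- exclude_trials(trials)
  if (!"mep_ratio" %in% names(trials)) trials <- add_trial_ratios(trials)
  imag <- dplyr::filter(trials, .data$cue %in% FINGERS, !.data$excluded)
  if (nrow(imag) == 0) abort("no imagery trials remain after exclusion")
  avg <- function(x) {
    x <- x[!is.na(x)]
    if (mean_type == "arithmetic") mean(x) else exp(mean(log(x)))
  }
  tibble::tibble(
    mep_ratio = avg(imag$mep_ratio),
    mep_ratio_mean = avg(imag$mep_ratio_mean),
    bg_ratio = if ("bg_ratio" %in% names(imag)) avg(imag$bg_ratio) else NA_real_,
    n_kept = nrow(imag),
    n_excluded_abs = sum(trials$exclude_reason == "abs_7uV", na.rm = TRUE),
    n_excluded_sd = sum(trials$exclude_reason == "sd_2.5", na.rm = TRUE)
  )
}
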