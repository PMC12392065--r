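# Neurofeedback task logic: the online background-EMG gate, trial success
# and star scoring, and the blocked-to-interleaved session schedules.

#' Online background-EMG gate configuration
#'
#' Parameters of the online gate that certifies muscle relaxation before and
#' during a trial: a 100 ms sliding rms window per muscle, a 10 µV ceiling,
#' a minimum of 1 s continuously below the ceiling before the trial
#' proceeds, and a 0.5 s freeze window before the pulse during which
#' excursions no longer restart the period. Imagery and preparation
#' durations are jittered uniformly over their intervals.
#'
#' @param rms_window_s Sliding rms window length, s.
#' @param threshold_uv Gate ceiling on every muscle's rms, µV.
#' @param required_clean_s Continuous clean time required to proceed, s.
#' @param freeze_before_pulse_s Window before the pulse in which the gate is
#'   frozen, s.
#' @param imagery_range_s Jitter interval for the imagery (or rest) period, s.
#' @param prep_range_s Jitter interval for the preparatory period, s.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(rms_window_s = 0.1, threshold_uv = 10,
                        required_clean_s = 1, freeze_before_pulse_s = 0.5,
                        imagery_range_s = c(4, 6), prep_range_s = c(1, 2)) {
  stopifnot(rms_window_s > 0, threshold_uv > 0, required_clean_s > 0,
            freeze_before_pulse_s > 0,
            length(imagery_range_s) == 2, all(imagery_range_s > 0),
            length(prep_range_s) == 2, all(prep_range_s > 0))
  if (freeze_before_pulse_s >= imagery_range_s[1]) {
    abort("freeze window must be shorter than the shortest imagery period")
  }
  structure(list(rms_window_s = rms_window_s, threshold_uv = threshold_uv,
                 required_clean_s = required_clean_s,
                 freeze_before_pulse_s = freeze_before_pulse_s,
                 imagery_range_s = imagery_range_s,
                 prep_range_s = prep_range_s),
            class = "gate_config")
}

#' Apply the background-EMG gate to an rms timeline
#'
#' Evaluates the online gate on a timeline of per-muscle sliding-window rms
#' values. In the preparatory phase the trial proceeds at the first moment
#' every muscle's rms has stayed below the threshold continuously for
#' `required_clean_s`. During the imagery (or rest) period any excursion of
#' any muscle above the threshold restarts the period — except within
#' `freeze_before_pulse_s` of the pulse, where the gate is frozen.
#'
#' @param timeline Tibble with a `time_s` column and one rms column per
#'   muscle (µV), sampled at 10 Hz or faster.
#' @param config A [gate_config()].
#' @param phase `"prep"` or `"imagery"`.
#' @param pulse_time_s Pulse time (s, on the timeline clock); required for
#'   the imagery phase.
#' @return For `phase = "prep"`: a list with `proceed_time_s` (`NA` if the
#'   gate never opened). For `phase = "imagery"`: a list with
#'   `restart_times_s`, the times of restart events (possibly empty).
#' @examples
#' tl <- tibble::tibble(time_s = seq(0, 2, by = 0.05), rms = 3)
#' nf_gate(tl, gate_config(), phase = "prep")$proceed_time_s  # 1
#' @export
nf_gate <- function(timeline, config = gate_config(),
                    phase = c("prep", "imagery"), pulse_time_s = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "gate_config"), "time_s" %in% names(timeline))
  t <- timeline$time_s
  if (length(t) > 1 && max(diff(t)) > 0.1 + 1e-9) {
    abort("timeline must be sampled at 10 Hz or faster")
  }
  rms <- as.matrix(timeline[setdiff(names(timeline), "time_s")])
  clean <- apply(rms < config$threshold_uv, 1, all)
  if (phase == "prep") {
    run_start <- t[1]
    for (i in seq_along(t)) {
      if (!clean[i]) {
        run_start <- if (i < length(t)) t[i + 1] else NA_real_
      } else if (!is.na(run_start) && t[i] - run_start >= config$required_clean_s) {
        return(list(proceed_time_s = t[i]))
      }
    }
    return(list(proceed_time_s = NA_real_))
  }
  if (is.null(pulse_time_s)) abort("`pulse_time_s` is required for the imagery phase")
  frozen <- t > pulse_time_s - config$freeze_before_pulse_s
  dirty <- which(!clean & !frozen)
  # consecutive dirty samples constitute a single excursion / restart event
  if (length(dirty) == 0) return(list(restart_times_s = numeric(0)))
  starts <- dirty[c(TRUE, diff(dirty) > 1)]
  list(restart_times_s = t[starts])
}

#' Score one neurofeedback trial
#'
#' Applies the success and star rules to a trial's three normalized MEPs. A
#' trial is successful iff the target finger's normalized MEP is strictly
#' above 1 *and* strictly above each nontarget's. Stars are only awarded on
#' success: the target finger earns its star when its normalized MEP exceeds
#' 1.5 times each nontarget's (`star_rule = "relative"`, the default) or
#' simply exceeds 1.5 (`star_rule = "absolute"`); each nontarget finger
#' earns its star when its own normalized MEP is below 1.
#'
#' @param mep_norm Named numeric vector of normalized MEPs for `thumb`,
#'   `index`, `little`.
#' @param target The cued finger.
#' @param star_rule `"relative"` or `"absolute"` target-star semantics.
#' @return A tibble row: `success`, `stars` (0–3), and per-finger
#'   `star_thumb`, `star_index`, `star_little`.
#' @examples
#' evaluate_trial(c(thumb = 1.6, index = 0.9, little = 0.8), "thumb")
#' @export
evaluate_trial <- function(mep_norm, target,
                           star_rule = c("relative", "absolute")) {
  star_rule <- match.arg(star_rule)
  assert_finger(target, "target")
  if (!all(FINGERS %in% names(mep_norm))) {
    abort("`mep_norm` must be named with all of thumb, index, little")
  }
  mep_norm <- mep_norm[FINGERS]
  nontarget <- setdiff(FINGERS, target)
  success <- mep_norm[[target]] > 1 && all(mep_norm[[target]] > mep_norm[nontarget])
  star <- stats::setNames(rep(FALSE, 3), FINGERS)
  if (success) {
    star[nontarget] <- mep_norm[nontarget] < 1
    star[target] <- if (star_rule == "relative") {
      all(mep_norm[[target]] > 1.5 * mep_norm[nontarget])
    } else {
      mep_norm[[target]] > 1.5
    }
  }
  tibble::tibble(success = success, stars = sum(star),
                 star_thumb = star[["thumb"]], star_index = star[["index"]],
                 star_little = star[["little"]])
}

# one block of cues for a given session design; 24 imagery trials
block_cues <- function(session_index, block, fingers_for_blocked) {
  if (identical(session_index, 1L)) {
    rep(fingers_for_blocked[ceiling(block / 2)], 24)
  } else if (identical(session_index, 2L)) {
    unlist(lapply(sample(FINGERS), rep, times = 8))
  } else if (identical(session_index, 3L)) {
    # six runs of four; each finger contributes two runs per block
    runs <- sample(rep(FINGERS, 2))
    unlist(lapply(runs, rep, times = 4))
  } else {
    sample(rep(FINGERS, 8))
  }
}

#' Build a session's cue schedule
#'
#' Generates the cue sequence of a training session (1–4) or a
#' feedback-free assessment. Every block starts with 10 rest cues followed
#' by 24 imagery cues. The imagery design shifts from blocked to
#' interleaved across training: session 1 cues a single finger for two
#' consecutive blocks; session 2 uses runs of eight repetitions per finger;
#' session 3 runs of four; session 4 and the feedback-free blocks are fully
#' interleaved with eight balanced repetitions of each finger per block.
#'
#' @param session `1:4` or `"feedback_free"`.
#' @param n_blocks Number of blocks (default 6 for training sessions, 2 for
#'   feedback-free).
#' @return A tibble with `block`, `trial` (within block) and `cue`.
#' @examples
#' set.seed(1)
#' sched <- schedule_session(4)
#' table(sched$cue[sched$block == 1])
#' @export
schedule_session <- function(session, n_blocks = NULL) {
  feedback_free <- identical(session, "feedback_free")
  if (!feedback_free) {
    if (!session %in% 1:4) abort("`session` must be 1, 2, 3, 4 or \"feedback_free\"")
    session <- as.integer(session)
  }
  n_blocks <- n_blocks %||% if (feedback_free) 2L else 6L
  fingers_for_blocked <- sample(FINGERS)
  purrr::map_dfr(seq_len(n_blocks), function(b) {
    imag <- if (feedback_free) sample(rep(FINGERS, 8))
            else block_cues(session, b, fingers_for_blocked)
    tibble::tibble(block = b, trial = seq_len(10 + 24),
                   cue = c(rep("rest", 10), imag))
  })
}
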