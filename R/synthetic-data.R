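# Synthetic-data generators: EMG traces, MEP trial streams, sigmoidal
# recruitment responders, and run-structured voxel-pattern datasets with
# known ground truth, so that every downstream stage can be validated
# without recorded data.

#' Generative parameters for a simulated participant
#'
#' Describes how a simulated participant's motor evoked potentials (MEPs)
#' respond to finger-selective motor imagery. MEP amplitudes are drawn from a
#' mean-preserving lognormal around `baseline_mep` times a cue- and
#' session-dependent multiplicative gain: imagery of a muscle's own finger
#' multiplies the mean by `facilitation_target` (and additionally by
#' `session_gain` after training), imagery of another finger multiplies it by
#' `suppression_nontarget`, and rest leaves it at baseline.
#'
#' @param baseline_mep Per-muscle mean MEP amplitude at rest, in mV. A single
#'   value is recycled across the three muscles.
#' @param mep_cv Coefficient of variation of the lognormal trial-to-trial
#'   MEP noise (unitless, > 0 unless exactly 0 for noiseless simulations).
#' @param facilitation_target Multiplicative gain on the target muscle's MEP
#'   during imagery of its finger.
#' @param suppression_nontarget Multiplicative gain on nontarget muscles
#'   during imagery of another finger.
#' @param session_gain Extra target-muscle gain applied in the post-training
#'   session, capturing the training effect.
#' @param emg_noise_sd Background EMG noise, µV (rms scale of clean trials).
#' @param contamination_rate Probability that a trial carries elevated
#'   background EMG (a contaminated trial), in \[0, 1\].
#' @return An object of class `subject_params`.
#' @examples
#' subject_params(facilitation_target = 1.5)
#' @export
subject_params <- function(baseline_mep = 0.5,
                           mep_cv = 0.3,
                           facilitation_target = 1.3,
                           suppression_nontarget = 0.9,
                           session_gain = 1.3,
                           emg_noise_sd = 2,
                           contamination_rate = 0.1) {
  baseline_mep <- rep_len(baseline_mep, length(FINGERS))
  stopifnot(all(baseline_mep > 0),
            mep_cv >= 0,
            facilitation_target > 0,
            suppression_nontarget > 0,
            session_gain > 0,
            emg_noise_sd > 0)
  if (contamination_rate < 0 || contamination_rate > 1) {
    abort("`contamination_rate` must lie in [0, 1]")
  }
  structure(
    list(baseline_mep = stats::setNames(baseline_mep, FINGERS),
         mep_cv = mep_cv,
         facilitation_target = facilitation_target,
         suppression_nontarget = suppression_nontarget,
         session_gain = session_gain,
         emg_noise_sd = emg_noise_sd,
         contamination_rate = contamination_rate),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>\n")
  cat("  baseline MEP (mV):", paste(signif(x$baseline_mep, 3), collapse = ", "), "\n")
  cat("  MEP CV:", x$mep_cv,
      " gains (target/nontarget/session):",
      x$facilitation_target, "/", x$suppression_nontarget, "/", x$session_gain, "\n")
  cat("  bgEMG noise (µV):", x$emg_noise_sd,
      " contamination rate:", x$contamination_rate, "\n")
  invisible(x)
}

# Cue- and session-dependent multiplicative MEP gain.
mep_gain <- function(subject, cue, muscle, session) {
  if (cue == "rest") return(1)
  if (cue == muscle) {
    g <- subject$facilitation_target
    if (session == "post") g <- g * subject$session_gain
    g
  } else {
    subject$suppression_nontarget
  }
}

# Mean-preserving lognormal multiplier: E[factor] = 1, CV = cv.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one MEP amplitude
#'
#' Draws a single motor evoked potential peak-to-peak amplitude for one
#' muscle under a given imagery cue, as
#' `baseline_mep * gain(cue, muscle, session) * lognormal(1, mep_cv)` where
#' the lognormal factor has mean exactly 1, so marginal means equal the
#' specified gains.
#'
#' @param subject A [subject_params()] object.
#' @param cue `"rest"` or one of `"thumb"`, `"index"`, `"little"`.
#' @param muscle Recorded muscle: `"thumb"`, `"index"` or `"little"`.
#' @param session `"pre"` or `"post"` (post applies `session_gain` to the
#'   target muscle).
#' @param n Number of draws.
#' @return Numeric vector of strictly positive amplitudes (mV).
#' @examples
#' set.seed(1)
#' simulate_mep(subject_params(mep_cv = 0), cue = "index", muscle = "index")
#' @export
simulate_mep <- function(subject, cue, muscle, session = c("pre", "post"), n = 1) {
  stopifnot(inherits(subject, "subject_params"))
  session <- match.arg(session)
  if (!identical(cue, "rest")) assert_finger(cue, "cue")
  assert_finger(muscle, "muscle")
  g <- mep_gain(subject, cue, muscle, session)
  subject$baseline_mep[[muscle]] * g * lognormal_factor(n, subject$mep_cv)
}

#' Simulate a raw EMG window
#'
#' Generates a sampled EMG trace as a sum of deterministic sinusoidal
#' components plus white Gaussian noise, used as a fixture for the filtering
#' stages. The default sampling rate matches typical surface-EMG hardware
#' (1926 Hz).
#'
#' @param duration_ms Window duration in milliseconds.
#' @param fs_hz Sampling rate in Hz; must exceed twice the highest sine
#'   frequency.
#' @param noise_sd Gaussian noise standard deviation, µV.
#' @param sine_components Data frame or tibble with columns `freq` (Hz),
#'   `amp` (µV) and optionally `phase` (radians); `NULL` for noise only.
#' @return A tibble with columns `time_s` and `emg` (µV).
#' @examples
#' w <- simulate_emg_window(100, sine_components = data.frame(freq = 50, amp = 10),
#'                          noise_sd = 0)
#' sqrt(mean(w$emg^2))  # ~ 10 / sqrt(2)
#' @export
simulate_emg_window <- function(duration_ms, fs_hz = 1926, noise_sd = 0,
                                sine_components = NULL) {
  if (duration_ms <= 0 || fs_hz <= 0) {
    abort("`duration_ms` and `fs_hz` must be positive")
  }
  if (!is.null(sine_components) && nrow(sine_components) > 0 &&
      fs_hz < 2 * max(sine_components$freq)) {
    abort("`fs_hz` must be at least twice the highest sine frequency")
  }
  n <- round(duration_ms * fs_hz / 1000)
  t <- seq_len(n) / fs_hz
  x <- rnorm(n, sd = noise_sd)
  if (!is.null(sine_components) && nrow(sine_components) > 0) {
    phase <- sine_components$phase %||% rep(0, nrow(sine_components))
    for (i in seq_len(nrow(sine_components))) {
      x <- x + sine_components$amp[i] *
        sin(2 * pi * sine_components$freq[i] * t + phase[i])
    }
  }
  tibble::tibble(time_s = t, emg = x)
}

# Background EMG rms for one trial and muscle: clean trials sit around 2 µV
# (lognormal, CV 0.25); contaminated trials are drawn uniformly in 8-15 µV so
# that both the 7 µV absolute rule and the ±2.5 SD rule are exercised.
draw_bg_rms <- function(n, noise_sd, contaminated) {
  clean <- noise_sd * lognormal_factor(n, 0.25)
  ifelse(contaminated, runif(n, 8, 15), clean)
}

#' Simulate a neurofeedback trial stream
#'
#' Generates the per-trial records of one or more neurofeedback blocks for a
#' simulated participant: each block contains 10 rest trials followed by 24
#' imagery trials (per the cue schedule), and each record carries the true
#' cue, raw per-muscle MEP amplitudes, and background-EMG rms values for all
#' six recorded muscles (both hands). A trial is contaminated — its bgEMG
#' drawn from the elevated 8–15 µV component — with probability
#' `contamination_rate`.
#'
#' @param subject A [subject_params()] object.
#' @param schedule Cue schedule tibble from [schedule_session()].
#' @param session `"pre"` or `"post"`.
#' @return A tibble with one row per trial: `block`, `trial`, `cue`,
#'   `mep_thumb`/`mep_index`/`mep_little` (mV), six `bg_<hand>_<finger>`
#'   columns (µV), and `contaminated`.
#' @examples
#' set.seed(1)
#' trials <- simulate_nf_stream(subject_params(),
#'                              schedule_session("feedback_free"))
#' dplyr::count(trials, cue)
#' @export
simulate_nf_stream <- function(subject, schedule, session = c("pre", "post")) {
  stopifnot(inherits(subject, "subject_params"))
  session <- match.arg(session)
  n <- nrow(schedule)
  contaminated <- runif(n) < subject$contamination_rate
  out <- schedule
  for (m in FINGERS) {
    g <- vapply(schedule$cue, function(cue) mep_gain(subject, cue, m, session),
                numeric(1), USE.NAMES = FALSE)
    out[[paste0("mep_", m)]] <-
      subject$baseline_mep[[m]] * g * lognormal_factor(n, subject$mep_cv)
  }
  for (col in bg_cols()) {
    out[[col]] <- draw_bg_rms(n, subject$emg_noise_sd, contaminated)
  }
  out$contaminated <- contaminated
  out
}

#' Sigmoidal recruitment model
#'
#' Logistic model of the probability that a TMS pulse at a given intensity
#' elicits a response at or above the amplitude criterion:
#' `P(response | intensity) = plogis((intensity - threshold) / slope)`.
#' Serves both as the generative model for simulated responders and as the
#' likelihood model for maximum-likelihood threshold hunting.
#'
#' @param threshold Stimulus intensity at which P(response) = 0.5, in %MSO
#'   (percent of maximum stimulator output); must lie in (0, 100].
#' @param slope Logistic scale parameter, %MSO; must be >= 0 (0 gives a
#'   deterministic step responder).
#' @param criterion Response amplitude criterion (µV for resting motor
#'   threshold, where 50 µV is conventional; a fraction of the maximum MEP
#'   for conditioned test-stimulus protocols). Informational: the binary
#'   outcome model already conditions on it.
#' @return An object of class `recruitment_model`.
#' @examples
#' m <- recruitment_model(threshold = 45, slope = 2)
#' response_prob(m, c(40, 45, 50))
#' @export
recruitment_model <- function(threshold, slope = 2, criterion = 50) {
  if (threshold <= 0 || threshold > 100) abort("`threshold` must lie in (0, 100]")
  if (slope < 0) abort("`slope` must be >= 0")
  structure(list(threshold = threshold, slope = slope, criterion = criterion),
            class = "recruitment_model")
}

#' @export
print.recruitment_model <- function(x, ...) {
  cat(sprintf("<recruitment_model> threshold %.1f %%MSO, slope %.2f %%MSO, criterion %s\n",
              x$threshold, x$slope, format(x$criterion)))
  invisible(x)
}

#' @rdname recruitment_model
#' @param model A `recruitment_model`.
#' @param intensity Stimulus intensity, %MSO (vectorised).
#' @export
response_prob <- function(model, intensity) {
  stopifnot(inherits(model, "recruitment_model"))
  if (model$slope == 0) as.numeric(intensity >= model$threshold)
  else plogis((intensity - model$threshold) / model$slope)
}

#' Simulate a binary recruitment outcome
#'
#' Draws Bernoulli response outcomes from a [recruitment_model()] at the
#' given intensity; the stochastic subject that adaptive threshold hunting
#' interrogates.
#'
#' @param model A [recruitment_model()].
#' @param intensity Stimulus intensity, %MSO (vectorised).
#' @return Integer vector of 0/1 outcomes.
#' @examples
#' set.seed(1)
#' mean(simulate_responder(recruitment_model(45, 2), rep(45, 1e4)))  # ~ 0.5
#' @export
simulate_responder <- function(model, intensity) {
  p <- response_prob(model, intensity)
  rbinom(length(p), 1L, p)
}

#' Specification for synthetic voxel-pattern datasets
#'
#' Describes the run/condition/trial/voxel structure and the generative
#' signal and noise of a synthetic pattern study: per-finger mean activity
#' patterns (distinctness controlled by `signal_scale_pre`/`_post`), an
#' execution task whose finger means share a fraction
#' `shared_exec_imagery` of the imagery means, and stationary Gaussian voxel
#' noise with exponentially decaying spatial correlation.
#'
#' @param n_voxels Number of voxels in the region of interest.
#' @param n_runs_imagery,n_runs_execution Runs per session for each task.
#' @param trials_per_finger_imagery,trials_per_finger_execution Trials per
#'   finger per session (split evenly over that task's runs).
#' @param signal_scale_pre,signal_scale_post Standard deviation of the
#'   finger-specific mean component in the pre/post session (arbitrary
#'   units; 0 gives a pure-null dataset).
#' @param shared_exec_imagery Fraction in \[0, 1\] of the execution finger
#'   means shared with imagery (1 = identical means, 0 = independent).
#' @param noise_sd Voxel noise standard deviation.
#' @param noise_corr_length Length scale (in voxel index units) of the
#'   exponential spatial correlation of the noise; 0 for independent voxels.
#' @param residual_mult Residual samples per run as a multiple of that run's
#'   trial count (residuals stabilise the noise-covariance estimate used for
#'   prewhitening).
#' @return An object of class `pattern_gen_spec`.
#' @export
pattern_gen_spec <- function(n_voxels = 50,
                             n_runs_imagery = 4,
                             n_runs_execution = 6,
                             trials_per_finger_imagery = 48,
                             trials_per_finger_execution = 30,
                             signal_scale_pre = 0.3,
                             signal_scale_post = 0.5,
                             shared_exec_imagery = 0.5,
                             noise_sd = 1,
                             noise_corr_length = 2,
                             residual_mult = 10) {
  stopifnot(n_voxels > 0, n_runs_imagery > 0, n_runs_execution > 0,
            trials_per_finger_imagery > 0, trials_per_finger_execution > 0,
            signal_scale_pre >= 0, signal_scale_post >= 0,
            noise_sd > 0, noise_corr_length >= 0, residual_mult >= 1)
  if (shared_exec_imagery < 0 || shared_exec_imagery > 1) {
    abort("`shared_exec_imagery` must lie in [0, 1]")
  }
  if (trials_per_finger_imagery %% n_runs_imagery != 0 ||
      trials_per_finger_execution %% n_runs_execution != 0) {
    abort("trials per finger must divide evenly across runs")
  }
  structure(as.list(environment()), class = "pattern_gen_spec")
}

# Exponential-decay spatial covariance over voxel indices; SPD by
# construction for any correlation length.
noise_covariance <- function(spec) {
  p <- spec$n_voxels
  if (spec$noise_corr_length == 0) {
    diag(spec$noise_sd^2, p)
  } else {
    d <- abs(outer(seq_len(p), seq_len(p), "-"))
    spec$noise_sd^2 * exp(-d / spec$noise_corr_length)
  }
}

# Draw n rows of correlated Gaussian noise with covariance given by its
# upper Cholesky factor.
corr_noise <- function(n, chol_sigma) {
  p <- ncol(chol_sigma)
  matrix(rnorm(n * p), n, p) %*% chol_sigma
}

new_pattern_dataset <- function(betas, residuals, task, session) {
  structure(list(betas = betas, residuals = residuals,
                 task = task, session = session),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf("<pattern_dataset> %s/%s: %d runs x %d conditions x %d trials x %d voxels\n",
              x$task, x$session, d[1], d[2], d[3], d[4]))
  cat(sprintf("  residuals: %d samples per run\n", dim(x$residuals)[2]))
  invisible(x)
}

# One task/session dataset given per-condition mean patterns (conditions x voxels).
generate_task_session <- function(means, n_runs, trials_per_run, spec, chol_sigma) {
  p <- spec$n_voxels
  k <- nrow(means)
  betas <- array(NA_real_,
                 dim = c(n_runs, k, trials_per_run, p),
                 dimnames = list(run = NULL, condition = rownames(means),
                                 trial = NULL, voxel = NULL))
  n_res <- spec$residual_mult * k * trials_per_run
  residuals <- array(NA_real_, dim = c(n_runs, n_res, p))
  for (r in seq_len(n_runs)) {
    for (c in seq_len(k)) {
      betas[r, c, , ] <- matrix(means[c, ], trials_per_run, p, byrow = TRUE) +
        corr_noise(trials_per_run, chol_sigma)
    }
    residuals[r, , ] <- corr_noise(n_res, chol_sigma)
  }
  list(betas = betas, residuals = residuals)
}

#' Simulate a run-structured voxel-pattern study
#'
#' Generates synthetic beta patterns and model-fit residuals for one
#' simulated participant: imagery and execution tasks, pre- and post-training
#' sessions. Finger-specific mean directions are drawn once per participant
#' and scaled by the session's signal scale; execution means mix a shared
#' component with an independent one according to `shared_exec_imagery`;
#' trial betas are the condition mean plus spatially correlated Gaussian
#' noise, and a residual array with the same noise covariance accompanies
#' each dataset for prewhitening.
#'
#' @param spec A [pattern_gen_spec()].
#' @return An object of class `pattern_study`: a list with elements
#'   `imagery_pre`, `imagery_post`, `execution_pre`, `execution_post` (each a
#'   `pattern_dataset` with `betas` `[run, condition, trial, voxel]` and
#'   `residuals` `[run, sample, voxel]`) and `truth` (the generating means
#'   per task/session and the noise covariance).
#' @examples
#' study <- simulate_pattern_study(pattern_gen_spec(n_voxels = 10,
#'   trials_per_finger_imagery = 4, trials_per_finger_execution = 6))
#' study$imagery_pre
#' @export
simulate_pattern_study <- function(spec = pattern_gen_spec()) {
  stopifnot(inherits(spec, "pattern_gen_spec"))
  p <- spec$n_voxels
  sigma <- noise_covariance(spec)
  ch <- chol(sigma)
  # unit-scale finger directions, shared across sessions; session scale applied below
  base_imag <- matrix(rnorm(3 * p), 3, p, dimnames = list(FINGERS, NULL))
  base_indep <- matrix(rnorm(3 * p), 3, p, dimnames = list(FINGERS, NULL))
  s <- spec$shared_exec_imagery
  base_exec <- s * base_imag + (1 - s) * base_indep
  truth <- list(noise_cov = sigma, means = list())
  out <- list()
  for (session in c("pre", "post")) {
    scale <- if (session == "pre") spec$signal_scale_pre else spec$signal_scale_post
    mi <- scale * base_imag
    me <- scale * base_exec
    truth$means[[paste0("imagery_", session)]] <- mi
    truth$means[[paste0("execution_", session)]] <- me
    gi <- generate_task_session(
      mi, spec$n_runs_imagery,
      spec$trials_per_finger_imagery / spec$n_runs_imagery, spec, ch)
    ge <- generate_task_session(
      me, spec$n_runs_execution,
      spec$trials_per_finger_execution / spec$n_runs_execution, spec, ch)
    out[[paste0("imagery_", session)]] <-
      new_pattern_dataset(gi$betas, gi$residuals, "imagery", session)
    out[[paste0("execution_", session)]] <-
      new_pattern_dataset(ge$betas, ge$residuals, "execution", session)
  }
  out$truth <- truth
  out$spec <- spec
  structure(out, class = "pattern_study")
}

#' Flatten a pattern dataset to a trial matrix
#'
#' Converts the `[run, condition, trial, voxel]` beta array of a
#' `pattern_dataset` into the single-trial feature matrix and label/run
#' vectors used by the decoding functions.
#'
#' @param dataset A `pattern_dataset` (or a list of them, whose runs are
#'   concatenated with distinct run labels).
#' @return A list with `x` (trials × voxels matrix), `y` (factor of
#'   condition labels) and `run` (integer run index).
#' @export
as_trial_matrix <- function(dataset) {
  if (inherits(dataset, "pattern_dataset")) dataset <- list(dataset)
  xs <- list(); ys <- list(); runs <- list(); run_offset <- 0L
  for (d in dataset) {
    stopifnot(inherits(d, "pattern_dataset"))
    dm <- dim(d$betas)
    conds <- dimnames(d$betas)$condition
    for (r in seq_len(dm[1])) {
      for (c in seq_len(dm[2])) {
        xs[[length(xs) + 1L]] <- matrix(d$betas[r, c, , ], dm[3], dm[4])
        ys[[length(ys) + 1L]] <- rep(conds[c], dm[3])
        runs[[length(runs) + 1L]] <- rep(run_offset + r, dm[3])
      }
    }
    run_offset <- run_offset + dm[1]
  }
  list(x = do.call(rbind, xs),
       y = factor(unlist(ys)),
       run = unlist(runs))
}
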