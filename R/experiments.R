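# Experiment drivers: seeded end-to-end simulation studies over the
# neurofeedback, threshold-hunting and pattern-analysis pipelines, plus
# configuration and trial-table input/output.

#' Read and write run configurations
#'
#' Run configurations are plain YAML: named parameter blocks for the
#' generators (`subject`, `patterns`, `hunt`), per-stage seeds, and driver
#' settings. `read_run_config()` round-trips losslessly with
#' `write_run_config()`.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list to serialise.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read and write trial tables
#'
#' Trial tables are plain comma-separated text with one row per trial:
#' `participant`, `group`, `session`, `block`, `trial`, `cue`, three
#' `mep_*` columns (mV), six `bg_<hand>_<finger>` columns (µV), and any
#' appended normalized/flag columns.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_trial_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_trial_table
#' @param trials Trial tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

# Derive independent, bounded sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}

#' Simulate and analyse a neurofeedback cohort
#'
#' End-to-end driver over the EMG and neurofeedback modules: simulates a
#' neurofeedback cohort (with training effects, via `session_gain`) and a
#' control cohort (without) in feedback-free pre- and post-training
#' assessments, runs normalization, exclusion and the target-ratio
#' summaries, and returns the long-format report table.
#'
#' @param n_per_group Participants per group.
#' @param subject Baseline [subject_params()]; the control cohort has
#'   `session_gain` reset to 1.
#' @param seed Master seed; every participant/session stream derives its
#'   own sub-seed from it.
#' @return A tibble: `participant`, `group`, `session`, `mep_ratio`,
#'   `mep_ratio_mean`, `bg_ratio`, `n_kept`, `n_excluded_abs`,
#'   `n_excluded_sd`.
#' @examples
#' run_nf_experiment(n_per_group = 2, seed = 1)
#' @export
run_nf_experiment <- function(n_per_group = 16, subject = subject_params(),
                              seed = 1) {
  control <- subject
  control$session_gain <- 1
  grid <- tidyr::expand_grid(group = c("nf", "control"),
                             participant = seq_len(n_per_group),
                             session = c("pre", "post"))
  seeds <- derive_seeds(seed, nrow(grid))
  purrr::pmap_dfr(c(grid, list(s = seeds)), function(group, participant, session, s) {
    set.seed(s)
    sub <- if (group == "nf") subject else control
    trials <- simulate_nf_stream(sub, schedule_session("feedback_free"), session)
    trials <- normalize_stream(trials)
    trials <- exclude_trials(trials)
    trials <- add_trial_ratios(trials)
    dplyr::bind_cols(tibble::tibble(participant = participant, group = group,
                                    session = session),
                     session_summary(trials))
  })
}

#' Simulation study of adaptive threshold hunting
#'
#' Runs many independent threshold-hunting tracks against a known logistic
#' responder and summarises estimator performance: bias, standard deviation
#' and the convergence-diagnostic rate.
#'
#' @param threshold,slope True responder parameters (%MSO).
#' @param n_reps Number of simulated tracks.
#' @param n_trials Counted trials per track.
#' @param seed Master seed.
#' @param ... Passed to [run_track()].
#' @return A list with `estimates` (tibble of per-track results) and
#'   `summary` (one-row tibble: `bias`, `sd`, `rmse`, `stable_rate`).
#' @export
run_hunt_experiment <- function(threshold = 45, slope = 2, n_reps = 500,
                                n_trials = 20, seed = 1, ...) {
  if (n_reps < 1) abort("`n_reps` must be at least 1")
  model <- recruitment_model(threshold, slope)
  seeds <- derive_seeds(seed, n_reps)
  estimates <- purrr::map_dfr(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    tr <- run_track(model, n_trials = n_trials, ...)
    tibble::tibble(rep = i, estimate = tr$estimate,
                   stable_tail = tr$stable_tail)
  })
  list(estimates = estimates,
       summary = tibble::tibble(
         threshold = threshold, slope = slope, n_reps = n_reps,
         bias = mean(estimates$estimate) - threshold,
         sd = sd(estimates$estimate),
         rmse = sqrt(mean((estimates$estimate - threshold)^2)),
         stable_rate = mean(estimates$stable_tail)))
}

#' Replicated pattern-analysis study
#'
#' Simulates many independent pattern studies and runs the representational
#' and decoding analyses on each: average inter-finger crossnobis distance
#' per task/session, leave-one-run-out execution decoding over the pooled
#' pre/post runs, and cross-task decoding per session.
#'
#' @param spec A [pattern_gen_spec()].
#' @param n_reps Number of replicate studies.
#' @param seed Master seed.
#' @param what Which analyses to run (any of `"rsa"`, `"loro"`,
#'   `"cross_task"`).
#' @return A long tibble: `rep`, `measure`, `task`, `session`, `value`.
#' @export
run_mvpa_experiment <- function(spec = pattern_gen_spec(), n_reps = 20,
                                seed = 1,
                                what = c("rsa", "loro", "cross_task")) {
  what <- match.arg(what, several.ok = TRUE)
  seeds <- derive_seeds(seed, n_reps)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    study <- simulate_pattern_study(spec)
    rows <- list()
    if ("rsa" %in% what) {
      for (session in c("pre", "post")) {
        d <- crossnobis(study[[paste0("imagery_", session)]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = i, measure = "avg_interfinger", task = "imagery",
          session = session, value = avg_interfinger(d))
      }
    }
    if ("loro" %in% what) {
      tm <- as_trial_matrix(list(study$execution_pre, study$execution_post))
      acc <- loro_cv(tm$x, tm$y, tm$run)$accuracy
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = i, measure = "loro_accuracy", task = "execution",
        session = "both", value = acc)
    }
    if ("cross_task" %in% what) {
      exec <- as_trial_matrix(list(study$execution_pre, study$execution_post))
      imag_all <- as_trial_matrix(list(study$imagery_pre, study$imagery_post))
      sc_imag <- fit_scaler(imag_all$x)
      for (session in c("pre", "post")) {
        im <- as_trial_matrix(study[[paste0("imagery_", session)]])
        acc <- cross_task(exec$x, exec$y, im$x, im$y,
                          scaler_test = sc_imag)$accuracy
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = i, measure = "cross_task_accuracy", task = "imagery",
          session = session, value = acc)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Summary plot of a neurofeedback cohort report
#'
#' Group-by-session distribution of the mean MEP target ratio from
#' [run_nf_experiment()], with the no-modulation reference line at 1.
#'
#' @param report Report tibble from [run_nf_experiment()].
#' @return A ggplot object.
#' @export
plot_nf_report <- function(report) {
  report$session <- factor(report$session, levels = c("pre", "post"))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$session, y = .data$mep_ratio,
                                       colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_boxplot(outlier.shape = NA, position = ggplot2::position_dodge(0.6),
                          width = 0.5) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(0.1, dodge.width = 0.6),
                        alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "mean MEP target ratio",
                  title = "Motor-imagery performance by group and session") +
    ggplot2::theme_minimal()
}
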