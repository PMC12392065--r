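# Adaptive maximum-likelihood threshold hunting (PEST) and the paired-pulse
# protocol arithmetic: resting motor threshold, conditioned test-stimulus
# thresholds, the maximum-MEP procedure, and the inhibition / facilitation
# percentages.

#' Maximum-likelihood threshold estimate from a stimulation history
#'
#' Given the sequence of (intensity, binary outcome) pairs collected so far,
#' returns the threshold that maximises the Bernoulli log-likelihood under a
#' logistic recruitment model with a fixed assumed slope, by exhaustive
#' search over a fine candidate grid (0.1 %MSO by default) across the
#' stimulator range. Ties are broken toward the lower intensity. Histories
#' containing only positive (or only negative) outcomes have their
#' likelihood maximised on the grid boundary and are flagged as
#' non-converged.
#'
#' @param history Tibble (or data frame) with columns `intensity` (%MSO)
#'   and `outcome` (0/1 or logical), in delivery order.
#' @param assumed_slope Fixed logistic slope, %MSO.
#' @param grid_range Searchable intensity range, %MSO.
#' @param grid_step Candidate grid resolution, %MSO.
#' @return A list: `estimate` (%MSO) and `converged` (`FALSE` when the
#'   history is one-sided).
#' @examples
#' ml_estimate(data.frame(intensity = c(40, 50), outcome = c(0, 1)))
#' @export
ml_estimate <- function(history, assumed_slope = 2,
                        grid_range = c(20, 90), grid_step = 0.1) {
  if (nrow(history) < 1) abort("`history` must contain at least one outcome")
  outcome <- as.numeric(history$outcome)
  stopifnot(all(outcome %in% c(0, 1)))
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  lp <- plogis(outer(history$intensity, grid, "-") / assumed_slope, log.p = TRUE)
  lq <- plogis(outer(history$intensity, grid, "-") / assumed_slope,
               lower.tail = FALSE, log.p = TRUE)
  ll <- colSums(outcome * lp + (1 - outcome) * lq)
  best <- which.max(ll)  # which.max takes the first maximum = lower intensity
  one_sided <- all(outcome == 1) || all(outcome == 0)
  list(estimate = grid[best], converged = !one_sided)
}

new_threshold_track <- function(assumed_slope, start_intensity, grid_range,
                                n_planned = 20L) {
  structure(
    list(history = tibble::tibble(intensity = numeric(0), outcome = integer(0)),
         assumed_slope = assumed_slope, start_intensity = start_intensity,
         grid_range = grid_range, n_planned = n_planned,
         estimate = NA_real_, converged = FALSE),
    class = "threshold_track")
}

#' @export
print.threshold_track <- function(x, ...) {
  cat(sprintf("<threshold_track> %d/%d trials, estimate %s %%MSO (%s)\n",
              nrow(x$history), x$n_planned,
              ifelse(is.na(x$estimate), "-", format(x$estimate)),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Recommended intensity for the next stimulus
#'
#' The adaptive rule: stimulate at the current maximum-likelihood threshold
#' estimate, rounded to the stimulator resolution (1 %MSO). An empty track
#' returns the configured start intensity.
#'
#' @param track A `threshold_track` (see [run_track()]).
#' @param resolution Stimulator intensity resolution, %MSO.
#' @return Intensity in %MSO.
#' @export
next_intensity <- function(track, resolution = 1) {
  stopifnot(inherits(track, "threshold_track"))
  if (nrow(track$history) == 0) return(track$start_intensity)
  est <- ml_estimate(track$history, track$assumed_slope, track$grid_range)$estimate
  round(est / resolution) * resolution
}

record_outcome <- function(track, intensity, outcome) {
  track$history <- dplyr::bind_rows(
    track$history, tibble::tibble(intensity = intensity,
                                  outcome = as.integer(outcome)))
  ml <- ml_estimate(track$history, track$assumed_slope, track$grid_range)
  track$estimate <- ml$estimate
  track$converged <- ml$converged
  track
}

#' Run one adaptive threshold-hunting track
#'
#' Simulates (or drives) a full PEST block against a responder: the first
#' stimulus is delivered twice and the first outcome discarded (first-pulse
#' MEPs are inflated by the novelty of the stimulation), then each
#' subsequent stimulus is placed at the current maximum-likelihood estimate
#' until `n_trials` counted outcomes are collected — 21 stimuli for the
#' default 20 counted trials. The returned track carries a convergence
#' diagnostic mirroring the experimenter's visual check: the fraction of
#' positive responses over the last five trials should lie in \[0.2, 0.8\].
#'
#' @param responder A [recruitment_model()], or a function
#'   `function(intensity)` returning a 0/1 outcome.
#' @param n_trials Counted trials (default 20).
#' @param assumed_slope Fixed slope used by the estimator, %MSO.
#' @param start_intensity First stimulus intensity, %MSO.
#' @param grid_range Searchable range, %MSO.
#' @param resolution Stimulator resolution, %MSO.
#' @return A `threshold_track` with fields `history` (the counted trials),
#'   `n_delivered` (counted + the discarded repeat), `estimate`,
#'   `converged`, and `stable_tail` (the last-five diagnostic).
#' @examples
#' set.seed(1)
#' run_track(recruitment_model(45, 2))$estimate
#' @export
run_track <- function(responder, n_trials = 20, assumed_slope = 2,
                      start_intensity = 40, grid_range = c(20, 90),
                      resolution = 1) {
  ask <- if (inherits(responder, "recruitment_model")) {
    function(intensity) simulate_responder(responder, intensity)
  } else {
    stopifnot(is.function(responder))
    responder
  }
  track <- new_threshold_track(assumed_slope, start_intensity, grid_range,
                               n_planned = as.integer(n_trials))
  # first stimulus delivered twice; the first outcome is discarded
  ask(start_intensity)
  n_delivered <- 1L
  for (i in seq_len(n_trials)) {
    intensity <- next_intensity(track, resolution)
    track <- record_outcome(track, intensity, ask(intensity))
    n_delivered <- n_delivered + 1L
  }
  tail5 <- utils::tail(track$history$outcome, 5)
  track$stable_tail <- mean(tail5) >= 0.2 && mean(tail5) <= 0.8
  track$n_delivered <- n_delivered
  track
}

#' @export
tidy.threshold_track <- function(x, ...) {
  dplyr::mutate(x$history, trial = dplyr::row_number(), .before = 1)
}

#' @export
glance.threshold_track <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, converged = x$converged,
                 stable_tail = x$stable_tail %||% NA,
                 n_trials = nrow(x$history),
                 n_delivered = x$n_delivered %||% NA_integer_)
}

#' Interleaved dual-track hunting block
#'
#' Runs two threshold-hunting tracks — one per motor-imagery condition
#' (target vs nontarget) — interleaved within one block, the cued condition
#' repeating in mini-runs of four trials. Each track receives exactly
#' `n_trials` counted trials and outcomes never cross tracks, so the two
#' estimates are independent given their responders.
#'
#' @param responder_target,responder_nontarget Responders for the two
#'   imagery conditions (see [run_track()]).
#' @param n_trials Counted trials per track.
#' @param run_length Trials per mini-run before the cue switches.
#' @param ... Passed on to the per-track machinery
#'   (`assumed_slope`, `start_intensity`, `grid_range`, `resolution`).
#' @return A list with `target` and `nontarget` `threshold_track`s and
#'   `cue_order`, the realised per-trial condition sequence.
#' @export
interleaved_block <- function(responder_target, responder_nontarget,
                              n_trials = 20, run_length = 4,
                              assumed_slope = 2, start_intensity = 40,
                              grid_range = c(20, 90), resolution = 1) {
  as_fun <- function(r) {
    if (inherits(r, "recruitment_model")) function(i) simulate_responder(r, i)
    else r
  }
  ask <- list(target = as_fun(responder_target),
              nontarget = as_fun(responder_nontarget))
  tracks <- list(
    target = new_threshold_track(assumed_slope, start_intensity, grid_range,
                                 as.integer(n_trials)),
    nontarget = new_threshold_track(assumed_slope, start_intensity, grid_range,
                                    as.integer(n_trials)))
  discarded <- c(target = FALSE, nontarget = FALSE)
  counted <- c(target = 0L, nontarget = 0L)
  cue_order <- character(0)
  cond <- "target"
  while (any(counted < n_trials)) {
    for (k in seq_len(run_length)) {
      if (counted[[cond]] >= n_trials) break
      if (!discarded[[cond]]) {
        ask[[cond]](start_intensity)  # repeated first stimulus, not counted
        discarded[[cond]] <- TRUE
      }
      intensity <- next_intensity(tracks[[cond]], resolution)
      tracks[[cond]] <- record_outcome(tracks[[cond]], intensity,
                                       ask[[cond]](intensity))
      counted[[cond]] <- counted[[cond]] + 1L
      cue_order <- c(cue_order, cond)
    }
    cond <- if (cond == "target") "nontarget" else "target"
  }
  list(target = tracks$target, nontarget = tracks$nontarget,
       cue_order = cue_order)
}

#' Maximum MEP from the 10-pulse procedure
#'
#' The maximum-MEP procedure delivers ten pulses (one at 50 %MSO, then three
#' each at 65, 80 and 95 %MSO). The first amplitude is discarded (novelty of
#' the stimulation), outliers more than `sd_limit` SD above the mean of the
#' remaining nine are removed, and the maximum of the survivors is returned.
#' Half of this value serves as the response criterion of the conditioned
#' test-stimulus protocols.
#'
#' @param amplitudes Exactly 10 MEP amplitudes (mV) in delivery order.
#' @param sd_limit Outlier cut, SD above the mean of the nine.
#' @return Maximum surviving amplitude, mV.
#' @examples
#' max_mep(c(9, rep(2, 8), 2.5))  # first discarded -> 2.5
#' @export
max_mep <- function(amplitudes, sd_limit = 2.5) {
  if (length(amplitudes) != 10) abort("`amplitudes` must contain exactly 10 MEPs")
  nine <- amplitudes[-1]
  keep <- nine <= mean(nine) + sd_limit * sd(nine)
  if (!any(keep)) abort("all amplitudes flagged as outliers")
  max(nine[keep])
}

#' Inhibition and facilitation percentages
#'
#' Expresses short-interval intracortical inhibition (SICI) and
#' intracortical facilitation (ICF) as the percentage change in the
#' conditioned test-stimulus threshold relative to the single-pulse
#' threshold:
#' `inhibition = (ts_sici - ts_single) / ts_single * 100` and
#' `facilitation = (ts_icf - ts_single) / ts_single * (-100)`.
#' With these signs, positive values mean more inhibition (a higher
#' intensity was needed under SICI) and more facilitation (a lower intensity
#' sufficed under ICF), respectively.
#'
#' @param ts_sici,ts_icf,ts_single Converged test-stimulus thresholds, %MSO.
#' @return Percentage (vectorised).
#' @examples
#' inhibition_percent(60, 50)    # 20
#' facilitation_percent(45, 50)  # 10
#' @export
inhibition_percent <- function(ts_sici, ts_single) {
  if (any(ts_single <= 0)) abort("`ts_single` must be positive")
  (ts_sici - ts_single) / ts_single * 100
}

#' @rdname inhibition_percent
#' @export
facilitation_percent <- function(ts_icf, ts_single) {
  if (any(ts_single <= 0)) abort("`ts_single` must be positive")
  (ts_icf - ts_single) / ts_single * (-100)
}

#' Pre-to-post training change
#'
#' Post-minus-pre difference of an inhibition (or facilitation) percentage
#' for one imagery condition: positive values indicate an increase in
#' inhibition (or facilitation) after training, negative values a release.
#'
#' @param pre,post Percentages from the pre- and post-training sessions.
#' @return `post - pre` (vectorised).
#' @examples
#' pre_post_delta(20, 10)  # -10: release of inhibition
#' @export
pre_post_delta <- function(pre, post) {
  post - pre
}

#' @export
autoplot.threshold_track <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$intensity)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$outcome,
                                                    levels = c(0, 1),
                                                    labels = c("negative", "positive"))),
                        size = 2) +
    ggplot2::geom_hline(yintercept = object$estimate, linetype = "dashed") +
    ggplot2::labs(x = "counted trial", y = "intensity (%MSO)", shape = "response",
                  title = sprintf("Threshold hunting: estimate %.1f %%MSO",
                                  object$estimate)) +
    ggplot2::theme_minimal()
}
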