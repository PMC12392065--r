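# Shared fixtures: all synthetic, built in code at test time.

fingers <- c("thumb", "index", "little")

# One normalized imagery trial row with the right-hand columns the ratio
# statistics read.
norm_trial <- function(cue, thumb, index, little,
                       bg = c(thumb = 1, index = 1, little = 1)) {
  tibble::tibble(cue = cue,
                 mepn_thumb = thumb, mepn_index = index, mepn_little = little,
                 bgn_right_thumb = bg[["thumb"]],
                 bgn_right_index = bg[["index"]],
                 bgn_right_little = bg[["little"]])
}

# Minimal raw trial table: n trials with constant bgEMG except where
# overridden; used by the exclusion-rule tests.
flat_bg_trials <- function(n, value = 2) {
  out <- tibble::tibble(trial = seq_len(n), cue = "thumb")
  for (col in c(outer(c("left", "right"), fingers,
                      function(h, f) paste("bg", h, f, sep = "_")))) {
    out[[col]] <- value
  }
  out
}

# Pure-null pattern generator spec at the study's structure, desk scale.
null_pattern_spec <- function(...) {
  pattern_gen_spec(signal_scale_pre = 0, signal_scale_post = 0, ...)
}

# Small but structured spec for fast non-null pattern tests.
small_pattern_spec <- function(...) {
  pattern_gen_spec(n_voxels = 12, trials_per_finger_imagery = 8,
                   trials_per_finger_execution = 12, ...)
}

# Hand-rolled pattern_dataset from an explicit run x condition x voxel array
# of condition patterns (one trial per condition) plus residuals.
dataset_from_patterns <- function(patterns, residuals,
                                  task = "imagery", session = "pre") {
  d <- dim(patterns)  # run x cond x voxel
  betas <- array(patterns, dim = c(d[1], d[2], 1, d[3]),
                 dimnames = list(run = NULL,
                                 condition = dimnames(patterns)[[2]],
                                 trial = NULL, voxel = NULL))
  structure(list(betas = betas, residuals = residuals,
                 task = task, session = session),
            class = "pattern_dataset")
}

# Independent brute-force crossnobis: literal double loop over ordered fold
# pairs of whitened pattern differences, never calling the package path.
crossnobis_bruteforce <- function(patterns, sigma, i, j) {
  m <- dim(patterns)[1]
  p <- dim(patterns)[3]
  e <- eigen(sigma, symmetric = TRUE)
  w_half <- e$vectors %*% diag(1 / sqrt(e$values), p) %*% t(e$vectors)
  acc <- 0
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      da <- drop(patterns[a, i, ] - patterns[a, j, ]) %*% w_half
      db <- drop(patterns[b, i, ] - patterns[b, j, ]) %*% w_half
      acc <- acc + sum(da * db)
    }
  }
  acc / (m * (m - 1) * p)
}

# Independent grid-search likelihood oracle for the threshold estimator.
ml_oracle <- function(history, slope = 2, range = c(20, 90), step = 0.1) {
  grid <- seq(range[1], range[2], by = step)
  best <- -Inf; arg <- NA_real_
  for (th in grid) {
    ll <- 0
    for (k in seq_len(nrow(history))) {
      p <- 1 / (1 + exp(-(history$intensity[k] - th) / slope))
      ll <- ll + if (history$outcome[k] == 1) log(p) else log(1 - p)
    }
    if (ll > best) { best <- ll; arg <- th }
  }
  arg
}

# Brute-force Benjamini-Hochberg step-up.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
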