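# Multivariate pattern analysis: shrinkage estimation of the voxel noise
# covariance, prewhitened cross-validated Mahalanobis (crossnobis)
# distances, linear decoding with leave-one-run-out and cross-task schemes,
# and permutation inference with Fisher combination and FDR control.

#' Shrinkage estimate of the voxel noise covariance
#'
#' Estimates the voxel-by-voxel noise covariance from model-fit residuals by
#' analytic shrinkage of the sample covariance toward its diagonal
#' (Ledoit–Wolf-type): `S* = (1 - w) S + w diag(S)`, with the shrinkage
#' weight `w` chosen to minimise the expected squared error of the
#' off-diagonal entries. The result is symmetric positive definite whenever
#' the diagonal is positive, even with fewer samples than voxels.
#'
#' @param residuals Sample × voxel matrix, or the `[run, sample, voxel]`
#'   residual array of a `pattern_dataset` (runs are pooled).
#' @return The covariance matrix, with the chosen weight in
#'   `attr(, "shrinkage")`.
#' @export
shrink_covariance <- function(residuals) {
  if (length(dim(residuals)) == 3) {
    d <- dim(residuals)
    residuals <- matrix(aperm(residuals, c(2, 1, 3)), d[1] * d[2], d[3])
  }
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  if (n < 2) abort("at least 2 residual samples are required")
  x <- scale(residuals, center = TRUE, scale = FALSE)
  s <- crossprod(x) / n
  # Schafer-Strimmer analytic weight for off-diagonal shrinkage toward zero:
  # w = sum Var(s_ij) / sum s_ij^2 over i != j, clipped to [0, 1]
  xs2 <- crossprod(x^2) / n
  var_s <- (xs2 - s^2) / n
  off <- !diag(TRUE, ncol(s))
  denom <- sum(s[off]^2)
  w <- if (denom > 0) min(1, max(0, sum(var_s[off]) / denom)) else 1
  out <- (1 - w) * s
  diag(out) <- diag(s)
  attr(out, "shrinkage") <- w
  out
}

# Inverse square root of an SPD matrix via eigendecomposition.
inv_sqrtm <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (any(e$values <= 0)) abort("covariance must be positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Per-run condition-mean patterns: run x condition x voxel.
run_condition_means <- function(dataset) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  apply(dataset$betas, c(1, 2, 4), mean)
}

#' Cross-validated Mahalanobis (crossnobis) distances
#'
#' Computes the crossnobis distance between each condition pair from per-run
#' condition-mean patterns. Patterns are prewhitened with the inverse square
#' root of the residual-derived noise covariance, so that inner products
#' become Mahalanobis products; the distance for a pair (i, j) is then
#' \deqn{d_{ij} = \frac{1}{M(M-1)P} \sum_{m \ne n}
#'   (w_{i,m}-w_{j,m}) \cdot (w_{i,n}-w_{j,n}),}
#' the average over all ordered pairs of the M runs (independent
#' cross-validation folds), normalized by the voxel count P. Because the
#' two factors come from independent folds, the estimate is unbiased: its
#' expected value is 0 when the conditions are statistically
#' indistinguishable, and single estimates may legitimately be negative.
#'
#' @param dataset A `pattern_dataset` (per-run condition means are computed
#'   from its betas; its residuals supply the covariance unless `sigma` is
#'   given).
#' @param sigma Optional noise covariance to prewhiten with; defaults to
#'   [shrink_covariance()] of the dataset residuals.
#' @param sigma_method `"pooled"` (default; residual samples of all runs
#'   pooled before shrinkage) or `"per_run"` (each run's covariance shrunk
#'   separately, then averaged).
#' @return An object of class `crossnobis_dist`: the symmetric
#'   condition × condition distance matrix with zero diagonal, plus fold
#'   count and shrinkage metadata.
#' @examples
#' study <- simulate_pattern_study(pattern_gen_spec(n_voxels = 10,
#'   trials_per_finger_imagery = 4, trials_per_finger_execution = 6))
#' crossnobis(study$imagery_pre)
#' @export
crossnobis <- function(dataset, sigma = NULL,
                       sigma_method = c("pooled", "per_run")) {
  sigma_method <- match.arg(sigma_method)
  means <- run_condition_means(dataset)
  m <- dim(means)[1]
  if (m < 2) abort("at least 2 runs are required for cross-validation")
  if (is.null(sigma)) {
    sigma <- if (sigma_method == "pooled") {
      shrink_covariance(dataset$residuals)
    } else {
      mats <- lapply(seq_len(m), function(r) {
        shrink_covariance(matrix(dataset$residuals[r, , ],
                                 dim(dataset$residuals)[2],
                                 dim(dataset$residuals)[3]))
      })
      Reduce(`+`, mats) / m
    }
  }
  w_half <- inv_sqrtm(sigma)
  conds <- dimnames(dataset$betas)$condition
  k <- length(conds)
  p <- dim(means)[3]
  # whiten each run's condition patterns
  white <- array(NA_real_, dim(means))
  for (r in seq_len(m)) {
    white[r, , ] <- matrix(means[r, , ], k, p) %*% w_half
  }
  dist <- matrix(0, k, k, dimnames = list(conds, conds))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      delta <- white[, i, , drop = FALSE] - white[, j, , drop = FALSE]
      delta <- matrix(delta, m, p)
      tot <- colSums(delta)
      # sum over ordered fold pairs m != n of delta_m . delta_n
      cross <- sum(tot^2) - sum(delta^2)
      dist[i, j] <- dist[j, i] <- cross / (m * (m - 1) * p)
    }
  }
  structure(list(dist = dist, n_folds = m,
                 shrinkage = attr(sigma, "shrinkage") %||% NA_real_,
                 task = dataset$task, session = dataset$session),
            class = "crossnobis_dist")
}

#' @export
print.crossnobis_dist <- function(x, ...) {
  cat(sprintf("<crossnobis_dist> %s folds, avg inter-condition distance %.6g\n",
              x$n_folds, avg_interfinger(x)))
  print(signif(x$dist, 6))
  invisible(x)
}

#' @export
tidy.crossnobis_dist <- function(x, ...) {
  conds <- rownames(x$dist)
  idx <- which(upper.tri(x$dist), arr.ind = TRUE)
  tibble::tibble(cond_a = conds[idx[, 1]], cond_b = conds[idx[, 2]],
                 distance = x$dist[idx])
}

#' Average inter-finger distance
#'
#' The strength of the finger representation in a region: the mean of the
#' pairwise crossnobis distances (the three off-diagonal finger pairs).
#'
#' @param distmat A `crossnobis_dist` or a symmetric distance matrix.
#' @return The mean off-diagonal distance (unitless).
#' @export
avg_interfinger <- function(distmat) {
  d <- if (inherits(distmat, "crossnobis_dist")) distmat$dist else as.matrix(distmat)
  mean(d[upper.tri(d)])
}

#' Feature scaler fitted on training data
#'
#' Learns per-feature centre and scale (mean and SD) from training rows and
#' applies them unchanged to any other matrix, so that test data never leaks
#' into the scaling. Constant features get a unit divisor.
#'
#' @param train Training feature matrix (rows = trials).
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler`.
#' @param x Matrix to transform with the training parameters.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

# Linear maximum-margin classifier (soft-margin SVM, linear kernel, C = 1).
fit_linear_svm <- function(x, y, cost = 1) {
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE,
             tolerance = 1e-6)
}

new_decoding_result <- function(accuracy, predictions, labels, scheme) {
  structure(list(accuracy = accuracy, predictions = predictions,
                 labels = labels, scheme = scheme,
                 null = NULL, p_value = NA_real_),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s: accuracy %.2f%%", x$scheme, x$accuracy))
  if (!is.na(x$p_value)) cat(sprintf(", empirical p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, accuracy = x$accuracy,
                 n_trials = length(x$labels),
                 n_perm = if (is.null(x$null)) 0L else length(x$null),
                 p_value = x$p_value)
}

#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(label = x$labels, prediction = x$predictions,
                 correct = x$labels == x$predictions)
}

#' Leave-one-run-out decoding accuracy
#'
#' Within-task cross-validated decoding: each run in turn is held out, a
#' feature scaler is fitted on the remaining runs and applied to the
#' held-out run, a linear soft-margin SVM (C = 1) is trained on the scaled
#' training trials, and the held-out trials are predicted. Accuracy is the
#' mean fold accuracy, in percent.
#'
#' @param x Trial × voxel feature matrix (see [as_trial_matrix()]).
#' @param y Condition labels (factor or character).
#' @param run Run index per trial; defines the folds.
#' @param cost SVM regularisation constant.
#' @return A `decoding_result` with per-trial predictions in fold order.
#' @export
loro_cv <- function(x, y, run, cost = 1) {
  y <- factor(y)
  runs <- unique(run)
  if (length(runs) < 2) abort("at least 2 runs are required")
  preds <- character(0); labs <- character(0); fold_acc <- numeric(0)
  for (r in runs) {
    tr <- run != r
    sc <- fit_scaler(x[tr, , drop = FALSE])
    fit <- fit_linear_svm(apply_scaler(sc, x[tr, , drop = FALSE]),
                          droplevels(y[tr]), cost)
    p <- as.character(predict(fit, apply_scaler(sc, x[!tr, , drop = FALSE])))
    preds <- c(preds, p)
    labs <- c(labs, as.character(y[!tr]))
    fold_acc <- c(fold_acc, mean(p == as.character(y[!tr])))
  }
  new_decoding_result(mean(fold_acc) * 100, preds, labs, "leave-one-run-out")
}

#' Cross-task decoding accuracy
#'
#' Trains the linear classifier on all motor-execution trials (both
#' sessions pooled) and tests it on one session's motor-imagery trials.
#' Scaling is fitted separately per task: the execution scaler on all
#' execution trials, the imagery scaler on all imagery trials, so the two
#' tasks are standardised within themselves before transfer.
#'
#' @param x_train,y_train Execution trials and labels.
#' @param x_test,y_test Imagery trials and labels for one session.
#' @param scaler_test Optional pre-fitted scaler for the test task (e.g.
#'   fitted on both sessions' imagery trials); defaults to a scaler fitted
#'   on `x_test`.
#' @param cost SVM regularisation constant.
#' @return A `decoding_result`.
#' @export
cross_task <- function(x_train, y_train, x_test, y_test,
                       scaler_test = NULL, cost = 1) {
  y_train <- factor(y_train)
  sc_train <- fit_scaler(x_train)
  sc_test <- scaler_test %||% fit_scaler(x_test)
  fit <- fit_linear_svm(apply_scaler(sc_train, x_train), y_train, cost)
  preds <- as.character(predict(fit, apply_scaler(sc_test, x_test)))
  labs <- as.character(y_test)
  new_decoding_result(mean(preds == labs) * 100, preds, labs, "cross-task")
}

#' Permutation null distribution and empirical p-value
#'
#' Builds the null distribution of classification accuracy by shuffling the
#' test-trial labels of a `decoding_result` (`n_perm` random permutations;
#' class counts are preserved because labels are permuted, not resampled)
#' and computes the empirical p-value
#' `p = (#\{null >= true\} + 1) / (n_perm + 1)`.
#'
#' @param result A `decoding_result` with per-trial predictions.
#' @param n_perm Number of permutations (1000 by default).
#' @return The `decoding_result` with `null` (accuracies, %) and `p_value`
#'   filled in.
#' @export
permutation_null <- function(result, n_perm = 1000) {
  stopifnot(inherits(result, "decoding_result"))
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  labs <- result$labels
  null <- vapply(seq_len(n_perm), function(i) {
    mean(result$predictions == sample(labs)) * 100
  }, numeric(1))
  result$null <- null
  result$p_value <- empirical_p(result$accuracy, null)
  result
}

#' @rdname permutation_null
#' @param true Observed accuracy.
#' @param null Vector of null accuracies.
#' @export
empirical_p <- function(true, null) {
  (sum(null >= true) + 1) / (length(null) + 1)
}

#' Fisher's method for combining p-values
#'
#' Combines independent p-values via `X = -2 * sum(log(p))`, which is
#' chi-square distributed with `2k` degrees of freedom under the joint null.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return A tibble: `statistic`, `df`, `p_combined`.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  tibble::tibble(statistic = stat, df = df,
                 p_combined = pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' False-discovery-rate control via the Benjamini–Hochberg step-up
#' procedure. The correction family should mirror the analysis structure
#' (e.g. within each group and region of interest); pass each family
#' separately.
#'
#' @param p_values Vector of p-values.
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' @export
autoplot.crossnobis_dist <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(df, dplyr::rename(df, cond_a = "cond_b", cond_b = "cond_a"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cond_a, y = .data$cond_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$distance, 3))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "crossnobis",
                  title = "Inter-finger crossnobis distances") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  if (is.null(object$null)) {
    abort("run `permutation_null()` first to obtain a null distribution")
  }
  ggplot2::ggplot(tibble::tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$accuracy, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "accuracy (%)", y = "permutations",
                  title = sprintf("%s decoding: %.1f%%, empirical p = %.4g",
                                  object$scheme, object$accuracy, object$p_value)) +
    ggplot2::theme_minimal()
}
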