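test_that("shrinkage covariance converges to the truth and stays PD", {
  set.seed(71)
  p <- 8
  big <- matrix(rnorm(4000 * p), 4000, p)
  s <- shrink_covariance(big)
  expect_lt(max(abs(s - diag(p))), 0.12)
  expect_true(attr(s, "shrinkage") >= 0 && attr(s, "shrinkage") <= 1)
  # duplicated samples (rank-deficient input): shrinkage keeps it PD
  dup <- big[rep(1:3, 10), ]
  sdup <- shrink_covariance(dup)
  expect_true(all(eigen(sdup, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(shrink_covariance(big[1, , drop = FALSE]), "at least 2")
  # correlated generator: Frobenius-close to the generating covariance
  rho <- 0.6
  sigma <- rho^abs(outer(1:p, 1:p, "-"))
  x <- matrix(rnorm(6000 * p), 6000, p) %*% chol(sigma)
  shat <- shrink_covariance(x)
  expect_lt(norm(shat - sigma, "F") / norm(sigma, "F"), 0.1)
})

test_that("crossnobis is zero for identical patterns and matches brute force", {
  conds <- c("thumb", "index", "little")
  # all conditions share one pattern within each run: every pairwise
  # difference is exactly zero, so every distance is too
  pat <- array(NA_real_, c(2, 3, 2), dimnames = list(NULL, conds, NULL))
  for (cc in 1:3) pat[, cc, ] <- matrix(c(1, 2, -0.5, 3), 2, 2)
  res <- array(rnorm(2 * 40 * 2), c(2, 40, 2))
  ds <- dataset_from_patterns(pat, res)
  d <- crossnobis(ds, sigma = diag(2))
  expect_equal(max(abs(d$dist)), 0)

  # 2 runs x 2 voxels, hand-written numbers, non-trivial covariance
  pat2 <- array(c(0.3, -0.1, 1.2, 0.8, -0.5, 0.9,
                  0.7, 0.2, -0.4, 1.1, 0.6, -0.2),
                c(2, 3, 2), dimnames = list(NULL, conds, NULL))
  sigma <- matrix(c(1.5, 0.4, 0.4, 0.9), 2)
  ds2 <- dataset_from_patterns(pat2, res)
  d2 <- crossnobis(ds2, sigma = sigma)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(d2$dist[pair[1], pair[2]],
                 crossnobis_bruteforce(pat2, sigma, pair[1], pair[2]),
                 tolerance = 1e-12)
  }
  expect_equal(d2$dist, t(d2$dist))
  expect_equal(diag(d2$dist), c(thumb = 0, index = 0, little = 0))
})

test_that("noiseless crossnobis equals squared Mahalanobis distance over P", {
  set.seed(72)
  p <- 6
  sigma <- 0.5^abs(outer(1:p, 1:p, "-"))
  mu <- matrix(rnorm(3 * p), 3, p, dimnames = list(fingers, NULL))
  pat <- array(NA_real_, c(4, 3, p), dimnames = list(NULL, fingers, NULL))
  for (r in 1:4) pat[r, , ] <- mu
  ds <- dataset_from_patterns(pat, array(rnorm(4 * 30 * p), c(4, 30, p)))
  d <- crossnobis(ds, sigma = sigma)
  delta <- mu[1, ] - mu[2, ]
  expect_equal(d$dist[1, 2],
               drop(delta %*% solve(sigma) %*% delta) / p,
               tolerance = 1e-10)
})

test_that("crossnobis is invariant under consistent invertible voxel transforms", {
  set.seed(73)
  spec <- small_pattern_spec()
  st <- simulate_pattern_study(spec)
  ds <- st$imagery_pre
  p <- dim(ds$betas)[4]
  qr_a <- qr(matrix(rnorm(p * p), p))
  rot <- qr.Q(qr_a) %*% diag(runif(p, 0.5, 2))
  sigma <- st$truth$noise_cov
  d0 <- crossnobis(ds, sigma = sigma)
  ds_rot <- ds
  dm <- dim(ds$betas)
  flat <- matrix(ds$betas, prod(dm[1:3]), dm[4]) %*% rot
  ds_rot$betas <- array(flat, dm, dimnames = dimnames(ds$betas))
  d1 <- crossnobis(ds_rot, sigma = t(rot) %*% sigma %*% rot)
  expect_equal(d1$dist, d0$dist, tolerance = 1e-8)
})

test_that("mean crossnobis grows quadratically with the generating separation", {
  set.seed(74)
  scales <- c(0, 0.3, 0.6)
  means <- vapply(scales, function(sc) {
    mean(replicate(12, {
      st <- simulate_pattern_study(small_pattern_spec(
        signal_scale_pre = sc, signal_scale_post = sc))
      avg_interfinger(crossnobis(st$imagery_pre))
    }))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # quadratic scaling: the 0.6 effect is ~4x the 0.3 effect
  expect_equal(means[3] / means[2], 4, tolerance = 0.5)
})

test_that("single crossnobis estimates may be negative and are not clipped", {
  set.seed(75)
  vals <- replicate(40, {
    st <- simulate_pattern_study(null_pattern_spec(
      n_voxels = 12, trials_per_finger_imagery = 8,
      trials_per_finger_execution = 12))
    tidy(crossnobis(st$imagery_pre))$distance
  })
  expect_true(any(vals < 0))
})

test_that("avg_interfinger averages the three off-diagonal pairs", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(1, 2, 3)
  m <- m + t(m)
  expect_equal(avg_interfinger(m), 2)
  expect_equal(avg_interfinger(matrix(0, 3, 3)), 0)
})

test_that("the feature scaler standardises training data and transfers affinely", {
  set.seed(76)
  x <- matrix(rnorm(60, sd = 3), 20, 3)
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-12)
  # constant feature: unit divisor, no NaN
  xc <- cbind(x, 5)
  zc <- apply_scaler(fit_scaler(xc), xc)
  expect_true(all(is.finite(zc)))
  expect_equal(zc[, 4], rep(0, 20))
  # test data transformed with training parameters only
  y <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_scaler(sc, y),
               sweep(sweep(y, 2, sc$center), 2, sc$scale, "/"))
})

test_that("leave-one-run-out decoding separates separable data and collapses when shuffled", {
  set.seed(77)
  st <- simulate_pattern_study(small_pattern_spec(
    signal_scale_pre = 4, signal_scale_post = 4, noise_sd = 0.5))
  tm <- as_trial_matrix(list(st$execution_pre, st$execution_post))
  expect_equal(loro_cv(tm$x, tm$y, tm$run)$accuracy, 100)
  shuffled <- loro_cv(tm$x, sample(tm$y), tm$run)$accuracy
  expect_lt(shuffled, 60)
  expect_error(loro_cv(tm$x, tm$y, rep(1, length(tm$y))), "2 runs")
})

test_that("cross-task transfer tracks the shared execution-imagery component", {
  acc_at <- function(shared, seed, reps = 1) {
    set.seed(seed)
    mean(replicate(reps, {
      st <- simulate_pattern_study(small_pattern_spec(
        signal_scale_pre = 2, signal_scale_post = 2,
        shared_exec_imagery = shared))
      exec <- as_trial_matrix(list(st$execution_pre, st$execution_post))
      im <- as_trial_matrix(st$imagery_pre)
      cross_task(exec$x, exec$y, im$x, im$y)$accuracy
    }))
  }
  expect_gt(acc_at(1, 78), 90)
  # no shared component: transfer averages to chance (single replicates vary
  # widely because the decision rule is fixed by the independent means)
  expect_lt(abs(acc_at(0, 79, reps = 8) - 100 / 3), 20)
  # reproducibility: same dataset, same accuracy bit for bit
  set.seed(80)
  st <- simulate_pattern_study(small_pattern_spec())
  exec <- as_trial_matrix(list(st$execution_pre, st$execution_post))
  im <- as_trial_matrix(st$imagery_pre)
  expect_identical(cross_task(exec$x, exec$y, im$x, im$y)$accuracy,
                   cross_task(exec$x, exec$y, im$x, im$y)$accuracy)
})

test_that("the empirical p-value follows the permutation formula", {
  null <- seq(0, 99.9, length.out = 1000)
  expect_equal(empirical_p(100, null), 1 / 1001)
  expect_equal(empirical_p(-1, null), 1)
  expect_equal(empirical_p(null[500], null), (501 + 1) / 1001)
  res <- mifind:::new_decoding_result(100, rep("thumb", 9),
                                      rep(c("thumb", "index", "little"), 3),
                                      "test")
  res$accuracy <- 100  # above any permuted accuracy of a 1/3-correct predictor
  set.seed(81)
  out <- permutation_null(res, n_perm = 200)
  expect_length(out$null, 200)
  expect_equal(out$p_value, 1 / 201)
  expect_error(permutation_null(res, n_perm = 0), "at least 1")
})

test_that("permutation preserves class counts", {
  res <- mifind:::new_decoding_result(50, rep(c("a", "b"), 10),
                                      rep(c("a", "b"), each = 10), "test")
  set.seed(82)
  # all permutations of the labels keep 10 a's and 10 b's, so any null
  # accuracy must be attainable from those counts
  out <- permutation_null(res, n_perm = 50)
  expect_true(all(out$null * 20 / 100 == round(out$null * 20 / 100)))
})

test_that("Fisher combination matches the chi-square oracle", {
  f <- fisher_combine(c(1, 1, 1))
  expect_equal(f$statistic, 0)
  expect_equal(f$p_combined, 1)
  f2 <- fisher_combine(c(0.05, 0.05))
  expect_equal(f2$statistic, -2 * sum(log(c(0.05, 0.05))), tolerance = 1e-12)
  expect_equal(f2$statistic, 11.98293, tolerance = 1e-4)
  expect_equal(f2$p_combined, pchisq(f2$statistic, 4, lower.tail = FALSE))
  expect_equal(f2$p_combined, 0.01747, tolerance = 1e-3)
  expect_equal(fisher_combine(c(0.2, 0.01, 0.7)),
               fisher_combine(c(0.7, 0.2, 0.01)))
  expect_error(fisher_combine(c(0, 0.5)), "p-values")
})

test_that("BH adjustment matches a brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  set.seed(83)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})
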