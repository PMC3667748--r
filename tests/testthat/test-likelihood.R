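test_that("multinomial log-likelihood: hand value, symmetry, linearity", {
  k <- c(8, 1, 1)
  g <- c(0.8, 0.1, 0.1)
  expect_equal(sfs_loglik(k, g), 8 * log(0.8) + 2 * log(0.1))
  expect_equal(sfs_loglik(k, g), -6.390319, tolerance = 1e-6)

  # consistent permutation of classes leaves the value unchanged
  p <- c(3, 1, 2)
  expect_equal(sfs_loglik(k[p], g[p]), sfs_loglik(k, g))

  # observing exactly L * g maximizes the full multinomial probability
  # (sfs_loglik drops the data-only coefficient; add it back here)
  L <- 100
  k0 <- L * g
  full_ll <- function(kk) sfs_loglik(kk, g) - sum(lgamma(kk + 1))
  base <- full_ll(k0)
  for (i in 1:3) {
    for (j in setdiff(1:3, i)) {
      kp <- k0; kp[i] <- kp[i] + 1; kp[j] <- kp[j] - 1
      expect_lt(full_ll(kp), base)
    }
  }

  # doubling counts doubles log-likelihood differences
  g2 <- c(0.7, 0.2, 0.1)
  d1 <- sfs_loglik(k, g) - sfs_loglik(k, g2)
  d2 <- sfs_loglik(2 * k, g) - sfs_loglik(2 * k, g2)
  expect_equal(d2, 2 * d1)

  # zero expected class with observations: -Inf, flagged
  v <- sfs_loglik(c(1, 1), c(1, 0))
  expect_identical(as.numeric(v), -Inf)
  expect_equal(attr(v, "zero_class"), 1L)
})

test_that("joint likelihood handles alpha, depth mismatch and bad parameters", {
  mix <- selection_mixture(c(0.8, 0, 0.2), c(0, -1, -200))
  test <- simulate_spectrum(20, 1e4, 0.01, mix, seed = 1)
  ref <- simulate_spectrum(20, 1e4, 0.01, 0, seed = 2)

  # all-ones alpha is bitwise identical to no alpha
  expect_identical(joint_negloglik(0.01, mix, test, ref),
                   joint_negloglik(0.01, mix, test, ref,
                                   alpha = rep(1, 11)))

  ref60 <- simulate_spectrum(60, 1e4, 0.01, 0, seed = 3)
  expect_error(joint_negloglik(0.01, mix, test, ref60), "depths")

  # invalid parameter points are +Inf, not errors (optimizer-safe)
  expect_identical(joint_negloglik(10, mix, test, ref), Inf)
  expect_error(joint_negloglik(0.01, mix, test, ref, alpha = rep(2, 11)),
               "zero class")
})

test_that("self-consistency: noiseless spectra return the generating parameters", {
  truth <- list(theta = 0.01, mix = selection_mixture(c(0.8, 0, 0.2),
                                                      c(0, -1, -300)))
  test <- simulate_spectrum(130, 5e5, truth$theta, truth$mix, noise = "none")
  ref <- simulate_spectrum(130, 5e5, truth$theta, 0, noise = "none")
  fit <- sfs_selection_fit(test, ref, seed = 1)
  expect_lt(abs(fit$fractions[["strong"]] - 0.2), 0.005)
  expect_lt(abs(fit$gammas[["strong"]] + 300) / 300, 0.05)
  expect_lt(abs(fit$theta - truth$theta) / truth$theta, 0.02)
})

test_that("identical neutral spectra yield no selection signal", {
  test <- simulate_spectrum(130, 2e5, 0.0132, 0, noise = "none")
  fit <- sfs_selection_fit(test, test, seed = 1)
  expect_lt(fit$fractions[["strong"]], 0.01)
  expect_lt(fit$fractions[["weak"]], 0.01)
})

test_that("a pure mutation deficit is fit as selection at the gamma limit", {
  # 22% of test sites carry no mutations; shape is neutral
  mix <- selection_mixture(c(0.78, 0, 0.22), c(0, -1, -Inf))
  test <- simulate_spectrum(130, 4e5, 0.0132, mix, seed = 7)
  ref <- simulate_spectrum(130, 4e5, 0.0132, 0, seed = 8)
  fit <- sfs_selection_fit(test, ref, seed = 1)
  expect_true(fit$strong_at_limit)
  expect_lt(fit$gammas[["strong"]], -693)
  expect_equal(fit$fractions[["strong"]], 0.22, tolerance = 0.1)
})

test_that("fit object methods are coherent", {
  mix <- selection_mixture(c(0.8, 0, 0.2), c(0, -1, -250))
  test <- simulate_spectrum(130, 2e5, 0.012, mix, seed = 11)
  ref <- simulate_spectrum(130, 2e5, 0.012, 0, seed = 12)
  fit <- sfs_selection_fit(test, ref, seed = 1)

  cf <- coef(fit)
  expect_named(cf, c("theta", "f_neutral", "f_weak", "f_strong",
                     "gamma_weak", "gamma_strong"))
  expect_equal(cf[["f_neutral"]] + cf[["f_weak"]] + cf[["f_strong"]], 1)

  f <- fitted(fit)
  expect_equal(sum(f$test), test$L, tolerance = 1e-6)
  expect_equal(sum(f$ref), ref$L, tolerance = 1e-6)
  expect_true(all(is.finite(residuals(fit)$test)))

  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_true(attr(ll, "df") %in% c(3L, 5L))

  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]]$test, "sfs_spectrum")
  expect_equal(sim[[1]]$test$L, test$L)

  pr <- predict(fit, n = 60)
  expect_s3_class(pr, "expected_sfs")
  expect_equal(sum(pr$g), 1, tolerance = 1e-8)
})

test_that("simulate_spectrum: exact mode, sampling mode, deficit category", {
  # noise = "none": neutral counts proportional to theta/i, summing to L
  sp <- simulate_spectrum(10, 1000, 0.05, 0, noise = "none")
  expect_equal(sp$L, 1000)
  g <- expected_sfs(10, 0.05, 0)$g
  expect_true(all(abs(sp$counts - 1000 * g) <= 1))

  # multinomial class frequencies within 4 binomial SEs
  L <- 1e6
  sp <- simulate_spectrum(10, L, 0.05, 0, seed = 3)
  se <- sqrt(g * (1 - g) / L)
  expect_true(all(abs(sp$counts / L - g) < 4 * se + 1e-12))

  # a zero-mutation category only contributes monomorphic sites
  mix <- selection_mixture(c(0.5, 0, 0.5), c(0, -1, -Inf))
  sp0 <- simulate_spectrum(10, 1e4, 1e-9, selection_mixture(1, -Inf),
                           seed = 4)
  expect_equal(unname(sp0$counts[1L]), 1e4)

  # determinism under a fixed seed
  a <- simulate_spectrum(20, 1e4, 0.01, mix, seed = 9)
  b <- simulate_spectrum(20, 1e4, 0.01, mix, seed = 9)
  expect_identical(a$counts, b$counts)
})

test_that("shallow sampling flattens the selection-vs-deficit likelihood contrast", {
  # compare the generating model (gamma = -283) with a deficit-matched
  # boundary alternative (gamma = -700, fraction rescaled so the same
  # polymorphism is missing) on noiseless spectra: at 130 chromosomes the
  # alternative is clearly worse; at 60 it costs only a couple of
  # log-likelihood units, within reach of sampling noise
  L <- 8.6e5
  penalty <- vapply(c(60, 130), function(n) {
    truth <- selection_mixture(c(0.774, 0, 0.226), c(0, -1, -283))
    tsp <- simulate_spectrum(n, L, 0.0132, truth, noise = "none")
    rsp <- simulate_spectrum(n, L, 0.0132, 0, noise = "none")
    fs2 <- 0.226 * (1 - retention_ratio(n, -283)) /
      (1 - retention_ratio(n, -700))
    alt <- selection_mixture(c(1 - fs2, 0, fs2), c(0, -1, -700))
    joint_negloglik(0.0132, alt, tsp, rsp) -
      joint_negloglik(0.0132, truth, tsp, rsp)
  }, 0)
  expect_lt(penalty[1], 4)          # n = 60: nearly indistinguishable
  expect_gt(penalty[2], 6)          # n = 130: distinguishable
  expect_gt(penalty[2], 2 * penalty[1])
})
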