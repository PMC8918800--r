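test_that("mode/concentration conversion matches beta identities", {
  expect_equal(unname(mode_conc_to_shapes(0.5, 2)), c(1, 1))
  ab <- mode_conc_to_shapes(0.8, 12)
  expect_equal(unname(ab), c(9, 3))
  expect_equal(unname((ab[1] - 1) / (sum(ab) - 2)), 0.8)
  ab2 <- mode_conc_to_shapes(0.7, 22)
  expect_equal(unname(ab2), c(15, 7))
  expect_error(mode_conc_to_shapes(0.5, 1.5), "kappa")
})

test_that("clamped sampler reproduces the conjugate beta posterior", {
  fit <- fit_hierarchical(data.frame(n_trials = 200, n_successes = 140),
                          chains = 3, samples = 10000, burn_in = 500,
                          seed = 301, omega_fixed = 0.5, kappa_fixed = 2)
  draws <- as.numeric(fit$p[, , 1])
  qs <- quantile(draws, c(0.025, 0.5, 0.975))
  expect_lt(max(abs(qs - qbeta(c(0.025, 0.5, 0.975), 141, 61))), 0.01)
  ks <- suppressWarnings(ks.test(draws, pbeta, 141, 61))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the hierarchy recovers known cohort parameters", {
  coh <- simulate_fish_cohort(0.7, 30, n_fish = 20,
                              n_trials_per_fish = 200, seed = 302)
  fit <- fit_hierarchical(coh, chains = 3, samples = 3000, burn_in = 800,
                          seed = 303)
  iv <- hdi(as.numeric(fit$omega))
  expect_lte(iv$lower, 0.7)
  expect_gte(iv$upper, 0.7)
  expect_true(all(fit$rhat[c("omega", "kappa")] < 1.05))

  # shrinkage: posterior fish means sit between raw rate and group mean
  # (slack of 0.005 covers Monte Carlo error when raw is already close)
  post_p <- apply(fit$p, 3, mean)
  raw <- coh$n_successes / coh$n_trials
  grand <- mean(as.numeric(fit$omega))
  inside <- (post_p >= pmin(raw, grand) - 0.005) &
            (post_p <= pmax(raw, grand) + 0.005)
  expect_true(all(inside))
})

test_that("fits are deterministic and reject bad inputs", {
  d <- data.frame(n_trials = c(100, 100), n_successes = c(70, 60))
  f1 <- fit_hierarchical(d, chains = 2, samples = 1200, burn_in = 200,
                         seed = 304)
  f2 <- fit_hierarchical(d, chains = 2, samples = 1200, burn_in = 200,
                         seed = 304)
  expect_identical(f1$omega, f2$omega)
  expect_identical(f1$p, f2$p)
  expect_error(fit_hierarchical(data.frame(n_trials = 0, n_successes = 0)),
               "at least one trial")
})

test_that("prior upper bound on kappa barely moves the omega posterior", {
  coh <- simulate_fish_cohort(0.7, 30, n_fish = 10,
                              n_trials_per_fish = 200, seed = 305)
  f_narrow <- fit_hierarchical(coh, chains = 2, samples = 2000,
                               burn_in = 500, seed = 306, kappa_max = 502)
  f_wide <- fit_hierarchical(coh, chains = 2, samples = 2000,
                             burn_in = 500, seed = 306, kappa_max = 2002)
  expect_lt(abs(mean(f_narrow$omega) - mean(f_wide$omega)), 0.01)
})

test_that("sample HDIs match analytic and grid-oracle intervals", {
  set.seed(307)
  z <- rnorm(100000)
  iv <- hdi(z)
  expect_lt(abs(iv$lower + 1.96), 0.03)
  expect_lt(abs(iv$upper - 1.96), 0.03)

  b <- rbeta(100000, 9, 3)
  ivb <- hdi(b)
  oracle <- oracle_beta_hdi(9, 3)
  expect_lt(abs(ivb$lower - oracle[1]), 0.02)
  expect_lt(abs(ivb$upper - oracle[2]), 0.02)

  full <- hdi(z, mass = 1)
  expect_equal(c(full$lower, full$upper), range(z))
  expect_error(hdi(rnorm(100)), "1000")
})

test_that("ROPE decisions cover every interval position", {
  expect_equal(rope_assessment(c(0.66, 0.79)), "above")
  expect_equal(rope_assessment(c(0.46, 0.54)), "within")
  expect_equal(rope_assessment(c(0.53, 0.70)), "overlapping")
  expect_equal(rope_assessment(c(0.10, 0.40)), "below")
  expect_equal(rope_assessment(c(-0.02, 0.03), center = 0), "within")
})

test_that("condition comparisons separate distinct cohorts only", {
  set.seed(308)
  x <- rbeta(3000, 20, 10)
  same <- compare_success_rates(x, x)
  expect_equal(same$decision, "within")
  expect_equal(same$mean_diff, 0)

  c1 <- simulate_fish_cohort(0.75, 30, 20, 200, seed = 309)
  c2 <- simulate_fish_cohort(0.60, 30, 20, 200, seed = 310)
  f1 <- fit_hierarchical(c1, chains = 2, samples = 1500, burn_in = 400,
                         seed = 311)
  f2 <- fit_hierarchical(c2, chains = 2, samples = 1500, burn_in = 400,
                         seed = 312)
  res <- compare_success_rates(f1, f2)
  expect_equal(res$decision, "above")

  # equal cohorts rarely flag a difference
  flags <- vapply(1:10, function(i) {
    a <- simulate_fish_cohort(0.7, 30, 10, 200, seed = 400 + i)
    b <- simulate_fish_cohort(0.7, 30, 10, 200, seed = 500 + i)
    fa <- fit_hierarchical(a, chains = 2, samples = 800, burn_in = 300,
                           seed = 600 + i)
    fb <- fit_hierarchical(b, chains = 2, samples = 800, burn_in = 300,
                           seed = 700 + i)
    compare_success_rates(fa, fb)$decision
  }, character(1))
  expect_gte(sum(flags %in% c("within", "overlapping")), 9)

  expect_error(compare_success_rates(rnorm(2000), rnorm(1500)), "matched")
})

test_that("split R-hat flags disagreeing chains", {
  set.seed(313)
  good <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- good
  bad[, 1] <- bad[, 1] + 5
  expect_gt(rhat(bad), 1.2)
  expect_error(rhat(good[, 1, drop = FALSE]), "2 chains")
})

test_that("posterior summaries carry HDI, R-hat and ROPE per parameter", {
  coh <- simulate_fish_cohort(0.72, 40, n_fish = 4,
                              n_trials_per_fish = 200, seed = 314)
  fit <- fit_hierarchical(coh, chains = 2, samples = 1500, burn_in = 400,
                          seed = 315)
  s <- posterior_summary(fit)
  expect_equal(nrow(s), 6)  # omega + 4 fish + kappa
  expect_true(all(c("omega", "kappa") %in% s$parameter))
  expect_true(all(s$hdi_lower < s$hdi_upper))
  expect_equal(s$rope_decision[s$parameter == "omega"], "above")
})
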