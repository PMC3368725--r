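test_that("a trajectory is fully determined by its parameters and seed", {
  a <- simulate_inhibition(ptk2, t_max = 600, seed = 11)
  b <- simulate_inhibition(ptk2, t_max = 600, seed = 11)
  expect_identical(a$events, b$events)
  expect_identical(a$absorbed, b$absorbed)
  c <- simulate_inhibition(ptk2, t_max = 600, seed = 12)
  expect_false(identical(a$events, c$events))

  p <- rate_parameters(0.05, 1, 0.02, 2, 20)
  x <- simulate_activation(p, initial_k = 3, seed = 7)
  y <- simulate_activation(p, initial_k = 3, seed = 7)
  expect_identical(x$events, y$events)
  expect_equal(x$final_m, 2L)
  expect_true(all(diff(x$events$time_s) > 0))
})

test_that("without production the checkpoint trajectory stays empty", {
  p <- rate_parameters(0, 24, 2e-4, 13, 3000)
  tr <- simulate_inhibition(p, t_max = 1000, seed = 3)
  expect_equal(nrow(tr$events), 0L)
  expect_false(tr$absorbed)
  expect_equal(tr$final_k, 0L)
})

test_that("state changes are single steps of the declared channels", {
  tr <- simulate_inhibition(rate_parameters(0.05, 0.5, 0.01, 3, 40),
                            t_max = 400, seed = 21)
  steps <- diff(c(0L, tr$events$k))
  expect_true(all(steps[tr$events$event == "production"] == 1L))
  expect_true(all(steps[tr$events$event == "inhibition"] == -1L))
  if (tr$absorbed) {
    expect_equal(tr$events$event[nrow(tr$events)], "activation")
  }

  p <- rate_parameters(0.05, 1, 0.02, 3, 20)
  ta <- simulate_activation(p, initial_k = 0, seed = 5)
  dk <- diff(c(0L, ta$events$k))
  dm <- diff(c(0L, ta$events$m))
  expect_true(all((dk == 1L & dm == 0L) | (dk == 0L & dm == 1L)))
  expect_true(all(ta$events$m <= ta$events$k))
  expect_equal(ta$final_m, 3L)
})

test_that("two sequential exponential waits average to 1/lambda + 1/mu", {
  p <- rate_parameters(lambda = 0.5, k_minus1 = 1, mu = 0.25, N = 1, S = 1)
  ens <- simulate_ensemble(p, "activation", n_runs = 2000, seed = 99,
                           initial_k = 0)
  s <- ensemble_summary(ens)
  expect_equal(s$n_runs, 2000)
  expect_lt(abs(s$mean_absorption_time_s - (1 / 0.5 + 1 / 0.25)), 3 * s$se)
  # and the spread is genuinely that of a hypoexponential sum
  expect_gt(s$se, 0)
})

test_that("first-event channel frequencies follow the propensities", {
  # from (k = 5, m = 0) with N = 1, S = 10: production propensity
  # lambda*5, activation propensity mu*5
  p <- rate_parameters(lambda = 0.04, k_minus1 = 1, mu = 0.06, N = 1, S = 10)
  first <- vapply(1:1500, function(i) {
    simulate_activation(p, initial_k = 5, seed = 1e6 + i)$events$event[1]
  }, "")
  counts <- c(sum(first == "production"), sum(first == "activation"))
  probs <- c(0.04 * 5, 0.06 * 5) / (0.04 * 5 + 0.06 * 5)
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 1e-4)
})

test_that("ensemble summaries compute survival fractions and errors", {
  # all runs unabsorbed: survival 1 with zero standard error
  p0 <- rate_parameters(0, 24, 2e-4, 13, 3000)
  trajs <- lapply(1:3, function(i) {
    simulate_inhibition(p0, t_max = 100, seed = i)
  })
  s <- ensemble_summary(trajs, checkpoint_times = c(10, 50))
  expect_equal(s$survival, c(1, 1))
  expect_equal(s$se, c(0, 0))

  # a checkpoint time between two absorption times splits the ensemble
  pfast <- rate_parameters(lambda = 2, k_minus1 = 0, mu = 1, N = 2, S = 10)
  tr2 <- lapply(1:2, function(i) {
    simulate_inhibition(pfast, t_max = 1e4, seed = i)
  })
  t_abs <- sort(vapply(tr2, function(x) x$absorption_time_s, 0))
  mid <- mean(t_abs)
  s2 <- ensemble_summary(tr2, checkpoint_times = mid)
  expect_equal(s2$survival, 0.5)

  # phases cannot be mixed
  mixed <- list(simulate_inhibition(ptk2, 10, seed = 1),
                simulate_activation(ptk2, 100, seed = 1))
  expect_error(ensemble_summary(mixed, checkpoint_times = 1),
               class = "sacr_invalid_parameter")
})

test_that("empirical survival tracks the closed form at reduced ensemble size", {
  n <- 1000
  ens <- simulate_ensemble(ptk2, "inhibition", n_runs = n, seed = 314,
                           t_max = 1200)
  s <- ensemble_summary(ens, checkpoint_times = c(300, 1200))
  ref <- survival_probability(ptk2, c(300, 1200))
  expect_true(all(abs(s$survival - ref) <=
                    3 * sqrt(ref * (1 - ref) / n) + 1e-12))
})

test_that("long-run occupancy under pure inhibition matches the binomial law", {
  p <- rate_parameters(lambda = 0.4, k_minus1 = 0.6, mu = 0, N = 3, S = 30)
  t_max <- 30 / (0.4 + 0.6) # 30 relaxation times
  n <- 1500
  ens <- simulate_ensemble(p, "inhibition", n_runs = n, seed = 2718,
                           t_max = t_max)
  expect_false(any(ens$absorbed))
  pmf <- equilibrium_distribution(p)$probability
  counts <- tabulate(ens$final_k + 1L, nbins = 31L)
  # pool sparse tail bins so expected counts stay above ~5
  keep <- which(n * pmf >= 5)
  for (k1 in keep) {
    se <- sqrt(n * pmf[k1] * (1 - pmf[k1]))
    expect_lt(abs(counts[k1] - n * pmf[k1]), 3 * se)
  }
  tail_p <- sum(pmf[-keep])
  tail_n <- sum(counts[-keep])
  expect_lt(abs(tail_n - n * tail_p), 3 * sqrt(n * tail_p * (1 - tail_p)))
})
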