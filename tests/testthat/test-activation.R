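test_that("one complex, one target: tau is two sequential exponential waits", {
  p <- rate_parameters(lambda = 0.5, k_minus1 = 1, mu = 0.25, N = 1, S = 1)
  init <- point_mass_at(0, 1)
  expect_equal(mean_activation_time(p, init), 1 / 0.5 + 1 / 0.25,
               tolerance = 1e-12)
  expect_equal(mean_activation_time(p, init, method = "matrix"),
               1 / 0.5 + 1 / 0.25, tolerance = 1e-12)
})

test_that("topological sweep and sparse fundamental-matrix solve coincide", {
  for (p in random_params(10, seed = 505)) {
    occ_s <- occupation_times(p)
    occ_m <- occupation_times(p, method = "matrix")
    expect_equal(attr(occ_s, "tau"), attr(occ_m, "tau"), tolerance = 1e-10)
    # per-state occupation times, not just their sum
    expect_equal(
      dplyr::arrange(tidy(occ_s), m, k)$time_s,
      dplyr::arrange(tidy(occ_m), m, k)$time_s,
      tolerance = 1e-9
    )
  }
})

test_that("occupation times match time-integration of the transient chain", {
  p <- rate_parameters(lambda = 0.2, k_minus1 = 1, mu = 0.1, N = 2, S = 6)
  init <- point_mass_at(0, 6)
  occ <- occupation_times(p, init)

  horizon <- 60
  tr <- transient_distribution(p, t_end = horizon, initial_pmf = init,
                               times = seq(0, horizon, by = 0.02),
                               rel_tol = 1e-10)
  traj <- attr(tr, "trajectory")
  idx <- attr(traj, "state_index")
  times <- attr(traj, "times")
  dt <- diff(times)
  quad <- vapply(seq_len(ncol(traj)), function(j) {
    y <- traj[, j]
    sum(dt * (y[-1] + y[-length(y)]) / 2)
  }, 0)
  quad_tbl <- tibble::tibble(k = idx$k, m = idx$m, quad = quad)

  joined <- dplyr::left_join(tidy(occ), quad_tbl, by = c("k", "m"))
  expect_lt(max(abs(joined$time_s - joined$quad)), 1e-4)
  trans_mass <- sum(quad_tbl$quad[quad_tbl$m < p$N])
  expect_equal(attr(occ, "tau"), trans_mass, tolerance = 1e-4)
})

test_that("the transient distribution honours its boundary behaviour", {
  p <- rate_parameters(lambda = 0.2, k_minus1 = 1, mu = 0.1, N = 2, S = 6)
  init <- point_mass_at(2, 6)
  tr0 <- transient_distribution(p, t_end = 0, initial_pmf = init)
  expect_equal(tr0$probability[tr0$k == 2 & tr0$m == 0], 1)
  expect_equal(sum(tr0$probability), 1)

  # lambda = 0 from k = 0: frozen at the origin
  pf <- rate_parameters(0, 1, 0.05, 2, 6)
  trf <- transient_distribution(pf, t_end = 50,
                                initial_pmf = point_mass_at(0, 6))
  expect_equal(trf$probability[trf$k == 0 & trf$m == 0], 1, tolerance = 1e-8)

  # absorption mass is non-decreasing in time
  absorbed <- vapply(c(5, 20, 60, 150), function(tt) {
    attr(transient_distribution(p, tt, initial_pmf = point_mass_at(0, 6)),
         "p_absorbed")
  }, 0)
  expect_true(all(diff(absorbed) > 0))
  expect_true(all(absorbed >= 0 & absorbed <= 1))
})

test_that("instantaneous binding reduces tau to the pure production time", {
  p <- rate_parameters(lambda = 1e-4, k_minus1 = 24, mu = 1e4 * 0.3,
                       N = 13, S = 3000)
  tau <- mean_activation_time(p, point_mass_at(0, 3000))
  production_only <- sum(1 / (1e-4 * (3000 - 0:12)))
  expect_equal(tau, production_only, tolerance = 0.01)
  expect_gt(tau, production_only) # binding still takes positive time
})

test_that("tau falls with production and rises with inhibition", {
  taus_lam <- vapply(c(0.1, 0.2, 0.3, 0.5), function(lS) {
    mean_activation_time(rate_parameters(lS / 3000, 24, 2e-4, 13, 3000))
  }, 0)
  expect_true(all(diff(taus_lam) < 0))

  taus_k1 <- vapply(c(1, 10, 24, 50), function(k1) {
    mean_activation_time(rate_parameters(1e-4, k1, 2e-4, 13, 3000))
  }, 0)
  expect_true(all(diff(taus_k1) > 0))
})

test_that("degenerate activation problems are refused with diagnostics", {
  p0 <- rate_parameters(0, 1, 0.05, 3, 10)
  # equilibrium init under lambda = 0 is the point mass at 0: divergent
  expect_error(occupation_times(p0), class = "sacr_divergent_mean_time")
  # but mass already above the threshold activates fine
  tau <- mean_activation_time(p0, point_mass_at(5, 10))
  expect_equal(tau, sum(1 / (0.05 * (3:1) * (5:3))), tolerance = 1e-12)

  expect_error(occupation_times(ptk2, initial_pmf = c(0.5, 0.5)),
               class = "sacr_invalid_parameter")
  bad <- point_mass_at(0, 3000) * 2
  expect_error(occupation_times(ptk2, initial_pmf = bad),
               class = "sacr_invalid_parameter")
  expect_error(occupation_times(p0, point_mass_at(5, 10),
                                method = "matrix"),
               class = "sacr_invalid_parameter")
})

test_that("glance reports tau, the state count and the initial Cdc20 level", {
  occ <- occupation_times(ptk2)
  g <- glance(occ)
  expect_equal(g$n_states, sum(3001:(3001 - 12)))
  expect_equal(g$initial_mean_cdc20, 3000 * 1e-4 / 24.0001, tolerance = 1e-12)
  expect_equal(g$tau_s, attr(occ, "tau"))
  # occupation times are non-negative and absent below the diagonal
  expect_true(all(occ$time_s >= 0))
  expect_true(all(occ$k >= occ$m))
})
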