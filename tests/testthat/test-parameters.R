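test_that("geometric rate constructors reproduce direct arithmetic", {
  geom <- ptk2_geometry()
  # 4 * 0.01 * 20 / 100
  expect_equal(mu_from_geometry(geom), 8e-3)
  # 2*pi * 0.002 * 20 * (1e4 / 100) = 8*pi
  expect_equal(k_minus1_smoluchowski(geom), 8 * pi)
  expect_equal(k_minus1_smoluchowski(geom), 25.13274, tolerance = 1e-6)

  # linearity: doubling the volume halves mu; doubling MCC doubles k_minus1
  geom2 <- cell_geometry(200, 0.01, 0.002, 20, mcc_copies = 10000)
  expect_equal(mu_from_geometry(geom2), mu_from_geometry(geom) / 2)
  geom3 <- ptk2_geometry(mcc_copies = 20000)
  expect_equal(k_minus1_smoluchowski(geom3), 2 * k_minus1_smoluchowski(geom))

  # no inhibitor, no capture
  expect_equal(k_minus1_smoluchowski(ptk2_geometry(mcc_copies = 0)), 0)

  # vanishing target radius: mu -> 0 linearly
  mus <- vapply(c(1e-3, 1e-4, 1e-5), function(a) {
    mu_from_geometry(cell_geometry(100, a, 0.002, 20, mcc_copies = 1))
  }, 0)
  expect_equal(mus / mus[1], c(1, 0.1, 0.01))
})

test_that("4aD/V matches the spherical narrow-target form and is degree-1 in D", {
  for (V in c(1, 50, 100, 5000)) {
    geom <- cell_geometry(V, 0.005, 0.002, 20, mcc_copies = 100)
    R <- (3 * V / (4 * pi))^(1 / 3)
    spherical <- 3 * 0.005 * 20 / (pi * R^3)
    expect_equal(mu_from_geometry(geom), spherical, tolerance = 1e-12)
  }
  for (fac in c(0.5, 2, 10)) {
    g1 <- cell_geometry(100, 0.01, 0.002, 20, mcc_copies = 1000)
    g2 <- cell_geometry(100, 0.01, 0.002, 20 * fac, mcc_copies = 1000)
    expect_equal(mu_from_geometry(g2), fac * mu_from_geometry(g1))
    expect_equal(k_minus1_smoluchowski(g2), fac * k_minus1_smoluchowski(g1))
  }
})

test_that("nanomolar/copy-number conversion uses Avogadro arithmetic", {
  expect_equal(nanomolar_to_copies(50, 100), 3011)
  expect_equal(nanomolar_to_copies(200, 100), 12044)
  expect_equal(nanomolar_to_copies(0, 100), 0)
  # round trip within rounding over a wide volume range
  for (V in 10^(0:4)) {
    copies <- nanomolar_to_copies(37.5, V)
    back <- copies_to_nanomolar(copies, V)
    # rounding moves the count by at most 0.5 molecule
    expect_lt(abs(back - 37.5), copies_to_nanomolar(0.5, V) + 1e-12)
    expect_equal(nanomolar_to_copies(back, V), copies)
  }
})

test_that("PTK2 defaults carry the tabulated worked-point rates", {
  p <- default_ptk2_parameters()
  expect_s3_class(p, "sac_params")
  expect_equal(p$lambda, 1e-4)
  expect_equal(p$k_minus1, 24)
  expect_equal(p$mu, 2e-4)
  expect_equal(p$N, 13)
  expect_equal(p$S, 3000)
  expect_equal(p$lambdaS, 0.3)
  # the defaults satisfy their own invariants
  expect_identical(as_tibble(rate_parameters(p$lambda, p$k_minus1, p$mu,
                                             p$N, p$S)),
                   as_tibble(p))
  td <- tidy(p)
  expect_named(td, c("term", "estimate", "unit"))
  expect_equal(td$estimate[td$term == "lambdaS"], 0.3)
})

test_that("invalid physical and kinetic parameters are rejected", {
  expect_error(cell_geometry(-1, 0.01, 0.002, 20, mcc_copies = 10),
               class = "sacr_invalid_parameter")
  expect_error(cell_geometry(100, 0, 0.002, 20, mcc_copies = 10),
               class = "sacr_invalid_parameter")
  expect_error(cell_geometry(100, 0.01, 0.002, 20,
                             mcc_copies = 10, mcc_conc_nM = 5),
               class = "sacr_invalid_parameter")
  expect_error(
    k_minus1_smoluchowski(cell_geometry(100, 0.01, 0.002, 20)),
    class = "sacr_invalid_parameter"
  )
  expect_error(nanomolar_to_copies(-1, 100),
               class = "sacr_invalid_parameter")
  expect_error(rate_parameters(-1e-4, 24, 2e-4, 13, 3000),
               class = "sacr_invalid_parameter")
  expect_error(rate_parameters(1e-4, 24, 2e-4, 0, 3000),
               class = "sacr_invalid_parameter")
  expect_error(rate_parameters(1e-4, 24, 2e-4, 14, 13),
               class = "sacr_invalid_parameter")
})

test_that("leaving the small-target regime warns but does not fail", {
  expect_warning(cell_geometry(1, 0.5, 0.002, 20, mcc_copies = 10),
                 "small-target")
  expect_silent(cell_geometry(100, 0.01, 0.002, 20, mcc_copies = 10))
})
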