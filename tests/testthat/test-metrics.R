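test_that("batch uptake and efficiency match hand arithmetic", {
  expect_equal(adsorbed_amount(120, 24, 0.010, 0.100), 9.6)
  expect_equal(adsorbed_amount(6900, 5175, 0.010, 0.100), 172.5)
  expect_equal(adsorbed_amount(500, 500, 0.010, 0.100), 0)
  expect_equal(adsorption_efficiency(120, 24), 80)
  expect_equal(adsorption_efficiency(100, 100), 0)
  expect_equal(adsorption_efficiency(100, 0), 100)
  expect_error(adsorbed_amount(100, 200, 0.01, 0.1),
               class = "sorbkit_error_domain")
  expect_error(adsorption_efficiency(0, 0), class = "sorbkit_error_domain")
})

test_that("uptake and efficiency satisfy the mass-balance identities", {
  withr::with_seed(51, {
    for (i in 1:25) {
      c0 <- runif(1, 10, 7000)
      ce <- runif(1, 0, c0)
      v <- runif(1, 0.005, 0.05)
      m <- runif(1, 0.05, 0.5)
      qe <- adsorbed_amount(c0, ce, v, m)
      expect_equal(qe * m / v + ce, c0, tolerance = 1e-12)
      expect_equal(adsorption_efficiency(c0, ce), 100 * qe * m / (v * c0),
                   tolerance = 1e-12)
    }
  })
})

test_that("mean free adsorption energies reproduce tabulated values", {
  # constructed exact inverse: K = 1/(2 * 8000^2) J-units -> 8 kJ/mol
  expect_equal(energy_dr(1 / (2 * 8000^2)), 8)
  expect_equal(round(energy_dr(8.110e-9), 2), 7.85)
  expect_equal(round(energy_dr(1.648e-8), 2), 5.51)
  # n-generalized form: E = 1000 J/mol at n = 3 needs K = 5e-10
  expect_equal(energy_da(5e-10, 3), 1)
  expect_equal(energy_da(8.110e-9, 2), energy_dr(8.110e-9))
  expect_error(energy_dr(0), class = "sorbkit_error_domain")
  expect_error(energy_da(1e-9, 0.5), class = "sorbkit_error_domain")
})

test_that("energy_da at n = 2 equals energy_dr for any constant", {
  withr::with_seed(52, {
    k <- 10^runif(20, -12, -7)
    expect_equal(energy_da(k, 2), energy_dr(k), tolerance = 1e-14)
  })
})

test_that("molar ratio and surface-normalized capacity match hand values", {
  expect_equal(molar_ratio(202.8, q_fg = 1.47e-3),
               (202.8e-3 / 470.68) / 1.47e-3)
  expect_equal(round(molar_ratio(202.8, q_fg = 1.47e-3), 3), 0.293)
  expect_equal(molar_ratio(0, q_fg = 1e-3), 0)
  expect_equal(molar_ratio(1.47e-3 * 470.68 * 1000, q_fg = 1.47e-3), 1)
  expect_equal(round(surface_capacity(144.2, 149), 3), 0.968)
  expect_equal(round(surface_capacity(210.3, 438), 3), 0.480)
  expect_equal(surface_capacity(0, 100), 0)
  expect_error(molar_ratio(100, q_fg = 0), class = "sorbkit_error_domain")
})

test_that("percent reduction matches the textural-property comparisons", {
  expect_equal(round(percent_reduction(770, 438), 1), 43.1)
  expect_equal(round(percent_reduction(181, 149), 1), 17.7)
  expect_equal(percent_reduction(5, 5), 0)
  expect_lt(percent_reduction(100, 120), 0) # increases are negative
  expect_error(percent_reduction(0, 1), class = "sorbkit_error_domain")
})

test_that("model ranking orders by MPSD with ratio-based ties", {
  scores <- tibble::tibble(
    family = c("langmuir", "freundlich", "redlich_peterson", "temkin",
               "dubinin_radushkevich", "dubinin_astakhov"),
    method = "nonlinear",
    mpsd = c(4.66, 23.15, 2.72, 22.22, 9.74, 3.58)
  )
  r <- rank_models(scores)
  expect_equal(r$label, c("R-P", "D-A", "L", "D-R", "T", "F"))
  expect_equal(format(r), "R-P ~ D-A ~ L > D-R > T ~ F")
})

test_that("ranking handles single fits, exact ties, and input order", {
  single <- rank_models(tibble::tibble(family = "langmuir",
                                       method = "nonlinear", mpsd = 5))
  expect_equal(format(single), "L")

  tied <- rank_models(tibble::tibble(
    family = c("temkin", "freundlich"), method = "nonlinear",
    mpsd = c(3, 3)
  ))
  expect_equal(tied$label, c("F", "T")) # stable alphabetical on ties
  expect_equal(tied$relation[1], "~")

  scores <- tibble::tibble(
    family = c("langmuir", "freundlich", "temkin"),
    method = "linear", r2 = c(0.999, 0.94, 0.98)
  )
  a <- rank_models(scores)
  b <- rank_models(scores[c(3, 1, 2), ])
  expect_equal(a$family, b$family)
  expect_equal(format(a), format(b))
})

test_that("mixed estimation methods are refused without an override", {
  scores <- tibble::tibble(
    family = c("langmuir", "freundlich"),
    method = c("linear", "nonlinear"),
    mpsd = c(3, 4), r2 = c(0.99, 0.95)
  )
  expect_error(rank_models(scores), class = "sorbkit_error_input")
  expect_s3_class(rank_models(scores, by = "mpsd", allow_mixed = TRUE),
                  "model_ranking")
})
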