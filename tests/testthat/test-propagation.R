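test_that("sensitivity coefficients match frozen high-precision values", {
  s <- sensitivity_coefficients(alpha = 1, beta = 0.1)
  expect_equal(s$c1, 1)
  expect_equal(s$c2, 1)
  expect_equal(s$c3, 1.04916680552250, tolerance = 1e-12)
  expect_equal(s$c4, -0.950833194477505, tolerance = 1e-12)
  expect_error(sensitivity_coefficients(1, 0), "positive")
})

test_that("coefficients reach their short-acquisition limits as beta -> 0", {
  for (alpha in c(-2, 0, 0.5, 3)) {
    s <- sensitivity_coefficients(alpha, 1e-9)
    expect_equal(s$c3, alpha, tolerance = 1e-8)
    expect_equal(s$c4, -1, tolerance = 1e-8)
  }
  # zero offset kills the X2 term entirely
  expect_equal(sensitivity_coefficients(0, 0.1)$c2, 0)
})

test_that("closed-form coefficients agree with the finite-difference oracle", {
  set.seed(42)
  n <- 1000
  alphas <- stats::runif(n, -3, 3)
  betas <- exp(stats::runif(n, log(1e-6), log(2)))
  s <- sensitivity_coefficients(alphas, betas)
  for (i in seq_len(n)) {
    fd <- fd_sensitivities(alphas[i], betas[i])
    expect_lt(abs(s$c1[i] - fd$c1), 1e-6 * max(1, abs(fd$c1)))
    expect_lt(abs(s$c2[i] - fd$c2), 1e-6 * max(1, abs(fd$c2)))
    expect_lt(abs(s$c3[i] - fd$c3), 1e-6 * max(1, abs(fd$c3)))
    expect_lt(abs(s$c4[i] - fd$c4), 1e-6 * max(1, abs(fd$c4)))
  }
})

terms_ab <- function(alpha, beta) {
  tibble::tibble(
    X1 = 1, X2 = alpha, X3 = 1, X4 = beta,
    alpha = alpha, beta = beta
  )
}

test_that("exact combined uncertainty matches the worked example", {
  u <- component_uncertainties(
    u_rel_R = 0.02, u_rel_offset = 0.01,
    u_rel_T_half = 0.0005, u_rel_T_acq = 0.001
  )
  b <- combined_exact(terms_ab(1, 0.1), u)
  expect_budget_valid(b)
  expect_equal(100 * b$u_rel_combined, 2.23870335576238, tolerance = 1e-10)
})

test_that("all-zero component uncertainties give a zero budget", {
  u <- component_uncertainties(u_offset = 0)
  b <- combined_exact(terms_ab(1, 0.1), u)
  expect_equal(b$u_rel_combined, 0)
  expect_true(all(b$components$share_pct == 0))
})

test_that("the clinical baseline set combines to about 4.90%", {
  b <- combined_exact(terms_ab(0, 1e-3), baseline_components())
  expect_budget_valid(b)
  expect_equal(100 * b$u_rel_combined, 4.9003, tolerance = 2e-4)
})

test_that("simplified budget matches hand arithmetic and warns off-regime", {
  u <- component_uncertainties(
    u_rel_R = 0.02, u_rel_offset = 0.01,
    u_rel_T_half = 0.0005, u_rel_T_acq = 0.001
  )
  b <- combined_simplified(terms_ab(1, 0.01), u)
  expect_budget_valid(b)
  expect_equal(100 * b$u_rel_combined, 2.23886131772381, tolerance = 1e-10)
  expect_false(b$regime_warning)

  expect_warning(
    bw <- combined_simplified(terms_ab(1, 0.5), u),
    class = "calibudget_regime_warning"
  )
  expect_true(bw$regime_warning)
})

test_that("exact and simplified forms disagree measurably at beta = 1", {
  u <- component_uncertainties(u_rel_T_acq = 0.001, u_offset = 0)
  be <- combined_exact(terms_ab(0, 1), u)
  bs <- suppressWarnings(combined_simplified(terms_ab(0, 1), u))
  # X4 coefficient squared is (beta e^-beta / (1-e^-beta))^2 = 0.33870, not 1
  g2 <- (exp(-1) / (1 - exp(-1)))^2
  expect_equal(g2, 0.338696887338466, tolerance = 1e-12)
  expect_equal(
    be$u_rel_combined / bs$u_rel_combined,
    sqrt(g2),
    tolerance = 1e-12
  )
})

test_that("exact converges to simplified as beta -> 0 (baseline set)", {
  u <- baseline_components()
  for (alpha in c(0, 1)) {
    be <- combined_exact(terms_ab(max(alpha, 1e-12), 1e-3), u)
    bs <- combined_simplified(terms_ab(max(alpha, 1e-12), 1e-3), u)
    expect_lt(
      abs(be$u_rel_combined - bs$u_rel_combined) / be$u_rel_combined,
      1e-4
    )
  }
})

test_that("the practical formula matches its worked example", {
  sc <- calibration_scenario(
    R = uq(1e6, 4e4, "counts"), V = uq(100, 2, "mL"),
    A = uq(1e5, 2e3, "Bq"), V_liq = uq(100, 0.05, "mL"),
    time_offset = uq(1.8289, 1 / 60, "h"),
    T_half = parse_parenthetic("1.82890(23) h"),
    T_acq = uq(15, 0.015, "min")
  )
  b <- combined_practical(sc)
  expect_budget_valid(b)
  # clock-offset term alone: (1 min * ln2 / 1.8289 h) = 0.6317%
  off <- b$components$contribution[b$components$component == "time_offset"]
  expect_equal(100 * sqrt(off), 0.631661272312998, tolerance = 1e-6)
  expect_equal(100 * b$u_rel_combined, 4.94080612331369, tolerance = 1e-6)
})

test_that("practical equals simplified on randomized scenarios", {
  set.seed(7)
  for (i in 1:50) {
    sc <- calibration_scenario(
      R = uq(1e6, 1e6 * stats::runif(1, 0, 0.05), "counts"),
      V = uq(100, 100 * stats::runif(1, 0, 0.05), "mL"),
      A = uq(1e5, 1e5 * stats::runif(1, 0, 0.05), "Bq"),
      V_liq = uq(100, 100 * stats::runif(1, 0, 0.01), "mL"),
      time_offset = uq(stats::runif(1, -10, 10), stats::runif(1, 0, 0.2), "h"),
      T_half = uq(stats::runif(1, 1, 200), stats::runif(1, 0, 0.01), "h"),
      T_acq = uq(stats::runif(1, 5, 30), stats::runif(1, 0, 0.01), "min")
    )
    bp <- combined_practical(sc)
    bs <- combined_simplified(sc)
    expect_equal(bp$u_rel_combined, bs$u_rel_combined, tolerance = 1e-12)
    expect_budget_valid(bp)
  }
})

test_that("zero offset uncertainty removes the time-offset block", {
  sc <- tc99m_scenario()
  b <- combined_practical(sc)
  expect_equal(
    b$components$contribution[b$components$component == "time_offset"], 0
  )
})

test_that("clock-offset contribution is invariant in the time difference", {
  # same absolute clock uncertainty (300 s), time differences spanning two
  # decades, entered through the relative-uncertainty route so that the
  # alpha^2 * u_rel^2 product has to cancel the offset itself
  th_s <- 6.0067 * 3600
  offs <- 10^seq(log10(0.3), log10(30), length.out = 25) * 3600
  expected <- clock_offset_contribution(300, th_s)
  contribs <- vapply(offs, function(off) {
    u <- component_uncertainties(
      u_rel_R = 0.04, u_rel_V = 0.02, u_rel_Ca = 0.02,
      u_rel_offset = 300 / off,
      u_rel_T_half = 5e-4, u_rel_T_acq = 1e-3
    )
    terms <- tibble::tibble(
      X1 = 10, X2 = off, X3 = log(2) / th_s, X4 = 60,
      alpha = off * log(2) / th_s, beta = 60 * log(2) / th_s
    )
    b <- combined_exact(terms, u)
    b$components$contribution[b$components$component == "time_offset"]
  }, numeric(1))
  expect_lt(max(abs(contribs - expected)) / expected, 1e-12)
})

test_that("dropping any component never increases the combined uncertainty", {
  u_full <- baseline_components(u_offset_s = 300)
  terms <- terms_ab(0.5, 0.01)
  b_full <- combined_exact(terms, u_full)
  drops <- list(
    component_uncertainties(
      u_rel_V = 0.02, u_rel_Ca = 0.02, u_offset = 300,
      u_rel_T_half = 5e-4, u_rel_T_acq = 1e-3
    ),
    component_uncertainties(
      u_rel_R = 0.04, u_rel_V = 0.02, u_rel_Ca = 0.02, u_offset = 0,
      u_rel_T_half = 5e-4, u_rel_T_acq = 1e-3
    ),
    component_uncertainties(
      u_rel_R = 0.04, u_rel_V = 0.02, u_rel_Ca = 0.02, u_offset = 300,
      u_rel_T_half = 0, u_rel_T_acq = 0
    )
  )
  for (u_less in drops) {
    expect_lte(
      combined_exact(terms, u_less)$u_rel_combined,
      b_full$u_rel_combined
    )
  }
})

test_that("component-uncertainty construction enforces exclusivity", {
  expect_error(
    component_uncertainties(u_rel_Ca = 0.02, u_rel_A = 0.02, u_rel_Vliq = 0.01),
    "not both"
  )
  expect_error(
    component_uncertainties(u_rel_offset = 0.01, u_offset = 60),
    "not both"
  )
  expect_error(component_uncertainties(u_rel_R = -0.1), "non-negative")
})
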