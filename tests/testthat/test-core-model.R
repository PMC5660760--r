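test_that("derived terms match hand arithmetic on the Tc-99m example", {
  t <- derive_terms(tc99m_scenario())
  expect_equal(t$X1, 10)
  expect_equal(t$alpha, log(2), tolerance = 1e-12)
  expect_equal(t$beta, 0.00192326119322297, tolerance = 1e-9)
})

test_that("zero time offset gives alpha = 0 and decay works both ways", {
  sc0 <- calibration_scenario(
    R = uq(1e6, unit = "counts"), V = uq(100, unit = "mL"),
    C_a = uq(1000, unit = "Bq/mL"),
    time_offset = uq(0, unit = "h"), T_half = uq(6.0067, unit = "h"),
    T_acq = uq(60, unit = "s")
  )
  expect_equal(derive_terms(sc0)$alpha, 0)

  neg <- calibration_scenario(
    R = uq(1e6, unit = "counts"), V = uq(100, unit = "mL"),
    C_a = uq(1000, unit = "Bq/mL"),
    time_offset = uq(-6.0067, unit = "h"), T_half = uq(6.0067, unit = "h"),
    T_acq = uq(60, unit = "s")
  )
  expect_equal(derive_terms(neg)$alpha, -log(2), tolerance = 1e-12)
  # decay correction divides instead of multiplying
  expect_equal(
    calibration_factor(neg) * 4,
    calibration_factor(tc99m_scenario()),
    tolerance = 1e-12
  )
})

test_that("therapy-nuclide acquisitions sit deep in the small-beta regime", {
  lu <- calibration_scenario(
    R = uq(1e6, unit = "counts"), V = uq(100, unit = "mL"),
    C_a = uq(1000, unit = "Bq/mL"),
    time_offset = uq(0, unit = "h"), nuclide = "Lu-177",
    T_acq = uq(20, unit = "min")
  )
  expect_equal(derive_terms(lu)$beta, 0.00144832919729858, tolerance = 1e-9)
  expect_lt(derive_terms(lu)$beta, 1e-2)
})

test_that("calibration factor reproduces the high-precision reference value", {
  expect_equal(calibration_factor(tc99m_scenario()), 0.333653979613687,
    tolerance = 1e-12
  )
})

test_that("factorized and longhand model forms agree on a random grid", {
  set.seed(101)
  for (i in 1:200) {
    R <- stats::runif(1, 1e4, 1e8)
    V <- stats::runif(1, 1, 1e4)
    Ca <- stats::runif(1, 1, 1e5)
    Th <- stats::runif(1, 0.5, 300) * 3600
    off <- stats::runif(1, -3, 3) * Th / log(2)
    Tacq <- stats::runif(1, 1, 3600)
    sc <- calibration_scenario(
      R = uq(R, unit = "counts"), V = uq(V, unit = "mL"),
      C_a = uq(Ca, unit = "Bq/mL"),
      time_offset = uq(off, unit = "s"), T_half = uq(Th, unit = "s"),
      T_acq = uq(Tacq, unit = "s")
    )
    expect_equal(
      calibration_factor(sc),
      raw_model(R, V, Ca, off, Th, Tacq),
      tolerance = 1e-12
    )
  }
})

test_that("small-beta evaluation is expm1-stable down to beta ~ 1e-8", {
  for (beta in c(1e-3, 1e-5, 1e-8)) {
    terms <- tibble::tibble(
      X1 = 10, X2 = 0, X3 = 1e-4, X4 = beta / 1e-4,
      alpha = 0, beta = beta
    )
    s <- calibration_factor(terms)
    expect_true(is.finite(s) && s > 0)
    # converges to X1 * exp(alpha) / X4 with relative error bounded by beta
    limit <- terms$X1 / terms$X4
    expect_lt(abs(s - limit) / s, beta)
  }
  expect_error(
    calibration_factor(tibble::tibble(X1 = 1, X3 = 1, alpha = 0, beta = 0)),
    "beta must be positive"
  )
})

test_that("limiting case: long acquisition drives the decay factor to 1", {
  terms <- tibble::tibble(X1 = 1, X2 = 0, X3 = 1, X4 = 60, alpha = 0, beta = 60)
  expect_equal(calibration_factor(terms), 1, tolerance = 1e-12)
})

test_that("expressing times in different units leaves S_rc consistent", {
  sc_h <- tc99m_scenario()
  sc_s <- calibration_scenario(
    R = uq(1e6, unit = "counts"), V = uq(100, unit = "mL"),
    C_a = uq(1000, unit = "Bq/mL"),
    time_offset = uq(6.0067 * 3600, unit = "s"),
    T_half = uq(6.0067 * 60, unit = "min"),
    T_acq = uq(1, unit = "min")
  )
  # different T_acq (60 s vs 1 min) is the same physical scenario
  expect_equal(calibration_factor(sc_h), calibration_factor(sc_s),
    tolerance = 1e-12
  )
})

test_that("scenario validation rejects inconsistent input sets", {
  expect_error(
    calibration_scenario(
      R = uq(1, unit = "counts"), V = uq(1, unit = "mL"),
      C_a = uq(1, unit = "Bq/mL"), A = uq(1, unit = "Bq"),
      V_liq = uq(1, unit = "mL"),
      time_offset = uq(0, unit = "s"), T_half = uq(1, unit = "h"),
      T_acq = uq(1, unit = "s")
    ),
    "not both"
  )
  expect_error(
    calibration_scenario(
      R = uq(1, unit = "counts"), V = uq(1, unit = "mL"),
      time_offset = uq(0, unit = "s"), T_half = uq(1, unit = "h"),
      T_acq = uq(1, unit = "s")
    ),
    "supply C_a"
  )
  expect_error(
    calibration_scenario(
      R = uq(1, unit = "counts"), V = uq(1, unit = "mL"),
      C_a = uq(1, unit = "Bq/mL"),
      time_offset = uq(0, unit = "s"), T_half = uq(-1, unit = "h"),
      T_acq = uq(1, unit = "s")
    ),
    "T_half must be positive"
  )
})

test_that("activity plus solution volume composes the concentration", {
  sc <- calibration_scenario(
    R = uq(1e6, unit = "counts"), V = uq(100, unit = "mL"),
    A = uq(1e5, 2e3, "Bq"), V_liq = uq(100, 0.05, "mL"),
    time_offset = uq(0, unit = "s"), T_half = uq(6.0067, unit = "h"),
    T_acq = uq(60, unit = "s")
  )
  expect_equal(sc$C_a$value, 1000)
  expect_equal(
    uq_rel(sc$C_a),
    sqrt(0.02^2 + 0.0005^2),
    tolerance = 1e-12
  )
})
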