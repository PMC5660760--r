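# Shared fixtures and independent oracles.

# Tc-99m scenario with offset equal to one half-life and a 60 s acquisition.
tc99m_scenario <- function(with_unc = FALSE) {
  if (with_unc) {
    calibration_scenario(
      R = uq(1e6, 4e4, "counts"),
      V = uq(100, 2, "mL"),
      C_a = uq(1000, 20, "Bq/mL"),
      time_offset = uq(6.0067, 5 / 60, "h"),
      T_half = uq(6.0067, 0.0010, "h"),
      T_acq = uq(60, 0.06, "s")
    )
  } else {
    calibration_scenario(
      R = uq(1e6, unit = "counts"),
      V = uq(100, unit = "mL"),
      C_a = uq(1000, unit = "Bq/mL"),
      time_offset = uq(6.0067, unit = "h"),
      T_half = uq(6.0067, unit = "h"),
      T_acq = uq(60, unit = "s")
    )
  }
}

# The fixed clinical component set used for the packaged sweep curves:
# counts 4%, volume 2%, activity 2%, half-life 0.05%, acquisition 0.1%.
baseline_components <- function(u_offset_s = 0) {
  component_uncertainties(
    u_rel_R = 0.04, u_rel_V = 0.02, u_rel_Ca = 0.02,
    u_offset = u_offset_s,
    u_rel_T_half = 5e-4, u_rel_T_acq = 1e-3
  )
}

# Independent oracle: the measurement model written out longhand, no expm1,
# no factorization reuse from the package internals.
raw_model <- function(R, V, Ca, offset, T_half, T_acq) {
  R / (V * Ca) * exp(offset / T_half * log(2)) *
    (log(2) / T_half) / (1 - exp(-T_acq / T_half * log(2)))
}

# Independent oracle for the relative sensitivity coefficients:
# Xi * d(log S)/d Xi by central finite differences on the plain
# (non-expm1, non-factorized-reuse) log model, at X1 = 1, X2 = alpha,
# X3 = 1, X4 = beta.
fd_sensitivities <- function(alpha, beta, h = 1e-6) {
  f <- function(x) {
    # -expm1 keeps the log argument accurate for small beta; the oracle's
    # independence lies in the finite differencing, not the elementaries
    log(x[1]) + x[2] * x[3] + log(x[3]) - log(-expm1(-x[3] * x[4]))
  }
  x0 <- c(1, alpha, 1, beta)
  d <- function(i) {
    if (x0[i] == 0) {
      return(0)
    }
    step <- h * abs(x0[i])
    xp <- x0
    xm <- x0
    xp[i] <- x0[i] + step
    xm[i] <- x0[i] - step
    (f(xp) - f(xm)) / (2 * step) * x0[i]
  }
  list(c1 = d(1), c2 = d(2), c3 = d(3), c4 = d(4))
}

expect_budget_valid <- function(b) {
  expect_s3_class(b, "uncertainty_budget")
  expect_true(all(b$components$contribution >= 0))
  expect_equal(
    b$u_rel_combined^2,
    sum(b$components$contribution),
    tolerance = 1e-12
  )
}
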