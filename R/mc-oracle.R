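#' Monte-Carlo propagation through the calibration-factor model
#'
#' An independent check on the first-order law-of-propagation budgets:
#' every input is drawn from a normal distribution centred on its estimate
#' with its standard uncertainty (inputs independent), the calibration
#' factor is evaluated per draw, and the empirical relative standard
#' deviation of the draws is returned. In the small-uncertainty regime this
#' should agree with the combined relative uncertainty from
#' [combined_exact()] to within sampling error plus the (tiny)
#' linearization error.
#'
#' Normality is the minimal assumption consistent with quoting standard
#' uncertainties only. Draws producing non-positive half-life, acquisition
#' duration, volume, concentration, activity or solution volume are
#' rejected and counted; a rejection fraction above 1% aborts, since the
#' comparison with a first-order budget is meaningless in that regime
#' (truncating instead would silently bias the check).
#'
#' @param scenario A [calibration_scenario()].
#' @param u Optional [component_uncertainties()] overriding the
#'   uncertainties carried by the scenario (relative uncertainties are
#'   applied to the scenario's values).
#' @param n_draws Number of draws, at least 1000.
#' @param seed Integer seed; mandatory, no hidden global state is used.
#' @return An object of class `"mc_result"`: `n_draws`, `n_rejected`,
#'   `seed`, `mean_S`, `rel_sd_S`, `se_rel_sd` (standard error of the
#'   relative-SD estimate, approximately `rel_sd / sqrt(2 n)`), and
#'   `distribution = "normal"`.
#' @examples
#' sc <- calibration_scenario(
#'   R = uq(1e6, 4e4, "counts"), V = uq(100, 2, "mL"),
#'   C_a = uq(1000, 20, "Bq/mL"),
#'   time_offset = uq(0, 0, "h"), nuclide = "Tc-99m",
#'   T_acq = uq(900, 0.9, "s")
#' )
#' mc_propagate(sc, n_draws = 10000, seed = 42)
#' @export
mc_propagate <- function(scenario, u = NULL, n_draws = 1e5, seed) {
  stopifnot(inherits(scenario, "calibration_scenario"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_draws < 1000) stop("n_draws must be at least 1000", call. = FALSE)
  if (is.null(u)) u <- scenario_uncertainties(scenario)
  stopifnot(inherits(u, "component_uncertainties"))

  x2 <- uq_seconds(scenario$time_offset)$value
  th <- uq_seconds(scenario$T_half)$value
  tacq <- uq_seconds(scenario$T_acq)$value
  u_x2 <- if (!is.null(u$offset_abs)) {
    u$offset_abs
  } else if (!is.null(u$offset_rel)) {
    if (x2 == 0 && u$offset_rel > 0) {
      stop(
        "relative offset uncertainty with zero time offset; give u_offset absolutely",
        call. = FALSE
      )
    }
    u$offset_rel * abs(x2)
  } else {
    0
  }

  rel <- function(x) {
    vals <- c(
      u$r, u$v, u$ca, u$a, u$vliq, u$t_half, u$t_acq,
      if (x2 != 0) u_x2 / abs(x2)
    )
    vals
  }
  if (any(rel(u) > 0.20)) {
    stop(
      "relative uncertainties above 20% are outside the Monte-Carlo ",
      "comparison regime",
      call. = FALSE
    )
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  draw <- function(value, u_abs) {
    if (u_abs == 0) rep(value, n_draws) else stats::rnorm(n_draws, value, u_abs)
  }
  r_d <- draw(scenario$R$value, u$r * scenario$R$value)
  v_d <- draw(scenario$V$value, u$v * scenario$V$value)
  if (!is.null(u$a)) {
    a_d <- draw(scenario$A$value, u$a * scenario$A$value)
    vl_d <- draw(scenario$V_liq$value, u$vliq * scenario$V_liq$value)
    ca_d <- a_d / vl_d
    pos_ca <- a_d > 0 & vl_d > 0
  } else {
    ca_d <- draw(scenario$C_a$value, u$ca * scenario$C_a$value)
    pos_ca <- ca_d > 0
  }
  x2_d <- draw(x2, u_x2)
  th_d <- draw(th, u$t_half * th)
  t4_d <- draw(tacq, u$t_acq * tacq)

  ok <- pos_ca & v_d > 0 & th_d > 0 & t4_d > 0
  n_rej <- sum(!ok)
  if (n_rej / n_draws > 0.01) {
    stop(
      sprintf(
        "%.2f%% of draws produced non-physical (non-positive) inputs; uncertainties too large for the Monte-Carlo comparison",
        100 * n_rej / n_draws
      ),
      call. = FALSE
    )
  }

  x3_d <- log(2) / th_d[ok]
  s <- (r_d[ok] / (v_d[ok] * ca_d[ok])) * exp(x2_d[ok] * x3_d) *
    x3_d / (-expm1(-x3_d * t4_d[ok]))
  mean_s <- mean(s)
  rel_sd <- stats::sd(s) / mean_s
  structure(
    list(
      n_draws = as.integer(n_draws),
      n_rejected = as.integer(n_rej),
      seed = as.integer(seed),
      mean_S = mean_s,
      rel_sd_S = rel_sd,
      se_rel_sd = rel_sd / sqrt(2 * (n_draws - n_rej)),
      distribution = "normal"
    ),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> n = %d (%d rejected), seed = %d\n  mean S = %.6g, relative SD = %.4g%% (se %.2g%%)\n",
    x$n_draws, x$n_rejected, x$seed, x$mean_S,
    100 * x$rel_sd_S, 100 * x$se_rel_sd
  ))
  invisible(x)
}
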