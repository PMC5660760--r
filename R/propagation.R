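#' Component relative uncertainties for a budget
#'
#' Collects the relative standard uncertainties of the measurement-model
#' inputs as dimensionless fractions. Supply either `u_rel_Ca` or the pair
#' (`u_rel_A`, `u_rel_Vliq`) — never both, which would double count the
#' concentration uncertainty. The clock-offset uncertainty may be given
#' either relatively (`u_rel_offset`, relative to the time difference) or as
#' an absolute standard uncertainty (`u_offset`, an [uq()] in a time unit or
#' seconds); the absolute form is the natural one when the two clocks are
#' synchronized to within a known tolerance, and is the only valid form when
#' the time offset is zero.
#'
#' @param u_rel_R,u_rel_V Relative uncertainties of VOI counts and VOI
#'   volume (fractions).
#' @param u_rel_Ca Relative uncertainty of the activity concentration, or
#'   `NULL` when the pair below is used.
#' @param u_rel_A,u_rel_Vliq Relative uncertainties of activity and solution
#'   volume, or `NULL`.
#' @param u_rel_offset Relative uncertainty of the time offset, or `NULL`.
#' @param u_offset Absolute clock-offset standard uncertainty ([uq()] or
#'   seconds), or `NULL`.
#' @param u_rel_T_half,u_rel_T_acq Relative uncertainties of half-life and
#'   acquisition duration (fractions).
#' @return An object of class `"component_uncertainties"`.
#' @examples
#' # the baseline clinical component set
#' component_uncertainties(
#'   u_rel_R = 0.04, u_rel_V = 0.02, u_rel_Ca = 0.02,
#'   u_offset = 0, u_rel_T_half = 5e-4, u_rel_T_acq = 1e-3
#' )
#' @export
component_uncertainties <- function(u_rel_R = 0, u_rel_V = 0,
                                    u_rel_Ca = NULL,
                                    u_rel_A = NULL, u_rel_Vliq = NULL,
                                    u_rel_offset = NULL, u_offset = NULL,
                                    u_rel_T_half = 0, u_rel_T_acq = 0) {
  has_ca <- !is.null(u_rel_Ca)
  has_pair <- !is.null(u_rel_A) || !is.null(u_rel_Vliq)
  if (has_ca && has_pair) {
    stop(
      "supply either u_rel_Ca or the pair (u_rel_A, u_rel_Vliq), not both",
      call. = FALSE
    )
  }
  if (has_pair && (is.null(u_rel_A) || is.null(u_rel_Vliq))) {
    stop("supply both u_rel_A and u_rel_Vliq", call. = FALSE)
  }
  if (!has_ca && !has_pair) u_rel_Ca <- 0
  if (!is.null(u_rel_offset) && !is.null(u_offset)) {
    stop("supply u_rel_offset or u_offset, not both", call. = FALSE)
  }
  if (!is.null(u_offset)) {
    u_offset <- if (is_uq(u_offset)) uq_seconds(u_offset)$value else u_offset
    stopifnot(is.numeric(u_offset), length(u_offset) == 1L)
  }
  vals <- c(
    u_rel_R, u_rel_V, u_rel_Ca, u_rel_A, u_rel_Vliq,
    u_rel_offset, u_offset, u_rel_T_half, u_rel_T_acq
  )
  if (any(vals < 0)) {
    stop("uncertainties must be non-negative", call. = FALSE)
  }
  structure(
    list(
      r = u_rel_R, v = u_rel_V, ca = u_rel_Ca,
      a = u_rel_A, vliq = u_rel_Vliq,
      offset_rel = u_rel_offset, offset_abs = u_offset,
      t_half = u_rel_T_half, t_acq = u_rel_T_acq
    ),
    class = "component_uncertainties"
  )
}

#' Extract component uncertainties from a scenario
#'
#' Reads each input's relative uncertainty off its [uq()] carrier. The clock
#' offset is taken in absolute form (the offset's own standard uncertainty in
#' seconds), so a zero time difference is handled without a division by zero.
#'
#' @param scenario A [calibration_scenario()].
#' @return A [component_uncertainties()] object.
#' @export
scenario_uncertainties <- function(scenario) {
  stopifnot(inherits(scenario, "calibration_scenario"))
  if (!is.null(scenario$A)) {
    component_uncertainties(
      u_rel_R = uq_rel(scenario$R),
      u_rel_V = uq_rel(scenario$V),
      u_rel_A = uq_rel(scenario$A),
      u_rel_Vliq = uq_rel(scenario$V_liq),
      u_offset = uq_seconds(scenario$time_offset)$u,
      u_rel_T_half = uq_rel(scenario$T_half),
      u_rel_T_acq = uq_rel(scenario$T_acq)
    )
  } else {
    component_uncertainties(
      u_rel_R = uq_rel(scenario$R),
      u_rel_V = uq_rel(scenario$V),
      u_rel_Ca = uq_rel(scenario$C_a),
      u_offset = uq_seconds(scenario$time_offset)$u,
      u_rel_T_half = uq_rel(scenario$T_half),
      u_rel_T_acq = uq_rel(scenario$T_acq)
    )
  }
}

#' Relative sensitivity coefficients of the factorized model
#'
#' The dimensionless factors multiplying each grouped input's relative
#' uncertainty in the variance budget, obtained by differentiating the log
#' of the factorized calibration-factor model with respect to the log of
#' each input:
#' `c1 = 1`, `c2 = alpha`,
#' `c3 = (1 + alpha) - beta * exp(-beta) / (1 - exp(-beta))`,
#' `c4 = -beta * exp(-beta) / (1 - exp(-beta))`.
#' As `beta -> 0`, `c3 -> alpha` and `c4 -> -1`, which is the simplified
#' short-acquisition budget. `c4` is reported signed; only its square enters
#' a budget.
#'
#' @param alpha Dimensionless decay offset `(T0 - T_cal) * ln(2) / T_half`
#'   (either sign).
#' @param beta Dimensionless acquisition duration `T_acq * ln(2) / T_half`,
#'   positive.
#' @return A tibble with columns `c1`, `c2`, `c3`, `c4` (vectorized over
#'   `alpha`, `beta`).
#' @examples
#' sensitivity_coefficients(alpha = 1, beta = 0.1)
#' @export
sensitivity_coefficients <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (any(beta <= 0)) stop("beta must be positive", call. = FALSE)
  # beta * e^-beta / (1 - e^-beta), stable for small beta via expm1
  g <- beta * exp(-beta) / (-expm1(-beta))
  tibble::tibble(
    c1 = rep(1, length.out = max(length(alpha), length(beta))),
    c2 = alpha + 0 * beta,
    c3 = (1 + alpha) - g,
    c4 = -g
  )
}

# Resolve the X2 (clock-offset) variance contribution. Preference order:
# absolute u_offset through the offset-cancellation identity, else
# alpha^2 * u_rel_offset^2.
.offset_contribution <- function(u, alpha, t_half_s) {
  if (!is.null(u$offset_abs)) {
    clock_offset_contribution(u$offset_abs, t_half_s)
  } else if (!is.null(u$offset_rel)) {
    alpha^2 * u$offset_rel^2
  } else {
    0
  }
}

.new_budget <- function(method, terms, components, warn_regime = FALSE) {
  total <- sum(components$contribution)
  components$share_pct <- if (total > 0) {
    100 * components$contribution / total
  } else {
    rep(0, nrow(components))
  }
  structure(
    list(
      method = method,
      s_rc = calibration_factor(terms),
      alpha = terms$alpha,
      beta = terms$beta,
      components = components,
      u_rel_combined = sqrt(total),
      sensitivity = sensitivity_coefficients(terms$alpha, terms$beta),
      regime_warning = warn_regime
    ),
    class = "uncertainty_budget"
  )
}

# Rows shared by every method: the product-form X1 parts, each with unit
# coefficient.
.x1_rows <- function(u) {
  if (!is.null(u$a)) {
    tibble::tibble(
      component = c("R", "V", "A", "V_liq"),
      u_rel = c(u$r, u$v, u$a, u$vliq),
      coefficient = 1
    )
  } else {
    tibble::tibble(
      component = c("R", "V", "C_a"),
      u_rel = c(u$r, u$v, u$ca),
      coefficient = 1
    )
  }
}

.time_rows <- function(u, alpha, t_half_s, c3, c4) {
  off <- .offset_contribution(u, alpha, t_half_s)
  tibble::tibble(
    component = c("time_offset", "half_life", "acq_duration"),
    u_rel = c(
      if (!is.null(u$offset_rel)) u$offset_rel else NA_real_,
      u$t_half, u$t_acq
    ),
    coefficient = c(abs(alpha), abs(c3), abs(c4)),
    contribution = c(off, c3^2 * u$t_half^2, c4^2 * u$t_acq^2)
  )
}

#' Combined relative uncertainty, exact law-of-propagation form
#'
#' Assembles the full first-order variance budget for the calibration
#' factor: the quadrature sum of the product-form components (counts, VOI
#' volume, concentration or activity + solution volume), the clock-offset
#' term, and the half-life and acquisition-duration terms weighted by the
#' exact sensitivity coefficients [sensitivity_coefficients()]. Valid at any
#' `beta`.
#'
#' @param terms One-row tibble from [derive_terms()], or a
#'   [calibration_scenario()].
#' @param u A [component_uncertainties()] object; defaults to the
#'   uncertainties carried by the scenario when `terms` is a scenario.
#' @return An `uncertainty_budget` object; see [tidy.uncertainty_budget()]
#'   and [glance.uncertainty_budget()] for tabular views.
#' @examples
#' sc <- calibration_scenario(
#'   R = uq(1e6, 4e4, "counts"), V = uq(100, 2, "mL"),
#'   C_a = uq(1000, 20, "Bq/mL"),
#'   time_offset = uq(0, 1, "min"), nuclide = "Tc-99m",
#'   T_acq = uq(60, 0.06, "s")
#' )
#' combined_exact(sc)
#' @export
combined_exact <- function(terms, u = NULL) {
  prep <- .prep_terms(terms, u)
  terms <- prep$terms
  u <- prep$u
  sens <- sensitivity_coefficients(terms$alpha, terms$beta)
  x1 <- dplyr::mutate(.x1_rows(u), contribution = .data$u_rel^2)
  tr <- .time_rows(u, terms$alpha, log(2) / terms$X3, sens$c3, sens$c4)
  .new_budget("exact", terms, dplyr::bind_rows(x1, tr))
}

#' Combined relative uncertainty, simplified short-acquisition form
#'
#' The budget obtained by taking the short-acquisition limit `beta -> 0`
#' of the exact sensitivity coefficients: the half-life term is weighted by
#' `alpha^2` and the acquisition-duration term by 1. Appropriate whenever
#' the acquisition is much shorter than the half-life, which holds for
#' essentially all clinical protocols (10-30 min acquisitions against
#' half-lives of hours to days). A regime warning is attached when
#' `beta > 0.1`, where the dropped `beta`-dependence of the
#' acquisition-duration coefficient reaches the half-percent level.
#'
#' @inheritParams combined_exact
#' @return An `uncertainty_budget` object with `method = "simplified"`.
#' @export
combined_simplified <- function(terms, u = NULL) {
  prep <- .prep_terms(terms, u)
  terms <- prep$terms
  u <- prep$u
  warn <- terms$beta > 0.1
  if (warn) {
    rlang::warn(
      sprintf(
        "beta = %.3g > 0.1: the short-acquisition approximation degrades; use combined_exact()",
        terms$beta
      ),
      class = "calibudget_regime_warning"
    )
  }
  x1 <- dplyr::mutate(.x1_rows(u), contribution = .data$u_rel^2)
  tr <- .time_rows(u, terms$alpha, log(2) / terms$X3,
    c3 = terms$alpha, c4 = -1
  )
  .new_budget("simplified", terms, dplyr::bind_rows(x1, tr), warn_regime = warn)
}

#' Combined relative uncertainty, practical clinical formula
#'
#' The closed formula a clinic can evaluate directly from logged quantities:
#' quadrature sum of the counts, VOI-volume, activity and solution-volume
#' relative uncertainties, plus
#' `((T0 - T_cal) * ln(2) / T_half)^2 * (u_rel^2(offset) + u_rel^2(T_half))`,
#' plus the acquisition-duration term. Algebraically identical to
#' [combined_simplified()] with the concentration term expanded into its
#' activity and solution-volume parts.
#'
#' @param scenario A [calibration_scenario()].
#' @param u A [component_uncertainties()]; defaults to
#'   [scenario_uncertainties()].
#' @return An `uncertainty_budget` object with `method = "practical"`.
#' @export
combined_practical <- function(scenario, u = NULL) {
  stopifnot(inherits(scenario, "calibration_scenario"))
  if (is.null(u)) u <- scenario_uncertainties(scenario)
  terms <- derive_terms(scenario)
  if (terms$beta > 0.1) {
    rlang::warn(
      sprintf(
        "beta = %.3g > 0.1: the short-acquisition approximation degrades; use combined_exact()",
        terms$beta
      ),
      class = "calibudget_regime_warning"
    )
  }
  x1 <- dplyr::mutate(.x1_rows(u), contribution = .data$u_rel^2)
  tr <- .time_rows(u, terms$alpha, log(2) / terms$X3,
    c3 = terms$alpha, c4 = -1
  )
  .new_budget(
    "practical", terms, dplyr::bind_rows(x1, tr),
    warn_regime = terms$beta > 0.1
  )
}

.prep_terms <- function(terms, u) {
  if (inherits(terms, "calibration_scenario")) {
    if (is.null(u)) u <- scenario_uncertainties(terms)
    terms <- derive_terms(terms)
  }
  stopifnot(is.data.frame(terms), nrow(terms) == 1L)
  if (is.null(u)) {
    stop("supply component uncertainties when passing derived terms", call. = FALSE)
  }
  stopifnot(inherits(u, "component_uncertainties"))
  list(terms = terms, u = u)
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf(
    "<uncertainty_budget: %s>  S_rc = %.6g, alpha = %.4g, beta = %.4g\n",
    x$method, x$s_rc, x$alpha, x$beta
  ))
  df <- x$components
  df$u_rel_pct <- signif(100 * df$u_rel, 3)
  df$contribution_pct2 <- signif(1e4 * df$contribution, 3)
  df$share_pct <- signif(df$share_pct, 3)
  print(as.data.frame(df[, c(
    "component", "u_rel_pct", "coefficient",
    "contribution_pct2", "share_pct"
  )]), row.names = FALSE)
  cat(sprintf(
    "combined u_rel(S_rc) = %s%%%s\n",
    signif(100 * x$u_rel_combined, 4),
    if (isTRUE(x$regime_warning)) "  [beta > 0.1: regime warning]" else ""
  ))
  invisible(x)
}
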