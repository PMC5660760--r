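#' Describe one calibration scenario
#'
#' Bundles the inputs of the decay-corrected calibration-factor measurement
#' model: summed VOI counts `R`, VOI volume `V`, activity concentration `C_a`
#' (or activity `A` plus solution volume `V_liq`), the time offset between
#' acquisition start and activity reference time, the radionuclide half-life
#' and the acquisition duration. Each input carries its own standard
#' uncertainty as an [uq()] object.
#'
#' Exactly one of `C_a` or the pair (`A`, `V_liq`) must be supplied; when the
#' pair is given the concentration `C_a = A / V_liq` and its relative
#' uncertainty (quadrature sum of the two parts) are derived. The time offset
#' is the difference acquisition start minus activity reference time and may
#' have either sign: a positive offset decay-corrects backwards to the
#' reference time, a negative one forwards.
#'
#' @param R Summed counts over the VOI; [uq()] with unit `"counts"` or a
#'   bare number.
#' @param V VOI volume, [uq()] in `"mL"`.
#' @param C_a Activity concentration, [uq()] in `"Bq/mL"`, or `NULL`.
#' @param A Activity, [uq()] in `"Bq"`, or `NULL`.
#' @param V_liq Volume of the solution the activity is dispersed in, [uq()]
#'   in `"mL"`, or `NULL`.
#' @param time_offset Acquisition start time minus activity reference time,
#'   [uq()] in a time unit. Its standard uncertainty is the clock-offset
#'   uncertainty.
#' @param T_half Radionuclide half-life, [uq()] in a time unit, or `NULL` if
#'   `nuclide` is given.
#' @param nuclide Nuclide name resolved through [nuclide_registry()] (e.g.
#'   `"Tc-99m"`); fills `T_half` from the registry.
#' @param T_acq Acquisition duration, [uq()] in a time unit, positive.
#' @return An object of class `"calibration_scenario"`.
#' @examples
#' sc <- calibration_scenario(
#'   R = uq(1e6, 4e4, "counts"),
#'   V = uq(100, 2, "mL"),
#'   C_a = uq(1000, 20, "Bq/mL"),
#'   time_offset = uq(6.0067, 5 / 60, "h"),
#'   nuclide = "Tc-99m",
#'   T_acq = uq(60, 0.06, "s")
#' )
#' calibration_factor(sc)
#' @export
calibration_scenario <- function(R, V, C_a = NULL, A = NULL, V_liq = NULL,
                                 time_offset, T_half = NULL, nuclide = NULL,
                                 T_acq) {
  as_uq <- function(x, unit, what) {
    if (is_uq(x)) {
      return(x)
    }
    if (is.numeric(x) && length(x) == 1L) {
      return(uq(x, 0, unit))
    }
    stop(what, " must be an uq() object or a number", call. = FALSE)
  }
  R <- as_uq(R, "counts", "R")
  V <- as_uq(V, "mL", "V")
  time_offset <- as_uq(time_offset, "s", "time_offset")
  T_acq <- as_uq(T_acq, "s", "T_acq")

  has_ca <- !is.null(C_a)
  has_pair <- !is.null(A) || !is.null(V_liq)
  if (has_ca && has_pair) {
    stop(
      "supply either C_a or the pair (A, V_liq), not both ",
      "(would double count the concentration uncertainty)",
      call. = FALSE
    )
  }
  if (!has_ca && !(!is.null(A) && !is.null(V_liq))) {
    stop("supply C_a, or both A and V_liq", call. = FALSE)
  }
  if (has_pair) {
    A <- as_uq(A, "Bq", "A")
    V_liq <- as_uq(V_liq, "mL", "V_liq")
    if (A$value <= 0 || V_liq$value <= 0) {
      stop("A and V_liq must be positive", call. = FALSE)
    }
    ca_value <- A$value / V_liq$value
    ca_rel <- concentration_uncertainty(uq_rel(A), uq_rel(V_liq))
    C_a <- uq(ca_value, ca_rel * ca_value, "Bq/mL")
  } else {
    if (!is_uq(C_a)) C_a <- as_uq(C_a, "Bq/mL", "C_a")
  }

  if (is.null(T_half)) {
    if (is.null(nuclide)) {
      stop("supply T_half or a nuclide name", call. = FALSE)
    }
    T_half <- nuclide_registry(nuclide)$half_life
  } else {
    T_half <- as_uq(T_half, "s", "T_half")
  }

  for (nm in c("R", "V", "C_a", "T_half", "T_acq")) {
    q <- get(nm)
    if (q$value <= 0) {
      stop(nm, " must be positive, got ", q$value, call. = FALSE)
    }
  }
  time_like <- function(q, what) {
    if (is.na(q$unit) || !q$unit %in% names(.time_units)) {
      stop(what, " must carry a time unit (s/min/h/d)", call. = FALSE)
    }
  }
  time_like(time_offset, "time_offset")
  time_like(T_half, "T_half")
  time_like(T_acq, "T_acq")

  structure(
    list(
      R = R, V = V, C_a = C_a, A = A, V_liq = V_liq,
      time_offset = time_offset, T_half = T_half, T_acq = T_acq,
      nuclide = nuclide
    ),
    class = "calibration_scenario"
  )
}

#' @export
print.calibration_scenario <- function(x, ...) {
  cat("<calibration_scenario>\n")
  cat("  R          ", format_parenthetic(x$R), "\n")
  cat("  V          ", format_parenthetic(x$V), "\n")
  cat("  C_a        ", format_parenthetic(x$C_a), "\n")
  cat("  offset     ", format_parenthetic(x$time_offset), "\n")
  cat("  T_half     ", format_parenthetic(x$T_half), "\n")
  cat("  T_acq      ", format_parenthetic(x$T_acq), "\n")
  invisible(x)
}

#' Derived terms of the factorized measurement model
#'
#' Reduces a scenario to the four independent grouped inputs and the two
#' dimensionless decay parameters, with all times in seconds:
#' \describe{
#'   \item{X1}{`R / (V * C_a)`, the count-to-concentration ratio.}
#'   \item{X2}{the time offset `T0 - T_cal` (either sign).}
#'   \item{X3}{the decay constant `ln(2) / T_half` (1/s).}
#'   \item{X4}{the acquisition duration `T_acq` (s).}
#'   \item{alpha}{`X2 * X3`, elapsed time in units of half-lives times ln 2.}
#'   \item{beta}{`X3 * X4`, acquisition duration in the same units; always
#'     positive and typically much less than 1 in clinical practice.}
#' }
#'
#' @param scenario A [calibration_scenario()].
#' @return A one-row tibble with columns `X1`, `X2`, `X3`, `X4`, `alpha`,
#'   `beta`.
#' @export
derive_terms <- function(scenario) {
  stopifnot(inherits(scenario, "calibration_scenario"))
  x2 <- uq_seconds(scenario$time_offset)$value
  th <- uq_seconds(scenario$T_half)$value
  x4 <- uq_seconds(scenario$T_acq)$value
  x3 <- log(2) / th
  tibble::tibble(
    X1 = scenario$R$value / (scenario$V$value * scenario$C_a$value),
    X2 = x2,
    X3 = x3,
    X4 = x4,
    alpha = x2 * x3,
    beta = x3 * x4
  )
}

#' Decay-corrected calibration factor
#'
#' Evaluates the measurement model
#' `S_rc = R / (V * C_a) * exp(alpha) * X3 / (1 - exp(-beta))`,
#' the count-rate-per-concentration calibration factor decay-corrected to the
#' activity reference time. The denominator is computed with `expm1` so that
#' short acquisitions (`beta` down to 1e-8 and below) do not lose precision;
#' as `beta -> 0` the factor converges to `X1 * exp(alpha) / T_acq`.
#'
#' @param x A [calibration_scenario()] or a one-row tibble of derived terms
#'   from [derive_terms()].
#' @return The calibration factor (1/s per unit concentration-volume ratio).
#' @export
calibration_factor <- function(x) {
  if (inherits(x, "calibration_scenario")) x <- derive_terms(x)
  stopifnot(is.data.frame(x), all(c("X1", "X3", "alpha", "beta") %in% names(x)))
  if (any(x$beta <= 0)) {
    stop("beta must be positive (zero acquisition duration?)", call. = FALSE)
  }
  x$X1 * exp(x$alpha) * x$X3 / (-expm1(-x$beta))
}
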