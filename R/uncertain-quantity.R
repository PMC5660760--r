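# Units recognised on dimensioned inputs. Internally every time is reduced to
# seconds before any combination; volumes to mL (cm^3 is the same thing).
.time_units <- c(s = 1, min = 60, h = 3600, d = 86400)
.unit_table <- c(
  .time_units,
  mL = 1, `cm^3` = 1, cm3 = 1,
  counts = 1, Bq = 1, `Bq/mL` = 1, `Bq/cm^3` = 1
)

#' Create an uncertain quantity
#'
#' The universal carrier for model inputs: a value with an absolute standard
#' uncertainty and a unit tag. Relative uncertainty is `u / |value|` and is
#' only defined for non-zero values.
#'
#' @param value Numeric scalar, the best estimate.
#' @param u Absolute standard uncertainty in the same unit as `value`.
#'   Must be non-negative.
#' @param unit Unit tag. Recognised: time units `"s"`, `"min"`, `"h"`, `"d"`;
#'   `"counts"`; volume `"mL"`/`"cm^3"`; activity `"Bq"`; concentration
#'   `"Bq/mL"`. Use `NA` for dimensionless quantities.
#' @return An object of class `"uq"`: a list with elements `value`, `u`,
#'   `unit`.
#' @examples
#' uq(6.0067, 0.0010, "h")
#' uq_rel(uq(6.0067, 0.0010, "h")) # ~ 1.66e-4
#' @export
uq <- function(value, u = 0, unit = NA_character_) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u))
  if (u < 0) {
    stop("standard uncertainty must be non-negative, got ", u, call. = FALSE)
  }
  if (!is.na(unit) && !unit %in% names(.unit_table)) {
    stop(
      "unknown unit '", unit, "'; recognised units: ",
      paste(names(.unit_table), collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(value = value, u = u, unit = unit), class = "uq")
}

#' @export
print.uq <- function(x, ...) {
  cat(
    format_parenthetic(x),
    if (x$u > 0) sprintf("  [u_rel = %.4g%%]", 100 * uq_rel(x)) else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

is_uq <- function(x) inherits(x, "uq")

#' Relative standard uncertainty of an uncertain quantity
#'
#' @param x An [uq()] object.
#' @return `u / |value|` as a dimensionless fraction.
#' @export
uq_rel <- function(x) {
  stopifnot(is_uq(x))
  if (x$value == 0) {
    stop("relative uncertainty undefined for zero value", call. = FALSE)
  }
  x$u / abs(x$value)
}

#' Convert an uncertain quantity to another unit
#'
#' Both the value and the standard uncertainty are scaled by the exact
#' conversion factor, so relative uncertainty is unchanged.
#'
#' @param x An [uq()] object with a convertible unit.
#' @param unit Target unit tag.
#' @return An [uq()] in the target unit.
#' @export
uq_convert <- function(x, unit) {
  stopifnot(is_uq(x))
  if (is.na(x$unit) || is.na(unit)) {
    stop("cannot convert a dimensionless quantity", call. = FALSE)
  }
  time_from <- x$unit %in% names(.time_units)
  time_to <- unit %in% names(.time_units)
  if (time_from != time_to) {
    stop(
      "incompatible units: '", x$unit, "' -> '", unit, "'",
      call. = FALSE
    )
  }
  if (!unit %in% names(.unit_table)) {
    stop("unknown unit '", unit, "'", call. = FALSE)
  }
  f <- .unit_table[[x$unit]] / .unit_table[[unit]]
  uq(x$value * f, x$u * f, unit)
}

# Time value in seconds; non-time units pass through unchanged.
uq_seconds <- function(x) {
  stopifnot(is_uq(x))
  if (!is.na(x$unit) && x$unit %in% names(.time_units)) {
    uq_convert(x, "s")
  } else {
    x
  }
}

#' Parse concise parenthetic uncertainty notation
#'
#' Nuclear-data tables quote values like `"1.82890(23) h"`, where the digits
#' in parentheses give the standard uncertainty in units of the last displayed
#' decimal place: here 1.82890 h with u = 0.00023 h.
#'
#' @param text A string of the form `<digits>[.<digits>](<digits>) [unit]`.
#' @return An [uq()] object.
#' @examples
#' parse_parenthetic("1.82890(23) h")
#' parse_parenthetic("11.43(3) d")
#' @export
parse_parenthetic <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(
    text,
    regexec(
      "^\\s*([0-9]+(?:\\.[0-9]+)?)\\(([0-9]+)\\)(?:\\s+(\\S+))?\\s*$",
      text
    )
  )[[1]]
  if (length(m) == 0L) {
    stop(
      "cannot parse '", text,
      "' as concise parenthetic notation (expected e.g. \"6.0067(10) h\")",
      call. = FALSE
    )
  }
  value_str <- m[2]
  unc_digits <- m[3]
  unit <- if (m[4] == "") NA_character_ else m[4]
  n_dec <- if (grepl("\\.", value_str)) {
    nchar(sub("^[0-9]+\\.", "", value_str))
  } else {
    0L
  }
  u <- as.numeric(unc_digits) * 10^(-n_dec)
  uq(as.numeric(value_str), u, unit)
}

#' Format an uncertain quantity in concise parenthetic notation
#'
#' Inverse of [parse_parenthetic()] whenever the uncertainty is an integer
#' multiple of the value's last decimal place; `parse_parenthetic(
#' format_parenthetic(x))` then reproduces `x` exactly.
#'
#' @param x An [uq()] object.
#' @param digits Number of decimal places to display; defaults to the
#'   smallest number that represents `u` exactly (up to 12).
#' @return A string.
#' @export
format_parenthetic <- function(x, digits = NULL) {
  stopifnot(is_uq(x))
  if (is.null(digits)) {
    digits <- 0L
    while (digits < 12L &&
      abs(x$u * 10^digits - round(x$u * 10^digits)) > 1e-9 * max(1, x$u * 10^digits)) {
      digits <- digits + 1L
    }
  }
  sprintf(
    "%.*f(%d)%s",
    digits, x$value, as.integer(round(x$u * 10^digits)),
    if (is.na(x$unit)) "" else paste0(" ", x$unit)
  )
}

#' Convert an expanded uncertainty to a standard uncertainty
#'
#' Calibration guidance quotes expanded uncertainties `U = k * u` at a
#' coverage factor `k` (k = 2 corresponds to ~95% coverage for a normal
#' distribution); the standard uncertainty is recovered as `U / k`.
#'
#' @param U Expanded uncertainty (any unit, commonly percent).
#' @param k Coverage factor, positive.
#' @return `U / k` in the same unit as `U`.
#' @examples
#' expanded_to_standard(5, k = 2) # 2.5
#' @export
expanded_to_standard <- function(U, k = 2) {
  stopifnot(is.numeric(U), is.numeric(k))
  if (any(U < 0)) stop("expanded uncertainty must be non-negative", call. = FALSE)
  if (any(k <= 0)) stop("coverage factor must be positive", call. = FALSE)
  U / k
}
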