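# Sub-models that turn raw clinical/metrological information into the
# relative standard uncertainties entering the budget.

# Normalize "18F", "f18", "F-18", "99mTc", "TC99M" ... to the registry key.
.normalize_nuclide <- function(name) {
  s <- toupper(gsub("[^A-Za-z0-9]", "", name))
  # split into element letters and mass-number (+ optional metastable m)
  m <- regmatches(s, regexec("^([A-Z]+)([0-9]+M?)$", s))[[1]]
  if (length(m) == 0L) {
    m <- regmatches(s, regexec("^([0-9]+M?)([A-Z]+)$", s))[[1]]
    if (length(m) == 0L) {
      return(NA_character_)
    }
    elem <- m[3]
    mass <- m[2]
  } else {
    elem <- m[2]
    mass <- m[3]
  }
  # registry spells Tc-99m with the isomer flag lowercase after the mass
  elem <- paste0(
    substr(elem, 1, 1),
    tolower(substr(elem, 2, nchar(elem)))
  )
  paste0(elem, "-", tolower(mass))
}

.registry_cache <- new.env(parent = emptyenv())

#' Load the radionuclide half-life registry
#'
#' Reads a delimited registry of adopted half-life values in concise
#' parenthetic notation. The packaged registry covers the nuclides most used
#' in quantitative imaging and radionuclide therapy (F-18, Tc-99m, I-131,
#' Lu-177, Y-90, Ra-223); a site can override it with its own file of the
#' same shape. Relative half-life uncertainties are always recomputed from
#' the parsed value and uncertainty, never stored.
#'
#' @param path Optional path to a tab-separated registry file with columns
#'   `nuclide`, `half_life` (concise notation with unit), `use`.
#' @return A tibble with columns `nuclide`, `half_life_value`, `half_life_u`,
#'   `unit`, `u_rel_pct` (percent), `use`, and a list-column `half_life` of
#'   [uq()] objects.
#' @export
load_nuclide_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_cache$default)) {
      return(.registry_cache$default)
    }
    path <- system.file("extdata", "nuclide_halflives.tsv",
      package = "calibudget", mustWork = TRUE
    )
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nuclide", "half_life", "use") %in% names(raw)))
  hl <- purrr::map(raw$half_life, parse_parenthetic)
  out <- tibble::tibble(
    nuclide = raw$nuclide,
    half_life_value = purrr::map_dbl(hl, "value"),
    half_life_u = purrr::map_dbl(hl, "u"),
    unit = purrr::map_chr(hl, "unit"),
    u_rel_pct = 100 * purrr::map_dbl(hl, uq_rel),
    use = raw$use,
    half_life = hl
  )
  if (cache) .registry_cache$default <- out
  out
}

#' Look up a radionuclide half-life record
#'
#' @param name Nuclide name; spellings like `"Lu-177"`, `"177Lu"`, `"lu177"`
#'   are accepted case-insensitively.
#' @param registry Registry tibble from [load_nuclide_registry()]; defaults
#'   to the packaged registry.
#' @return A list with `nuclide`, `half_life` ([uq()]), `u_rel_pct`
#'   (recomputed percent relative uncertainty), `use`.
#' @examples
#' nuclide_registry("Lu-177")$half_life # 6.647(4) d
#' @export
nuclide_registry <- function(name, registry = load_nuclide_registry()) {
  key <- .normalize_nuclide(name)
  i <- match(key, registry$nuclide)
  if (is.na(i)) {
    stop(
      "unknown nuclide '", name, "'; known: ",
      paste(registry$nuclide, collapse = ", "),
      call. = FALSE
    )
  }
  list(
    nuclide = registry$nuclide[i],
    half_life = registry$half_life[[i]],
    u_rel_pct = registry$u_rel_pct[i],
    use = registry$use[i]
  )
}

#' Voxelization uncertainty of a VOI volume
#'
#' Discretizing a continuous VOI onto the voxel grid makes the delineated
#' boundary uncertain by about one voxel in diameter, so the standard
#' uncertainty of the mean radius is half a voxel side. Since any VOI with a
#' defined mean radius satisfies `V = C * r^3` for some constant, the shape
#' constant cancels and the relative volume uncertainty is exactly three
#' times the relative radius uncertainty.
#'
#' @param mean_radius Mean VOI radius, positive (any length unit).
#' @param voxel_side Voxel side, same unit, non-negative.
#' @return A one-row tibble with `u_r` (same unit), `u_rel_r`, `u_rel_V`
#'   (fractions).
#' @examples
#' voxelization_volume_uncertainty(150, 3) # u_rel_V = 0.03
#' @export
voxelization_volume_uncertainty <- function(mean_radius, voxel_side) {
  stopifnot(is.numeric(mean_radius), is.numeric(voxel_side))
  if (any(mean_radius <= 0)) stop("mean_radius must be positive", call. = FALSE)
  if (any(voxel_side < 0)) stop("voxel_side must be non-negative", call. = FALSE)
  u_r <- voxel_side / 2
  u_rel_r <- u_r / mean_radius
  tibble::tibble(u_r = u_r, u_rel_r = u_rel_r, u_rel_V = 3 * u_rel_r)
}

#' Clock-offset contribution to the budget
#'
#' The variance contribution of an offset between the clocks defining the
#' acquisition start and the activity reference time is
#' `(u_offset * ln(2) / T_half)^2`. The absolute time difference between the
#' two events cancels out of the product `alpha^2 * u_rel^2(X2)`, so the
#' contribution depends only on the clock-offset uncertainty and the
#' half-life — not on how far apart the two times are.
#'
#' @param u_offset Standard uncertainty of the clock offset, [uq()] in a
#'   time unit or a number of seconds. Non-negative.
#' @param T_half Half-life, [uq()] in a time unit or a number of seconds.
#' @return Squared relative contribution (dimensionless variance fraction).
#' @examples
#' sqrt(clock_offset_contribution(uq(5, unit = "min"), uq(6.0067, unit = "h")))
#' @export
clock_offset_contribution <- function(u_offset, T_half) {
  to_s <- function(x, what) {
    if (is_uq(x)) {
      return(uq_seconds(x)$value)
    }
    if (is.numeric(x)) {
      return(x)
    }
    stop(what, " must be an uq() or a number of seconds", call. = FALSE)
  }
  uo <- to_s(u_offset, "u_offset")
  th <- to_s(T_half, "T_half")
  if (any(uo < 0)) stop("u_offset must be non-negative", call. = FALSE)
  if (any(th <= 0)) stop("T_half must be positive", call. = FALSE)
  (uo * log(2) / th)^2
}

# AAPM-style accuracy guidance for radionuclide calibrators: expanded
# uncertainties (k = 2) by instrument class and emission class.
.calibrator_table <- tibble::tribble(
  ~instrument_class, ~emission_class, ~expanded_U_pct,
  "field", "photon>100keV", 5,
  "field", "photon<100keV", 10,
  "field", "beta-medium-high", 5,
  "field", "beta-low", 10,
  "secondary-standard", "photon>100keV", 2,
  "secondary-standard", "photon<100keV", 5,
  "secondary-standard", "beta-medium-high", 2,
  "secondary-standard", "beta-low", 5
)

#' Radionuclide-calibrator accuracy guidance
#'
#' Recommended expanded uncertainties (coverage factor k = 2, ~95% coverage)
#' for activity measurements with well-type ionization chambers, by
#' instrument class (clinical field instrument vs secondary-standard /
#' reference calibrator) and emission class.
#'
#' @param instrument_class `"field"` or `"secondary-standard"`
#'   (`"reference"` is accepted as a synonym).
#' @param emission_class One of `"photon>100keV"`, `"photon<100keV"`,
#'   `"beta-medium-high"`, `"beta-low"`.
#' @return A one-row tibble with `instrument_class`, `emission_class`,
#'   `expanded_U_pct`, `k`, and the derived `standard_u_pct = expanded_U / k`.
#' @examples
#' calibrator_guidance("field", "photon>100keV") # 5% (k = 2) -> 2.5% standard
#' @export
calibrator_guidance <- function(instrument_class, emission_class) {
  ic <- tolower(instrument_class)
  if (ic %in% c("reference", "secondary", "secondary-standard")) {
    ic <- "secondary-standard"
  }
  row <- .calibrator_table[
    .calibrator_table$instrument_class == ic &
      tolower(.calibrator_table$emission_class) == tolower(emission_class),
  ]
  if (nrow(row) != 1L) {
    stop(
      "unknown calibrator class ('", instrument_class, "', '",
      emission_class, "'); known instrument classes: field, ",
      "secondary-standard; emission classes: ",
      paste(unique(.calibrator_table$emission_class), collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::mutate(row,
    k = 2,
    standard_u_pct = expanded_to_standard(.data$expanded_U_pct, k = 2)
  )
}

#' Named weighing-uncertainty defaults
#'
#' Typical relative standard uncertainties achievable when the solution
#' volume is determined by weighing: analytic balances for small masses and
#' large-capacity laboratory balances (up to 100-150 kg) for phantom fills.
#' These are guidance magnitudes, not a physics model.
#'
#' @format A named numeric vector of fractional relative uncertainties:
#'   `analytic_balance` (1e-5, i.e. 0.001%), `large_capacity_balance`
#'   (5e-4, i.e. 0.05%).
#' @export
weighing_defaults <- c(
  analytic_balance = 1e-5,
  large_capacity_balance = 5e-4
)

#' Relative uncertainty of an activity concentration
#'
#' For the quotient model `C_a = A / V_liq` the law of propagation of
#' uncertainty in product/quotient form gives the quadrature sum of the two
#' relative uncertainties.
#'
#' @param u_rel_A,u_rel_Vliq Relative standard uncertainties (fractions),
#'   non-negative.
#' @return `sqrt(u_rel_A^2 + u_rel_Vliq^2)`.
#' @examples
#' concentration_uncertainty(0.03, 0.04) # 0.05
#' @export
concentration_uncertainty <- function(u_rel_A, u_rel_Vliq) {
  stopifnot(is.numeric(u_rel_A), is.numeric(u_rel_Vliq))
  if (any(u_rel_A < 0) || any(u_rel_Vliq < 0)) {
    stop("relative uncertainties must be non-negative", call. = FALSE)
  }
  sqrt(u_rel_A^2 + u_rel_Vliq^2)
}
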