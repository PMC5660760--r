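# Configuration ingestion and report serialization.
#
# Config format: YAML. A dimensioned field is a mapping with `value` and
# `unit` plus exactly one uncertainty declaration among
#   u             absolute standard uncertainty, same unit
#   u_rel_pct     relative standard uncertainty in percent
#   expanded_pct  expanded uncertainty in percent, with coverage factor `k`
#   concise       concise parenthetic string, e.g. "6.0067(10) h"
# The half-life block may instead name a registry nuclide.

.validation_error <- function(..., field = NULL) {
  rlang::abort(
    paste0(if (!is.null(field)) paste0("[", field, "] "), ...),
    class = "calibudget_validation_error"
  )
}

# Resolve one config block to an uq(). Unit tags are mandatory on every
# dimensioned field (no defaults: silent unit assumptions are the failure
# mode this tool exists to prevent).
.parse_quantity <- function(block, field) {
  if (is.null(block)) .validation_error("missing", field = field)
  if (is.character(block) && length(block) == 1L) {
    block <- list(concise = block)
  }
  decls <- intersect(names(block), c("u", "u_rel_pct", "expanded_pct", "concise"))
  if (length(decls) > 1L) {
    .validation_error(
      "uncertainty declared more than once (",
      paste(decls, collapse = ", "), ")",
      field = field
    )
  }
  if (identical(decls, "concise")) {
    q <- tryCatch(parse_parenthetic(block$concise), error = function(e) {
      .validation_error(conditionMessage(e), field = field)
    })
    return(q)
  }
  if (is.null(block$value)) .validation_error("missing value", field = field)
  unit <- block$unit
  if (is.null(unit)) .validation_error("missing unit", field = field)
  value <- as.numeric(block$value)
  u <- if (length(decls) == 0L) {
    0
  } else if (decls == "u") {
    as.numeric(block$u)
  } else if (decls == "u_rel_pct") {
    as.numeric(block$u_rel_pct) / 100 * abs(value)
  } else {
    k <- block$k %||% 2
    expanded_to_standard(as.numeric(block$expanded_pct), k) / 100 * abs(value)
  }
  if (is.na(u) || u < 0) .validation_error("negative or missing uncertainty", field = field)
  tryCatch(uq(value, u, unit), error = function(e) {
    .validation_error(conditionMessage(e), field = field)
  })
}

#' Load a calibration run configuration
#'
#' Reads a YAML configuration describing one calibration scenario, the
#' budget method, and optional Monte-Carlo and sweep blocks. Every
#' uncertainty declaration is resolved to an absolute standard uncertainty
#' on ingestion (expanded uncertainties divided by their coverage factor,
#' concise parenthetic strings parsed); half-lives given by nuclide name
#' are filled from the registry.
#'
#' @param path Path to a YAML file.
#' @return A list of class `"run_config"` with elements `scenario`
#'   ([calibration_scenario()]), `method`, `mc` (list or `NULL`), `sweep`
#'   (list or `NULL`), `output` (list or `NULL`).
#' @export
read_calibration_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config not found: ", path), class = "calibudget_io_error")
  }
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scenario
  if (is.null(sc)) .validation_error("missing", field = "scenario")

  has_ca <- !is.null(sc$C_a)
  has_pair <- !is.null(sc$A) || !is.null(sc$V_liq)
  if (has_ca && has_pair) {
    .validation_error(
      "declare C_a or the pair (A, V_liq), not both",
      field = "scenario"
    )
  }

  hl <- sc$half_life
  nuclide <- NULL
  T_half <- NULL
  if (!is.null(hl$nuclide)) {
    extra <- setdiff(names(hl), "nuclide")
    if (length(extra) > 0L) {
      .validation_error(
        "half-life given both by nuclide and explicitly",
        field = "scenario.half_life"
      )
    }
    nuclide <- hl$nuclide
    # fail early on unknown nuclide with a validation error
    tryCatch(nuclide_registry(nuclide), error = function(e) {
      .validation_error(conditionMessage(e), field = "scenario.half_life")
    })
  } else {
    T_half <- .parse_quantity(hl, "scenario.half_life")
  }

  scenario <- tryCatch(
    calibration_scenario(
      R = .parse_quantity(sc$R, "scenario.R"),
      V = .parse_quantity(sc$V, "scenario.V"),
      C_a = if (has_ca) .parse_quantity(sc$C_a, "scenario.C_a"),
      A = if (!has_ca) .parse_quantity(sc$A, "scenario.A"),
      V_liq = if (!has_ca) .parse_quantity(sc$V_liq, "scenario.V_liq"),
      time_offset = .parse_quantity(sc$time_offset, "scenario.time_offset"),
      T_half = T_half, nuclide = nuclide,
      T_acq = .parse_quantity(sc$T_acq, "scenario.T_acq")
    ),
    error = function(e) {
      if (inherits(e, "calibudget_validation_error")) rlang::cnd_signal(e)
      .validation_error(conditionMessage(e), field = "scenario")
    }
  )

  method <- cfg$method %||% "exact"
  if (!method %in% c("exact", "simplified", "practical")) {
    .validation_error(
      "unknown method '", method,
      "' (exact, simplified, practical)",
      field = "method"
    )
  }
  structure(
    list(
      scenario = scenario, method = method,
      mc = cfg$mc, sweep = cfg$sweep, output = cfg$output
    ),
    class = "run_config"
  )
}

#' Compute the budget requested by a run configuration
#'
#' @param config A `run_config` from [read_calibration_config()].
#' @return An `uncertainty_budget`.
#' @export
run_budget <- function(config) {
  stopifnot(inherits(config, "run_config"))
  switch(config$method,
    exact = combined_exact(config$scenario),
    simplified = combined_simplified(config$scenario),
    practical = combined_practical(config$scenario)
  )
}

# GUM display convention: uncertainties to 2 significant digits.
.display2 <- function(x) signif(x, 2)

#' Write a machine-readable budget report
#'
#' Serializes a budget (and an optional Monte-Carlo cross-check) to JSON
#' and/or a delimited component table. Numeric fields are written at full
#' double precision alongside a 2-significant-digit display column;
#' [read_budget_report()] reconstructs the budget bit-exactly from the
#' full-precision channel.
#'
#' @param budget An `uncertainty_budget`.
#' @param path Output path for the JSON report.
#' @param mc Optional `mc_result` to embed.
#' @param table_path Optional path for a tab-separated component table.
#' @return `path`, invisibly.
#' @export
write_budget_report <- function(budget, path, mc = NULL, table_path = NULL) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  comp <- tidy(budget)
  report <- list(
    method = budget$method,
    s_rc = budget$s_rc,
    alpha = budget$alpha,
    beta = budget$beta,
    u_rel_combined = budget$u_rel_combined,
    u_rel_combined_pct_display = .display2(100 * budget$u_rel_combined),
    regime_warning = isTRUE(budget$regime_warning),
    sensitivity = as.list(budget$sensitivity),
    components = lapply(seq_len(nrow(comp)), function(i) {
      list(
        component = comp$component[i],
        u_rel = comp$u_rel[i],
        u_rel_pct_display = .display2(100 * comp$u_rel[i]),
        coefficient = comp$coefficient[i],
        contribution = comp$contribution[i],
        share_pct = comp$share_pct[i]
      )
    })
  )
  if (!is.null(mc)) {
    stopifnot(inherits(mc, "mc_result"))
    report$mc <- list(
      n_draws = mc$n_draws, n_rejected = mc$n_rejected, seed = mc$seed,
      mean_S = mc$mean_S, rel_sd_S = mc$rel_sd_S, se_rel_sd = mc$se_rel_sd,
      distribution = mc$distribution
    )
  }
  ok <- tryCatch(
    {
      # I(17) significant digits is the shortest decimal form guaranteed to
      # round-trip an IEEE double exactly
      jsonlite::write_json(report, path,
        auto_unbox = TRUE, digits = I(17), null = "null", na = "null"
      )
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    rlang::abort(paste0("cannot write report to ", path),
      class = "calibudget_io_error"
    )
  }
  if (!is.null(table_path)) {
    utils::write.table(comp, table_path,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Re-read a budget report
#'
#' Reconstructs an `uncertainty_budget` (and the embedded `mc_result`, if
#' any) from the full-precision fields of a JSON report written by
#' [write_budget_report()].
#'
#' @param path Path to the JSON report.
#' @return A list with elements `budget` and `mc` (`NULL` when absent).
#' @export
read_budget_report <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("report not found: ", path), class = "calibudget_io_error")
  }
  r <- jsonlite::read_json(path)
  comp <- purrr::map_dfr(r$components, function(ci) {
    tibble::tibble(
      component = ci$component,
      u_rel = ci$u_rel %||% NA_real_,
      coefficient = ci$coefficient,
      contribution = ci$contribution,
      share_pct = ci$share_pct
    )
  })
  budget <- structure(
    list(
      method = r$method,
      s_rc = r$s_rc,
      alpha = r$alpha,
      beta = r$beta,
      components = comp,
      u_rel_combined = r$u_rel_combined,
      sensitivity = tibble::as_tibble(r$sensitivity),
      regime_warning = isTRUE(r$regime_warning)
    ),
    class = "uncertainty_budget"
  )
  mc <- NULL
  if (!is.null(r$mc)) {
    mc <- structure(
      list(
        n_draws = r$mc$n_draws, n_rejected = r$mc$n_rejected,
        seed = r$mc$seed, mean_S = r$mc$mean_S,
        rel_sd_S = r$mc$rel_sd_S, se_rel_sd = r$mc$se_rel_sd,
        distribution = r$mc$distribution
      ),
      class = "mc_result"
    )
  }
  list(budget = budget, mc = mc)
}
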