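#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an uncertainty budget
#'
#' One row per uncertainty component with the relative uncertainty, the
#' dimensionless coefficient applied to it, the squared (variance-space)
#' contribution and its percent share of the total variance.
#'
#' @param x An `uncertainty_budget`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `u_rel`, `u_rel_pct`,
#'   `coefficient`, `contribution`, `contribution_pct2`, `share_pct`.
#' @method tidy uncertainty_budget
#' @export
tidy.uncertainty_budget <- function(x, ...) {
  dplyr::mutate(
    x$components,
    u_rel_pct = 100 * .data$u_rel,
    contribution_pct2 = 1e4 * .data$contribution,
    .after = "u_rel"
  )
}

#' One-row summary of an uncertainty budget
#'
#' @param x An `uncertainty_budget`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `s_rc`, `alpha`, `beta`,
#'   `u_rel_combined`, `u_rel_combined_pct`, `n_components`,
#'   `regime_warning`.
#' @method glance uncertainty_budget
#' @export
glance.uncertainty_budget <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    s_rc = x$s_rc,
    alpha = x$alpha,
    beta = x$beta,
    u_rel_combined = x$u_rel_combined,
    u_rel_combined_pct = 100 * x$u_rel_combined,
    n_components = nrow(x$components),
    regime_warning = isTRUE(x$regime_warning)
  )
}

#' Tidy a Monte-Carlo propagation result
#'
#' @param x An `mc_result` from [mc_propagate()].
#' @param ... Unused.
#' @return A one-row tibble: `n_draws`, `n_rejected`, `seed`, `mean_S`,
#'   `rel_sd_S`, `rel_sd_pct`, `se_rel_sd`.
#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws,
    n_rejected = x$n_rejected,
    seed = x$seed,
    mean_S = x$mean_S,
    rel_sd_S = x$rel_sd_S,
    rel_sd_pct = 100 * x$rel_sd_S,
    se_rel_sd = x$se_rel_sd
  )
}
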