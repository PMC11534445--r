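#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into long format
#'
#' @param x A `scav_sim` trajectory.
#' @param fluxes If `TRUE`, include every flux column; otherwise only the
#'   five state biomasses.
#' @param ... Unused.
#' @return A long tibble with `scenario_id`, `time`, `variable`, `value`.
#' @method tidy scav_sim
#' @export
tidy.scav_sim <- function(x, fluxes = FALSE, ...) {
  cols <- if (fluxes) c(state_names, flux_fields) else state_names
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("time", cols)], -"time",
    names_to = "variable", values_to = "value"
  ) |>
    dplyr::mutate(scenario_id = attr(x, "scenario_id") %||% "run",
                  .before = 1L)
}

#' One-row summary of a trajectory
#'
#' @param x A `scav_sim` trajectory.
#' @param window Terminal window for equilibrium means (years), default 50.
#' @param ... Unused.
#' @return A one-row tibble: `scenario_id`, `t_end`, per-state terminal
#'   means (`V_mean`, ...) and amplitudes (`V_amp`, ...).
#' @method glance scav_sim
#' @export
glance.scav_sim <- function(x, window = 50, ...) {
  eq <- equilibrium_summary(x, window)
  out <- c(
    stats::setNames(as.list(eq$mean), paste0(eq$state, "_mean")),
    stats::setNames(as.list(eq$amplitude), paste0(eq$state, "_amp"))
  )
  dplyr::bind_cols(
    tibble::tibble(scenario_id = attr(x, "scenario_id") %||% "run",
                   t_end = max(x$time)),
    tibble::as_tibble(out)
  )
}
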