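runs_long <- function(runs, cols) {
  purrr::map2(runs$label, runs$trajectory, function(lab, traj) {
    d <- tibble::as_tibble(traj)[, c("time", cols)]
    d$label <- lab
    d
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(
      dplyr::select(runs, "label", "boar_present", "wolf_present",
                    "target", "leftover"),
      by = "label"
    ) |>
    dplyr::mutate(
      boar = ifelse(.data$boar_present, "boar present", "boar absent"),
      wolf = ifelse(.data$wolf_present, "wolf present", "wolf absent"),
      target = factor(.data$target),
      leftover = factor(.data$leftover)
    )
}

#' Time-series panel of one state across a scenario grid
#'
#' Biomass of one state over time, faceted by boar and wolf presence,
#' with hunting target as line colour and leftover fraction as line type.
#'
#' @param runs Output of [run_scenarios()] on a grid that carries
#'   presence/target/leftover columns.
#' @param state State to plot, default `"S"` (scavengers).
#' @return A ggplot object.
#' @export
plot_scenario_biomass <- function(runs, state = "S") {
  d <- runs_long(runs, state)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time, y = .data[[state]],
    colour = .data$target, linetype = .data$leftover
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(wolf ~ boar) +
    ggplot2::labs(
      x = "time (years)",
      y = sprintf("%s biomass density (ton/ha)", state),
      colour = "hunting target", linetype = "fraction left"
    ) +
    ggplot2::theme_minimal()
}

#' Scavenger growth-source fraction panel
#'
#' Fraction of scavenger growth coming from vegetation (1 = all
#' vegetation, 0 = all carrion) over time, same faceting and aesthetics
#' as [plot_scenario_biomass()].
#'
#' @inheritParams plot_scenario_biomass
#' @return A ggplot object.
#' @export
plot_growth_sources <- function(runs) {
  frac <- purrr::map2(runs$label, runs$trajectory, function(lab, traj) {
    d <- growth_source_series(traj)
    d$label <- lab
    d
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(
      dplyr::select(runs, "label", "boar_present", "wolf_present",
                    "target", "leftover"),
      by = "label"
    ) |>
    dplyr::mutate(
      boar = ifelse(.data$boar_present, "boar present", "boar absent"),
      wolf = ifelse(.data$wolf_present, "wolf present", "wolf absent"),
      target = factor(.data$target),
      leftover = factor(.data$leftover)
    )
  ggplot2::ggplot(frac, ggplot2::aes(
    x = .data$time, y = .data$veg_growth_fraction,
    colour = .data$target, linetype = .data$leftover
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(wolf ~ boar) +
    ggplot2::labs(
      x = "time (years)",
      y = "vegetation share of scavenger growth",
      colour = "hunting target", linetype = "fraction left"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Deer versus boar carrion composition panel
#'
#' Deer carrion available to scavengers and boar carrion over time, with
#' wolf presence as facets.
#'
#' @inheritParams plot_scenario_biomass
#' @return A ggplot object.
#' @export
plot_carrion_composition <- function(runs) {
  d <- runs_long(runs, c("K_D_avail", "K_B")) |>
    tidyr::pivot_longer(c("K_D_avail", "K_B"),
                        names_to = "carrion", values_to = "flux") |>
    dplyr::mutate(carrion = dplyr::recode(.data$carrion,
                                          K_D_avail = "deer carrion",
                                          K_B = "boar carrion"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time, y = .data$flux,
    colour = .data$target, linetype = .data$leftover
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(carrion ~ wolf) +
    ggplot2::labs(
      x = "time (years)", y = "carrion flux (ton/ha/yr)",
      colour = "hunting target", linetype = "fraction left"
    ) +
    ggplot2::theme_minimal()
}

#' End-state image plot for a factorial sensitivity sweep
#'
#' 2-D tile plot of a state's terminal-window mean against the first two
#' varied parameters, with any further varied parameters as facets.
#'
#' @param sens Output of [factorial_runs()].
#' @param state State column to display, default `"S"`.
#' @return A ggplot object.
#' @export
plot_endstate_image <- function(sens, state = "S") {
  fac_cols <- grep("_factor$", names(sens), value = TRUE)
  if (length(fac_cols) < 2L) {
    stop("need at least two varied parameters for an image plot",
         call. = FALSE)
  }
  p <- ggplot2::ggplot(sens, ggplot2::aes(
    x = factor(.data[[fac_cols[1L]]]),
    y = factor(.data[[fac_cols[2L]]]),
    fill = .data[[state]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = fac_cols[1L], y = fac_cols[2L],
                  fill = sprintf("mean %s", state)) +
    ggplot2::theme_minimal()
  extra <- fac_cols[-(1:2)]
  if (length(extra)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(extra, collapse = "+"))
    ), labeller = ggplot2::label_both)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a single trajectory
#'
#' Faceted time series of all five state biomasses.
#'
#' @param object A `scav_sim` trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scav_sim
#' @export
autoplot.scav_sim <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", state_names)],
    -"time", names_to = "state", values_to = "biomass"
  )
  d$state <- factor(d$state, levels = state_names)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$biomass)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = "biomass density (ton/ha)",
                  title = attr(object, "scenario_id")) +
    ggplot2::theme_minimal()
}
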