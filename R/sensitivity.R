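#' Factorial sensitivity design
#'
#' Defines a full-factorial sweep of parameter multipliers around a base
#' parameter set, run under one scenario.
#'
#' @param varied Character vector of parameter names to vary.
#' @param factors Multipliers applied to every varied parameter;
#'   default `c(0.75, 0.875, 1, 1.125, 1.25)`.
#' @param base_params Baseline [scav_params()].
#' @param scenario A single scenario row (tibble) as produced by
#'   [build_scenario_grid()]; default the full-presence scenario at the
#'   medium hunting regime.
#' @return A list of class `scav_design`.
#' @export
sensitivity_design <- function(varied,
                               factors = c(0.75, 0.875, 1, 1.125, 1.25),
                               base_params = scav_params(),
                               scenario = build_scenario_grid(
                                 targets = 0.5, leftovers = 0.5
                               )[1, ]) {
  base_params <- validate_params(base_params)
  unknown <- setdiff(varied, setdiff(names(base_params), "carrion_dialect"))
  if (length(unknown)) {
    stop("unknown parameter(s) in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  if (nrow(scenario) != 1L) stop("scenario must be a single row", call. = FALSE)
  structure(
    list(varied = varied, factors = factors,
         base_params = base_params, scenario = scenario),
    class = "scav_design"
  )
}

#' Run a full factorial sensitivity sweep
#'
#' Runs one simulation per combination of multipliers (so
#' `length(factors) ^ length(varied)` runs) and summarises each by the
#' terminal-window mean of every state.
#'
#' @param design A [sensitivity_design()].
#' @param settings A [run_settings()] object.
#' @param window Terminal window for end-state means (years), default 50.
#' @param max_runs Guard against combinatorial explosion; designs larger
#'   than this are rejected unless `force = TRUE`. Default 10000.
#' @param force Set `TRUE` to override `max_runs`.
#' @return A tibble with one multiplier column per varied parameter
#'   (named `<param>_factor`) and window-mean columns `V`, `D`, `B`,
#'   `S`, `W`.
#' @export
factorial_runs <- function(design, settings = run_settings(), window = 50,
                           max_runs = 10000, force = FALSE) {
  stopifnot(inherits(design, "scav_design"))
  n_runs <- length(design$factors) ^ length(design$varied)
  if (n_runs > max_runs && !force) {
    stop(sprintf("design implies %d runs (> %d); use force = TRUE",
                 n_runs, max_runs), call. = FALSE)
  }
  combos <- tidyr::expand_grid(
    !!!stats::setNames(
      rep(list(design$factors), length(design$varied)),
      paste0(design$varied, "_factor")
    )
  )
  means <- purrr::map(seq_len(nrow(combos)), function(i) {
    p <- design$base_params
    for (j in seq_along(design$varied)) {
      p <- scale_parameter(p, design$varied[j], combos[[j]][i])
    }
    traj <- run_scenarios(design$scenario, p, settings)$trajectory[[1L]]
    eq <- equilibrium_summary(traj, window)
    stats::setNames(as.list(eq$mean), eq$state)
  }) |>
    purrr::map(tibble::as_tibble) |>
    purrr::list_rbind()
  dplyr::bind_cols(combos, means)
}

#' Ratio of terminal-window biomass between two runs
#'
#' @param varied,baseline Two `scav_sim` trajectories on the same output
#'   grid.
#' @param state State name (`"V"`, `"D"`, `"B"`, `"S"` or `"W"`).
#' @param window Terminal window (years), default 50.
#' @return The ratio of window means, varied over baseline.
#' @export
biomass_ratio_vs_baseline <- function(varied, baseline, state = "S",
                                      window = 50) {
  if (!isTRUE(all.equal(varied$time, baseline$time))) {
    stop("trajectories must share the same output grid", call. = FALSE)
  }
  mean_of <- function(traj) {
    eq <- equilibrium_summary(traj, window)
    eq$mean[eq$state == state]
  }
  base <- mean_of(baseline)
  if (base <= 0) stop("baseline window mean is zero for state ", state,
                      call. = FALSE)
  mean_of(varied) / base
}

#' Multistart convergence check for one scenario
#'
#' Integrates a scenario from several distinct strictly positive initial
#' states (the base initial state of each present guild scaled
#' component-wise by fixed multipliers) and measures the maximum relative
#' spread of the terminal-window means across starts. Convergence to a
#' single attractor shows up as a small spread.
#'
#' States that are (numerically) extinct in all starts are excluded from
#' the spread: relative spread among near-zero biomasses is not
#' informative about the attractor.
#'
#' @param scenario A single scenario row.
#' @param params Baseline [scav_params()].
#' @param settings A [run_settings()] object.
#' @param multipliers Component-wise initial-state multipliers, default
#'   `c(0.5, 1, 2)` (deterministic, no RNG).
#' @param rel_tol Pass threshold on the spread, default 0.01.
#' @param window Terminal window (years), default 50.
#' @param extinct_threshold States whose across-start mean biomass is
#'   below this (ton ha^-1) are treated as extinct, default `1e-4`.
#' @return A one-row tibble: `label`, `pass`, `spread`.
#' @export
multistart_endstate_check <- function(scenario, params = scav_params(),
                                      settings = run_settings(),
                                      multipliers = c(0.5, 1, 2),
                                      rel_tol = 0.01, window = 50,
                                      extinct_threshold = 1e-4) {
  if (length(multipliers) < 2L) {
    stop("need at least two starts", call. = FALSE)
  }
  base_init <- scenario_initial(scenario)
  p <- scenario_params(scenario, params)
  means <- purrr::map(multipliers, function(m) {
    traj <- simulate_trophic(base_init * m, p, settings,
                             label = scenario$label)
    eq <- equilibrium_summary(traj, window)
    stats::setNames(eq$mean, eq$state)
  })
  mat <- do.call(rbind, means)
  center <- colMeans(mat)
  alive <- center > extinct_threshold
  spread <- if (any(alive)) {
    max((apply(mat[, alive, drop = FALSE], 2L, max) -
           apply(mat[, alive, drop = FALSE], 2L, min)) / center[alive])
  } else {
    0
  }
  tibble::tibble(label = scenario$label, pass = spread < rel_tol,
                 spread = spread)
}
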