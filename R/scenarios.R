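presence_levels <- tibble::tibble(
  boar_present = c(TRUE, FALSE, TRUE, FALSE),
  wolf_present = c(TRUE, TRUE, FALSE, FALSE),
  presence = c("boar+wolf", "wolf-only", "boar-only", "neither")
)

#' Build the factorial scenario grid
#'
#' Crosses boar/wolf presence with hunting targets and leftover fractions.
#' Targets and leftovers are varied jointly for deer and boar
#' (`T_D = T_B`, `L_D = L_B`), matching the way the hunting regime is
#' described: a single "hunting target" and a single "fraction of carrion
#' left" factor. Absence of a guild is encoded by a zero initial biomass.
#'
#' @param targets Hunting target levels (ton ha^-1) in `[0, 1]`;
#'   default `c(0, 0.5, 1)` (zero / medium / high target).
#' @param leftovers Fractions of hunted biomass left in the field, in
#'   `[0, 1]`; default `c(0, 0.5, 1)`.
#' @param presence Data frame with logical columns `boar_present` and
#'   `wolf_present`; default all four combinations.
#' @param hunting_rate Hunting rate `H_D = H_B` (yr^-1), default 1.
#' @param initial Baseline initial state for present guilds.
#' @return A tibble with one row per scenario: `label`, presence flags,
#'   `target`, `leftover`, `hunting_rate`, and initial-state columns
#'   `V0`, `D0`, `B0`, `S0`, `W0`.
#' @examples
#' nrow(build_scenario_grid()) # 4 presence x 3 targets x 3 leftovers = 36
#' @export
build_scenario_grid <- function(targets = c(0, 0.5, 1),
                                leftovers = c(0, 0.5, 1),
                                presence = presence_levels,
                                hunting_rate = 1,
                                initial = initial_state()) {
  if (!length(targets) || !length(leftovers) || !nrow(presence)) {
    stop("targets, leftovers and presence must be non-empty", call. = FALSE)
  }
  if (any(targets < 0 | targets > 1) || any(leftovers < 0 | leftovers > 1)) {
    stop("targets and leftovers must lie in [0, 1]", call. = FALSE)
  }
  presence <- tibble::as_tibble(presence)
  if (!"presence" %in% names(presence)) {
    presence$presence <- paste0(
      ifelse(presence$boar_present, "boar+", "boar-"),
      ifelse(presence$wolf_present, "wolf+", "wolf-")
    )
  }
  grid <- tidyr::expand_grid(presence, target = targets, leftover = leftovers)
  dplyr::mutate(
    grid,
    hunting_rate = hunting_rate,
    V0 = initial[["V"]],
    D0 = initial[["D"]],
    B0 = ifelse(.data$boar_present, initial[["B"]], 0),
    S0 = initial[["S"]],
    W0 = ifelse(.data$wolf_present, initial[["W"]], 0),
    label = sprintf("%s_T%g_L%g", .data$presence, .data$target,
                    .data$leftover),
    .before = 1L
  ) |>
    dplyr::relocate("label")
}

#' Incremental model-building sequence
#'
#' The step-by-step complexity ladder used to bring the model up:
#' vegetation alone, then vegetation + deer, vegetation + boar,
#' vegetation + deer + boar, adding scavengers, and finally the full
#' five-state system. Later guilds are removed by zeroing their initial
#' biomass.
#'
#' @param initial Baseline initial state for the full system.
#' @return A tibble of six scenario rows in build order, same columns as
#'   [build_scenario_grid()].
#' @export
incremental_build_sequence <- function(initial = initial_state()) {
  keep <- list(
    "V-only"    = c("V"),
    "V+D"       = c("V", "D"),
    "V+B"       = c("V", "B"),
    "V+D+B"     = c("V", "D", "B"),
    "V+D+B+S"   = c("V", "D", "B", "S"),
    "full"      = c("V", "D", "B", "S", "W")
  )
  purrr::imap(keep, function(guilds, lab) {
    s <- initial
    s[setdiff(state_names, guilds)] <- 0
    tibble::tibble(
      label = lab,
      boar_present = s[["B"]] > 0, wolf_present = s[["W"]] > 0,
      presence = lab, target = 0.5, leftover = 0.5, hunting_rate = 1,
      V0 = s[["V"]], D0 = s[["D"]], B0 = s[["B"]],
      S0 = s[["S"]], W0 = s[["W"]]
    )
  }) |>
    purrr::list_rbind()
}

scenario_params <- function(row, params) {
  params$T_D <- row$target
  params$T_B <- row$target
  params$L_D <- row$leftover
  params$L_B <- row$leftover
  params$H_D <- row$hunting_rate
  params$H_B <- row$hunting_rate
  validate_params(params)
}

scenario_initial <- function(row) {
  c(V = row$V0, D = row$D0, B = row$B0, S = row$S0, W = row$W0)
}

#' Run every scenario in a grid
#'
#' Integrates each scenario row independently (run order cannot affect
#' the output: every run is deterministic given its own inputs).
#'
#' @param grid A scenario tibble from [build_scenario_grid()] or
#'   [incremental_build_sequence()].
#' @param params Baseline [scav_params()]; each row overrides the hunting
#'   regime (`T`, `H`, `L`) with its own factors.
#' @param settings A [run_settings()] object.
#' @return `grid` with an added list-column `trajectory` of `scav_sim`
#'   tibbles.
#' @export
run_scenarios <- function(grid, params = scav_params(),
                          settings = run_settings()) {
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) {
    grid$trajectory <- list()
    return(grid)
  }
  grid$trajectory <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    tryCatch(
      simulate_trophic(scenario_initial(row), scenario_params(row, params),
                       settings, label = row$label),
      error = function(e) {
        stop(sprintf("scenario '%s': %s", row$label, conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
  grid
}

#' Terminal-window summary of a set of runs
#'
#' @param runs Output of [run_scenarios()].
#' @param window Terminal window width (years), default 50.
#' @return A long tibble: one row per scenario and state with the
#'   window `mean` and `amplitude`.
#' @export
summarise_runs <- function(runs, window = 50) {
  purrr::map2(runs$label, runs$trajectory, function(lab, traj) {
    dplyr::mutate(equilibrium_summary(traj, window), label = lab,
                  .before = 1L)
  }) |>
    purrr::list_rbind()
}
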