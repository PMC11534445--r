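#' Numerical run settings
#'
#' @param t_end Simulation horizon (years), default 250.
#' @param output_step Output grid spacing (years), default 1.
#' @param rtol,atol Relative and absolute integration tolerances,
#'   defaults `1e-8` and `1e-10`.
#' @param extinction_floor Density below which a state is reported as 0
#'   (ton ha^-1), default `1e-12`.
#' @return A named list of class `run_settings`.
#' @export
run_settings <- function(t_end = 250, output_step = 1,
                         rtol = 1e-8, atol = 1e-10,
                         extinction_floor = 1e-12) {
  if (t_end <= 0 || output_step <= 0 || rtol <= 0 || atol <= 0) {
    stop("t_end, output_step, rtol and atol must all be > 0", call. = FALSE)
  }
  structure(
    list(t_end = t_end, output_step = output_step,
         rtol = rtol, atol = atol, extinction_floor = extinction_floor),
    class = "run_settings"
  )
}

#' Default initial state
#'
#' @param boar_present,wolf_present Logical presence flags; an absent
#'   guild starts (and therefore stays) at zero biomass.
#' @param V,D,B,S,W Initial biomass densities (ton ha^-1) for the guilds
#'   that are present.
#' @return Named numeric state vector.
#' @export
initial_state <- function(boar_present = TRUE, wolf_present = TRUE,
                          V = 5, D = 0.5, B = 0.5, S = 0.1, W = 0.05) {
  s <- c(V = V, D = D, B = if (boar_present) B else 0,
         S = S, W = if (wolf_present) W else 0)
  if (any(s < 0)) stop("initial biomasses must be >= 0", call. = FALSE)
  s
}

#' Integrate the trophic-web model
#'
#' Solves the five-state system with `deSolve`'s `lsoda`, which switches
#' automatically between stiff and non-stiff methods, and returns the
#' solution on a fixed output grid together with the full flux breakdown
#' recomputed at every output time.
#'
#' @param initial Named initial state (see [initial_state()]); components
#'   of value 0 encode absent guilds.
#' @param params A [scav_params()] set.
#' @param settings A [run_settings()] object.
#' @param label Scenario label stored with the trajectory.
#' @return A tibble of class `scav_sim` with columns `time`, the five
#'   states (`V`, `D`, `B`, `S`, `W`) and every flux field; attributes
#'   `params`, `settings`, `scenario_id` and `params_hash`.
#' @examples
#' traj <- simulate_trophic(initial_state(), settings = run_settings(t_end = 50))
#' tail(traj[, c("time", "V", "D", "B", "S", "W")])
#' @export
simulate_trophic <- function(initial, params = scav_params(),
                             settings = run_settings(), label = "run") {
  params <- validate_params(params)
  initial <- initial[state_names]
  if (anyNA(initial) || any(initial < 0)) {
    stop("initial state must be a non-negative vector with components ",
         paste(state_names, collapse = ", "), call. = FALSE)
  }
  times <- seq(0, settings$t_end, by = settings$output_step)
  if (times[length(times)] < settings$t_end) {
    times <- c(times, settings$t_end)
  }
  ode_fun <- function(t, y, parms) list(rhs(t, y, parms)$derivatives)
  out <- deSolve::lsoda(
    y = initial, times = times, func = ode_fun, parms = params,
    rtol = settings$rtol, atol = settings$atol
  )
  out <- as.matrix(out)
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    bad <- if (nrow(out) > 0) out[nrow(out), ] else c(time = NA)
    stop(sprintf(
      "integration failed for scenario '%s' near t = %s (last state: %s)",
      label, format(bad[["time"]]),
      paste(format(bad[-1], digits = 4), collapse = ", ")
    ), call. = FALSE)
  }
  states <- out[, state_names, drop = FALSE]
  states[states < settings$extinction_floor] <- 0
  fluxes <- t(apply(states, 1L, flux_breakdown, params = params))
  traj <- tibble::as_tibble(cbind(time = out[, "time"], states, fluxes))
  new_scav_sim(traj, params = params, settings = settings, label = label)
}

new_scav_sim <- function(traj, params, settings, label) {
  structure(
    traj,
    class = c("scav_sim", class(tibble::tibble())),
    params = params,
    settings = settings,
    scenario_id = label,
    params_hash = rlang::hash(list(params = unclass(params),
                                   settings = unclass(settings)))
  )
}

#' @export
print.scav_sim <- function(x, ...) {
  cat(sprintf("<scav_sim> scenario '%s': %d output times over %g years\n",
              attr(x, "scenario_id"), nrow(x), max(x$time)))
  NextMethod()
}

#' Equilibrium summary over the final window of a trajectory
#'
#' Time-average and amplitude (max minus min) of each state over the last
#' `window` years of the run; used to read equilibria and residual
#' oscillations off a trajectory.
#'
#' @param traj A `scav_sim` trajectory (or any tibble with `time` and
#'   state columns).
#' @param window Width of the terminal window (years); must not exceed
#'   the trajectory's span.
#' @return A tibble with columns `state`, `mean`, `amplitude`.
#' @export
equilibrium_summary <- function(traj, window = 50) {
  t_end <- max(traj$time)
  if (window <= 0 || window > t_end - min(traj$time)) {
    stop("window must be positive and no longer than the trajectory",
         call. = FALSE)
  }
  tail_rows <- traj[traj$time >= t_end - window, , drop = FALSE]
  present <- intersect(state_names, names(traj))
  tibble::tibble(
    state = present,
    mean = vapply(present, function(s) mean(tail_rows[[s]]), numeric(1),
                  USE.NAMES = FALSE),
    amplitude = vapply(
      present,
      function(s) max(tail_rows[[s]]) - min(tail_rows[[s]]),
      numeric(1), USE.NAMES = FALSE
    )
  )
}

#' Write a trajectory as a tidy long CSV with a JSON metadata sidecar
#'
#' @param traj A `scav_sim` trajectory.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(traj), -"time",
    names_to = "variable", values_to = "value"
  )
  long <- dplyr::mutate(long, scenario_id = attr(traj, "scenario_id"),
                        .before = 1L)
  readr::write_csv(long, path)
  meta <- list(
    scenario_id = attr(traj, "scenario_id"),
    params = unclass(attr(traj, "params")),
    settings = unclass(attr(traj, "settings")),
    params_hash = attr(traj, "params_hash"),
    deterministic = TRUE,
    package_version = as.character(utils::packageVersion("scavsim"))
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
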