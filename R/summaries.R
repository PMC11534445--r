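#' Scavenger growth source decomposition
#'
#' Per-time fraction of scavenger biomass growth attributable to
#' vegetation, `SgrowthV / (SgrowthV + SgrowthD + SgrowthB)`, mapped into
#' `[0, 1]`. Time points with zero total scavenger growth report a
#' fraction of 1 (vegetation-dominance convention) and are flagged.
#'
#' @param traj A `scav_sim` trajectory.
#' @return A tibble with `scenario_id`, `time`, the three growth
#'   channels, `veg_growth_fraction`, and a logical `degenerate` flag.
#' @export
growth_source_series <- function(traj) {
  total <- traj$SgrowthV + traj$SgrowthD + traj$SgrowthB
  tibble::tibble(
    scenario_id = attr(traj, "scenario_id") %||% "run",
    time = traj$time,
    SgrowthV = traj$SgrowthV,
    SgrowthD = traj$SgrowthD,
    SgrowthB = traj$SgrowthB,
    veg_growth_fraction = ifelse(total > 0, traj$SgrowthV / total, 1),
    degenerate = total <= 0
  )
}

#' Carrion composition and origin decomposition
#'
#' Splits the total carrion flux `K_D + K_B` by origin — hunting
#' leftovers, wolf-kill leftovers, and natural mortality — and reports
#' the deer-versus-boar composition of the carrion available to
#' scavengers (`K_D_avail`, `K_B`). Origin channels sum to `K_D + K_B`
#' exactly.
#'
#' @param traj A `scav_sim` trajectory.
#' @param params Parameter set used for the run; defaults to the one
#'   stored on the trajectory.
#' @return A tibble with `scenario_id`, `time`, `carrion_deer`
#'   (`K_D_avail`), `carrion_boar` (`K_B`), `carrion_from_hunting`,
#'   `carrion_from_predation`, `carrion_from_natural`.
#' @export
carrion_origin_series <- function(traj, params = attr(traj, "params")) {
  if (is.null(params)) stop("params not found on trajectory", call. = FALSE)
  tibble::tibble(
    scenario_id = attr(traj, "scenario_id") %||% "run",
    time = traj$time,
    carrion_deer = traj$K_D_avail,
    carrion_boar = traj$K_B,
    carrion_from_hunting = traj$Dhunt * params$L_D + traj$Bhunt * params$L_B,
    carrion_from_predation = (traj$Dpred + traj$Bpred) * params$v,
    carrion_from_natural = traj$Ddeath + traj$Bdeath
  )
}

#' Write a complete run bundle to disk
#'
#' Emits, for a set of scenario runs: one tidy long trajectory CSV per
#' run (with a JSON metadata sidecar), the two summary CSVs (scavenger
#' growth sources and carrion origin, all scenarios stacked), a bundle
#' metadata JSON, and optionally the faceted figures.
#'
#' @param runs Output of [run_scenarios()] (may be empty).
#' @param dir Destination directory, created if needed.
#' @param figures If `TRUE`, also writes PNG figures of scavenger
#'   biomass, growth sources, and carrion composition.
#' @param window Terminal window used in the logged end-state summary.
#' @return Invisibly, a character vector of the files written.
#' @export
write_run_bundle <- function(runs, dir, figures = FALSE, window = 50) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (i in seq_len(nrow(runs))) {
    path <- file.path(dir, paste0("trajectory_", runs$label[i], ".csv"))
    write_trajectory(runs$trajectory[[i]], path)
    written <- c(written, path, sub("\\.csv$", ".json", path))
  }
  if (nrow(runs)) {
    growth <- purrr::map(runs$trajectory, growth_source_series) |>
      purrr::list_rbind()
    origin <- purrr::map(runs$trajectory, carrion_origin_series) |>
      purrr::list_rbind()
    gpath <- file.path(dir, "summary_growth_sources.csv")
    opath <- file.path(dir, "summary_carrion_origin.csv")
    readr::write_csv(growth, gpath)
    readr::write_csv(origin, opath)
    written <- c(written, gpath, opath)
  }
  meta <- list(
    n_scenarios = nrow(runs),
    scenario_labels = runs$label,
    settings = if (nrow(runs)) unclass(attr(runs$trajectory[[1L]],
                                            "settings")),
    package_version = as.character(utils::packageVersion("scavsim")),
    deterministic = TRUE
  )
  mpath <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, mpath)
  if (figures && nrow(runs)) {
    figs <- list(
      scavenger_biomass = plot_scenario_biomass(runs),
      growth_sources = plot_growth_sources(runs),
      carrion_composition = plot_carrion_composition(runs)
    )
    for (nm in names(figs)) {
      fpath <- file.path(dir, paste0("figure_", nm, ".png"))
      try(ggplot2::ggsave(fpath, figs[[nm]], width = 9, height = 6,
                          dpi = 150), silent = TRUE)
      if (file.exists(fpath)) written <- c(written, fpath)
    }
  }
  invisible(written)
}
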