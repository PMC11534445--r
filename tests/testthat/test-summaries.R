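fake_traj <- function(SgrowthV, SgrowthD, SgrowthB) {
  structure(
    tibble::tibble(time = seq_along(SgrowthV) - 1,
                   SgrowthV = SgrowthV, SgrowthD = SgrowthD,
                   SgrowthB = SgrowthB),
    scenario_id = "fixture"
  )
}

test_that("the vegetation share of scavenger growth is a bounded fraction", {
  d <- growth_source_series(fake_traj(0.3, 0.1, 0.2))
  expect_equal(d$veg_growth_fraction, 0.5)
  expect_false(d$degenerate)
  expect_equal(growth_source_series(fake_traj(0.4, 0, 0))$veg_growth_fraction,
               1)
  expect_equal(growth_source_series(fake_traj(0, 0.1, 0.3))$veg_growth_fraction,
               0)
  degen <- growth_source_series(fake_traj(0, 0, 0))
  expect_equal(degen$veg_growth_fraction, 1)  # vegetation-dominance convention
  expect_true(degen$degenerate)
})

test_that("growth fraction is in [0,1] along a real trajectory", {
  traj <- simulate_trophic(initial_state(), label = "full")
  d <- growth_source_series(traj)
  expect_true(all(d$veg_growth_fraction >= 0 & d$veg_growth_fraction <= 1))
})

test_that("carrion origin channels sum to the total carrion flux", {
  p <- scav_params()
  traj <- simulate_trophic(initial_state(), p, label = "full")
  d <- carrion_origin_series(traj)
  total <- d$carrion_from_hunting + d$carrion_from_predation +
    d$carrion_from_natural
  expect_equal(total, traj$K_D + traj$K_B, tolerance = 1e-12)
  # wolf present above the floor implies a live predation channel
  expect_true(all(d$carrion_from_predation[traj$W > 1e-12] > 0))
})

test_that("absent processes produce identically zero origin channels", {
  no_wolf <- run_scenarios(
    build_scenario_grid(targets = 0.5, leftovers = 0.5,
                        presence = data.frame(boar_present = TRUE,
                                              wolf_present = FALSE)),
    settings = run_settings(t_end = 60)
  )$trajectory[[1]]
  expect_true(all(carrion_origin_series(no_wolf)$carrion_from_predation == 0))

  no_leftover <- run_scenarios(
    build_scenario_grid(targets = 0.5, leftovers = 0),
    settings = run_settings(t_end = 60)
  )$trajectory[[1]]
  expect_true(all(carrion_origin_series(no_leftover)$carrion_from_hunting == 0))
})

test_that("run bundles are complete and byte-deterministic", {
  runs <- run_scenarios(build_scenario_grid(targets = 0.5, leftovers = 0.5),
                        settings = run_settings(t_end = 30))
  dir1 <- withr::local_tempdir()
  files <- write_run_bundle(runs[1, ], dir1)
  expect_setequal(
    basename(files),
    c("trajectory_boar+wolf_T0.5_L0.5.csv",
      "trajectory_boar+wolf_T0.5_L0.5.json",
      "summary_growth_sources.csv", "summary_carrion_origin.csv",
      "metadata.json")
  )
  dir2 <- withr::local_tempdir()
  write_run_bundle(runs[1, ], dir2)
  for (f in grep("\\.csv$", basename(files), value = TRUE)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # empty run set: metadata-only bundle
  dir3 <- withr::local_tempdir()
  files3 <- write_run_bundle(runs[0, ], dir3)
  expect_equal(basename(files3), "metadata.json")
})

test_that("plot constructors return ggplot objects", {
  runs <- run_scenarios(build_scenario_grid(targets = 0.5, leftovers = 0.5),
                        settings = run_settings(t_end = 30))
  expect_s3_class(plot_scenario_biomass(runs), "ggplot")
  expect_s3_class(plot_growth_sources(runs), "ggplot")
  expect_s3_class(plot_carrion_composition(runs), "ggplot")
  expect_s3_class(ggplot2::autoplot(runs$trajectory[[1]]), "ggplot")
  sens <- factorial_runs(
    sensitivity_design(c("C_VS", "A_XS"), factors = c(0.9, 1.1)),
    run_settings(t_end = 20), window = 10
  )
  expect_s3_class(plot_endstate_image(sens), "ggplot")
})

test_that("tidy and glance summarise trajectories", {
  traj <- simulate_trophic(initial_state(), settings = run_settings(t_end = 20),
                           label = "tiny")
  long <- tidy(traj)
  expect_named(long, c("scenario_id", "time", "variable", "value"))
  expect_equal(nrow(long), 21 * 5)
  expect_gt(nrow(tidy(traj, fluxes = TRUE)), nrow(long))
  g <- glance(traj, window = 10)
  expect_equal(nrow(g), 1)
  expect_equal(g$scenario_id, "tiny")
  expect_true(all(c("V_mean", "W_amp") %in% names(g)))
})
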