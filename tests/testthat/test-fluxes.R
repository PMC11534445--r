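p <- scav_params()

test_that("vegetation regrowth is logistic", {
  expect_equal(vegetation_growth(10, p), 0)  # vanishes at carrying capacity
  expect_equal(vegetation_growth(0, p), 0)
  expect_equal(vegetation_growth(5, p), 4 * 5 * (1 - 0.5))
  expect_lt(vegetation_growth(12, p), 0)     # overshoot damping only
})

test_that("holling type-II response saturates at the maximum rate", {
  expect_equal(holling2(0, 23.5, 10), 0)
  expect_equal(holling2(10, 23.5, 10), 23.5 / 2)
  expect_equal(holling2(10, 23.5, 10), 11.75)
  expect_lt(holling2(1e6, 23.5, 10), 23.5)
  expect_error(holling2(1, 1, 0), "half_sat")
})

test_that("boar carrion diet portion has guarded limits and saturates below u", {
  expect_equal(boar_carrion_portion(5, 0, p), 0)
  expect_equal(boar_carrion_portion(0, 1, p), 0)
  # x = 2.015 / 20.15 = 0.1 -> 0.2 * 0.1 / 0.2
  expect_equal(boar_carrion_portion(2.015, 1, p), 0.1)
  expect_lt(boar_carrion_portion(1e9, 1, p), p$u)
})

test_that("diet-corrected boar intake equals A_XB at the average diet and falls with carrion share", {
  expect_equal(boar_intake_capacity(p$u_a, p), p$A_XB)
  expect_equal(boar_intake_capacity(0, p),
               20.15 * (0.055 * 0.84 + 0.069 * 0.16) / 0.055)
  expect_lt(boar_intake_capacity(p$u, p), p$A_XB)
  expect_gt(boar_intake_capacity(0, p), boar_intake_capacity(p$u, p))
})

test_that("realized boar intake is a type-II response to the diet-weighted food density", {
  expect_equal(boar_realized_intake(0, 0, 0, 21, p), 0)
  expect_equal(boar_realized_intake(10, 0, 0, 21, p), 21 / 2)
  # m = 9 * 0.9 + 19 * 0.1 = 10
  expect_equal(boar_realized_intake(9, 19, 0.1, 21, p), 21 * 10 / 20)
})

test_that("carrion pools combine mortality, hunting leftovers and kill leftovers", {
  expect_equal(carrion_pool(0, 0, 0, 0.5, 0.32), 0)
  expect_equal(carrion_pool(0.1, 0.2, 0.5, 0.5, 0.32), 0.36)
  expect_equal(carrion_pool(0.1, 0.2, 0.5, 1, 1), 0.8)
})

test_that("scavenger intake capacity responds to combined food density", {
  expect_equal(scavenger_intake_capacity(0, 0, 0, p), 0)
  expect_equal(scavenger_intake_capacity(10, 0, 0, p), 20 * 10 / 20)
  expect_equal(scavenger_intake_capacity(5, 3, 2, p), 10)
})

test_that("predation splits by squared prey preference and conserves the total", {
  expect_equal(predation_fluxes(1, 1, 0, p), c(Dpred = 0, Bpred = 0))
  expect_equal(predation_fluxes(0, 0, 0.3, p), c(Dpred = 0, Bpred = 0))
  eq <- predation_fluxes(2, 2, 0.1, p)
  expect_equal(eq[["Dpred"]], eq[["Bpred"]])
  one <- predation_fluxes(10, 0, 0.1, p)
  expect_equal(one[["Dpred"]], 96.6 * (10 / 20) * 0.1)
  expect_equal(one[["Bpred"]], 0)
})

test_that("hunting is zero at the target, continuous there, and increasing above", {
  expect_equal(hunting_flux(0.5, 0.5, 1), 0)
  expect_equal(hunting_flux(0.3, 0.5, 1), 0)
  expect_equal(hunting_flux(2, 0, 0.7), 0.7 * 2)  # T = 0: proportional harvest
  expect_equal(hunting_flux(1, 0.5, 1), 0.25)
  # continuity at X = T and monotonicity above
  xs <- seq(0.5, 3, by = 1e-3)
  fx <- hunting_flux(xs, 0.5, 1)
  expect_lt(fx[2], 1e-5)
  expect_true(all(diff(fx) >= 0))
})

test_that("natural prey mortality is suppressed by predation pressure", {
  expect_equal(natural_mortality_prey(2, 1, 0, 0.125, 10), 0.25)
  expect_equal(natural_mortality_prey(0, 1, 0.3, 0.125, 10), 0)
  expect_equal(natural_mortality_prey(1, 1, 0.1, 0.125, 10),
               0.125 * exp(-1))
  expect_lte(natural_mortality_prey(1, 0.4, 0.2, 0.125, 10), 0.125)
})

test_that("scavenger carrion growth is capped by availability in both dialects", {
  expect_equal(scavenger_carrion_growth(5, 1, 0, 0.1), 0)
  expect_equal(scavenger_carrion_growth(5, 1, 2, 0.1), 0.2)   # availability binds
  expect_equal(scavenger_carrion_growth(1, 1, 2, 0.1), 0.1)   # demand binds
  prop <- scavenger_carrion_growth(5, 1, 2, 0.1, total_food = 10,
                                   dialect = "proportional")
  expect_equal(prop, min(5 * 1 * 2 / 10, 2) * 0.1)
  expect_lte(prop, 2 * 0.1)
})

test_that("rhs is absorbing at extinction and reduces to pure regrowth", {
  zero <- c(V = 0, D = 0, B = 0, S = 0, W = 0)
  expect_equal(unname(rhs(0, zero, p)$derivatives), rep(0, 5))
  veg <- rhs(0, c(V = 5, D = 0, B = 0, S = 0, W = 0), p)$derivatives
  expect_equal(unname(veg), c(10, 0, 0, 0, 0))
  expect_error(rhs(0, c(V = NaN, D = 0, B = 0, S = 0, W = 0), p),
               "non-finite")
})

test_that("rhs matches the independent transcription on 1000 random states", {
  states <- random_states(1000)
  for (i in seq_len(nrow(states))) {
    got <- rhs(0, states[i, ], p)$derivatives
    want <- oracle_rhs(states[i, ], p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("flux breakdown satisfies the conservation and bound invariants", {
  states <- random_states(500, seed = 7)
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    f <- flux_breakdown(st, p)
    # non-negative closure (Vgrowth may dip below 0 only above k0)
    expect_true(all(f[setdiff(names(f), "Vgrowth")] >= 0))
    if (st[["V"]] <= p$k0) expect_gte(f[["Vgrowth"]], 0)
    # predation conservation
    if (st[["D"]]^2 + st[["B"]]^2 > 0) {
      total <- p$r * (st[["D"]] + st[["B"]]) /
        (p$B_XX + st[["D"]] + st[["B"]]) * st[["W"]]
      expect_equal(f[["Dpred"]] + f[["Bpred"]], total, tolerance = 1e-14)
    }
    # carrion caps and availability identity
    expect_lte(f[["SgrowthD"]], f[["K_D_avail"]] * p$C_XS * (1 + 1e-12))
    expect_lte(f[["SgrowthB"]], f[["K_B"]] * p$C_XS * (1 + 1e-12))
    expect_equal(f[["K_D_avail"]],
                 max(f[["K_D"]] - f[["A_tdot_XB"]] * f[["u_dd"]] * st[["B"]],
                     0))
    # realized diet portion strictly below its maximum
    expect_lt(f[["u_dd"]], p$u)
    expect_gte(f[["u_dd"]], 0)
  }
})

test_that("deer carrion flux is non-decreasing in the leftover and unconsumed fractions", {
  st <- c(V = 5, D = 1.2, B = 0.8, S = 0.3, W = 0.1)
  kd_at <- function(L_D, v) {
    flux_breakdown(st, scav_params(L_D = L_D, v = v))[["K_D"]]
  }
  ls <- vapply(seq(0, 1, 0.1), kd_at, numeric(1), v = 0.32)
  vs <- vapply(seq(0, 1, 0.1), function(v) kd_at(0.5, v), numeric(1))
  expect_true(all(diff(ls) >= 0))
  expect_true(all(diff(vs) >= 0))
})
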