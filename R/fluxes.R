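#' Holling type-II functional response
#'
#' Per-consumer intake rate that saturates with resource density:
#' `rate * resource / (half_sat + resource)`. Monotone increasing in the
#' resource and bounded above by `rate`; equals `rate / 2` at the
#' half-saturation density.
#'
#' @param resource Resource density (ton ha^-1), non-negative.
#' @param rate Maximum intake rate (yr^-1).
#' @param half_sat Half-saturation density (ton ha^-1), strictly positive.
#' @return Per-unit intake (yr^-1).
#' @export
holling2 <- function(resource, rate, half_sat) {
  if (any(half_sat <= 0)) stop("half_sat must be > 0", call. = FALSE)
  rate * resource / (half_sat + resource)
}

#' Logistic vegetation regrowth
#'
#' `R0 * V * (1 - V / k0)`; zero at `V = 0` and at the carrying capacity
#' `k0`, negative only when vegetation overshoots `k0`.
#'
#' @param V Vegetation biomass density (ton ha^-1).
#' @param params A [scav_params()] set (uses `R0`, `k0`).
#' @return Growth flux (ton ha^-1 yr^-1).
#' @export
vegetation_growth <- function(V, params) {
  params$R0 * V * (1 - V / params$k0)
}

#' Realized deer-carrion portion of the boar diet
#'
#' Boar scavenge deer carrion opportunistically: the realized diet portion
#' follows a Holling type-II response in the per-boar carrion supply
#' `x = K_D / (A_XB * B)`, saturating strictly below the maximum portion
#' `u`. Defined as 0 when boar are absent or no deer carrion is produced.
#'
#' @param K_D Deer carrion production flux (ton ha^-1 yr^-1).
#' @param B Boar biomass density (ton ha^-1).
#' @param params A [scav_params()] set (uses `A_XB`, `u`, `B_u`).
#' @return Dimensionless portion in `[0, u)`.
#' @export
boar_carrion_portion <- function(K_D, B, params) {
  if (B <= 0 || K_D <= 0) return(0)
  x <- K_D / (params$A_XB * B)
  params$u * x / (params$B_u + x)
}

#' Diet-corrected maximum boar intake
#'
#' Deer carrion converts to boar biomass more efficiently than vegetation
#' (`C_DB > C_VB`), so a boar eating more carrion needs less total food to
#' realize the same biomass gain. The maximum intake is rescaled from its
#' average-diet calibration `A_XB` by the ratio of diet-weighted conversion
#' efficiencies; it equals `A_XB` exactly at the average portion `u_a` and
#' decreases as the realized portion `u_dd` rises.
#'
#' @param u_dd Realized deer-carrion diet portion, in `[0, u]`.
#' @param params A [scav_params()] set (uses `A_XB`, `C_VB`, `C_DB`, `u_a`).
#' @return Intake capacity (yr^-1).
#' @export
boar_intake_capacity <- function(u_dd, params) {
  num <- params$C_VB * (1 - params$u_a) + params$C_DB * params$u_a
  den <- params$C_VB * (1 - u_dd) + params$C_DB * u_dd
  if (den <= 0) stop("degenerate conversion factors: denominator <= 0",
                     call. = FALSE)
  params$A_XB * num / den
}

#' Realized total boar intake
#'
#' Holling type-II response of the diet-corrected capacity to the
#' diet-weighted food density `m = V * (1 - u_dd) + K_D * u_dd`.
#'
#' @param V Vegetation density (ton ha^-1).
#' @param K_D Deer carrion flux (ton ha^-1 yr^-1).
#' @param u_dd Realized carrion diet portion.
#' @param A_ddot_XB Diet-corrected intake capacity (yr^-1), from
#'   [boar_intake_capacity()].
#' @param params A [scav_params()] set (uses `B_XX`).
#' @return Realized intake per unit boar (yr^-1).
#' @export
boar_realized_intake <- function(V, K_D, u_dd, A_ddot_XB, params) {
  m <- V * (1 - u_dd) + K_D * u_dd
  A_ddot_XB * m / (params$B_XX + m)
}

#' Carrion production flux for one prey guild
#'
#' Carrion is produced by natural mortality, by the portion of hunted
#' biomass left in the field, and by the portion of wolf kills the wolves
#' do not consume: `death + hunt * leftover + pred * unconsumed`.
#'
#' @param death,hunt,pred Mortality, hunting, and predation fluxes
#'   (ton ha^-1 yr^-1).
#' @param leftover Fraction of hunted biomass left behind (`L_D` / `L_B`).
#' @param unconsumed Fraction of predated biomass not eaten by wolves (`v`).
#' @return Carrion flux (ton ha^-1 yr^-1).
#' @export
carrion_pool <- function(death, hunt, pred, leftover, unconsumed) {
  death + hunt * leftover + pred * unconsumed
}

#' Scavenger total intake capacity
#'
#' Holling type-II response to the scavengers' combined food density:
#' vegetation plus the deer carrion left after boar scavenging plus boar
#' carrion.
#'
#' @param V Vegetation density (ton ha^-1).
#' @param K_D_avail Deer carrion flux net of boar consumption.
#' @param K_B Boar carrion flux.
#' @param params A [scav_params()] set (uses `A_XS`, `B_XX`).
#' @return Intake capacity per unit scavenger (yr^-1).
#' @export
scavenger_intake_capacity <- function(V, K_D_avail, K_B, params) {
  total <- V + K_D_avail + K_B
  params$A_XS * total / (params$B_XX + total)
}

#' Wolf predation fluxes on deer and boar
#'
#' Total predation follows a Holling type-II response to combined prey
#' density, `r * (D + B) / (B_XX + D + B) * W`, and is split between deer
#' and boar in proportion to the squares of their biomasses — wolves
#' specialise on the more abundant prey. Both fluxes are 0 when no prey is
#' present.
#'
#' @param D,B,W Deer, boar, and wolf biomass densities (ton ha^-1).
#' @param params A [scav_params()] set (uses `r`, `B_XX`).
#' @return Named numeric vector `c(Dpred = , Bpred = )` (ton ha^-1 yr^-1).
#' @export
predation_fluxes <- function(D, B, W, params) {
  s2 <- D^2 + B^2
  if (s2 == 0 || W <= 0) return(c(Dpred = 0, Bpred = 0))
  total <- params$r * (D + B) / (params$B_XX + D + B) * W
  c(Dpred = total * D^2 / s2, Bpred = total * B^2 / s2)
}

#' Target-based hunting flux
#'
#' No hunting at or below the target biomass `T`; above it, the excess is
#' removed at rate `H` with an efficiency that declines as the population
#' approaches the target: `(1 - T/X) * H * (X - T) = H * (X - T)^2 / X`.
#' Continuous at `X = T` and monotone increasing above it.
#'
#' @param X Prey biomass density (ton ha^-1).
#' @param target Hunting target biomass `T` (ton ha^-1).
#' @param H Hunting rate (yr^-1).
#' @return Hunting flux (ton ha^-1 yr^-1).
#' @export
hunting_flux <- function(X, target, H) {
  ifelse(X <= target, 0, (1 - target / X) * H * (X - target))
}

#' Natural prey mortality suppressed by predation pressure
#'
#' Wolves preferentially take old and weak animals, so the background
#' death rate of a prey guild decays exponentially with the wolves'
#' predation pressure on that guild:
#' `exp(-q * W * own_sq_share) * M * X`, where `own_sq_share` is the
#' guild's squared-biomass share of predation (`X^2 / (D^2 + B^2)`,
#' 0 when both prey are absent).
#'
#' @param X Prey biomass density (ton ha^-1).
#' @param own_sq_share Squared-preference share in `[0, 1]`.
#' @param W Wolf biomass density (ton ha^-1).
#' @param M Baseline death rate (yr^-1).
#' @param q Decay rate of mortality with predation pressure.
#' @return Mortality flux (ton ha^-1 yr^-1), never exceeding `M * X`.
#' @export
natural_mortality_prey <- function(X, own_sq_share, W, M, q) {
  exp(-q * W * own_sq_share) * M * X
}

#' Scavenger growth from one carrion channel
#'
#' Carrion consumption is a Holling type-I response: scavengers consume at
#' their (type-II) capacity until the channel's availability is exhausted.
#' The `"literal"` dialect caps each channel independently at its own
#' availability; the `"proportional"` dialect first apportions the total
#' scavenger demand across food sources by availability, so that summed
#' consumption never exceeds total capacity.
#'
#' @param A_ddot_XS Scavenger intake capacity (yr^-1).
#' @param S Scavenger biomass density (ton ha^-1).
#' @param pool_avail Available carrion flux in this channel
#'   (ton ha^-1 yr^-1).
#' @param C_XS Carrion-to-scavenger conversion factor.
#' @param total_food Combined food density `V + K_D_avail + K_B`
#'   (needed by the proportional dialect).
#' @param dialect `"literal"` (default) or `"proportional"`.
#' @return Scavenger growth flux (ton ha^-1 yr^-1), never exceeding
#'   `pool_avail * C_XS`.
#' @export
scavenger_carrion_growth <- function(A_ddot_XS, S, pool_avail, C_XS,
                                     total_food = NULL,
                                     dialect = c("literal", "proportional")) {
  dialect <- match.arg(dialect)
  if (pool_avail <= 0) return(0)
  demand <- if (dialect == "literal") {
    A_ddot_XS * S
  } else {
    if (is.null(total_food) || total_food <= 0) return(0)
    A_ddot_XS * S * pool_avail / total_food
  }
  min(demand, pool_avail) * C_XS
}

# flux field names, in dependency order; fixed so trajectories and the
# breakdown always agree column-for-column
flux_fields <- c(
  "Vgrowth", "VconsD", "VconsB", "VconsS",
  "u_dd", "A_ddot_XB", "A_tdot_XB", "A_ddot_XS",
  "K_D", "K_B", "K_D_avail",
  "Dpred", "Bpred", "Dhunt", "Bhunt",
  "Ddeath", "Bdeath", "Sdeath", "Wdeath",
  "DgrowthV", "BgrowthV", "BgrowthD",
  "SgrowthV", "SgrowthD", "SgrowthB",
  "WgrowthD", "WgrowthB"
)

state_names <- c("V", "D", "B", "S", "W")

#' Evaluate every model flux at one state
#'
#' The audit trail of the right-hand side: every named flux and
#' intermediate quantity of the model, evaluated at a single state.
#' Negative state components are treated as 0.
#'
#' @param state Named numeric vector `c(V=, D=, B=, S=, W=)`
#'   (ton ha^-1).
#' @param params A [scav_params()] set.
#' @return Named numeric vector with elements `Vgrowth`, `VconsD`,
#'   `VconsB`, `VconsS`, the boar diet intermediates (`u_dd`,
#'   `A_ddot_XB`, `A_tdot_XB`), the scavenger capacity `A_ddot_XS`, the
#'   carrion fluxes (`K_D`, `K_B`, `K_D_avail`), and all mortality,
#'   hunting, predation, and growth fluxes.
#' @export
flux_breakdown <- function(state, params) {
  s <- pmax(as.numeric(state[state_names]), 0)
  V <- s[1L]; D <- s[2L]; B <- s[3L]; S <- s[4L]; W <- s[5L]
  if (any(!is.finite(s))) stop("non-finite state components", call. = FALSE)

  pred <- predation_fluxes(D, B, W, params)
  Dpred <- pred[["Dpred"]]; Bpred <- pred[["Bpred"]]
  Dhunt <- hunting_flux(D, params$T_D, params$H_D)
  Bhunt <- hunting_flux(B, params$T_B, params$H_B)
  s2 <- D^2 + B^2
  shareD <- if (s2 > 0) D^2 / s2 else 0
  shareB <- if (s2 > 0) B^2 / s2 else 0
  Ddeath <- natural_mortality_prey(D, shareD, W, params$M_D, params$q)
  Bdeath <- natural_mortality_prey(B, shareB, W, params$M_B, params$q)

  K_D <- carrion_pool(Ddeath, Dhunt, Dpred, params$L_D, params$v)
  u_dd <- boar_carrion_portion(K_D, B, params)
  A_ddot_XB <- boar_intake_capacity(u_dd, params)
  A_tdot_XB <- boar_realized_intake(V, K_D, u_dd, A_ddot_XB, params)
  VconsB <- B * A_tdot_XB * (1 - u_dd)
  BgrowthD <- A_tdot_XB * u_dd * B * params$C_DB

  K_B <- carrion_pool(Bdeath, Bhunt, Bpred, params$L_B, params$v)
  # boar cannot remove more deer carrion than is produced
  K_D_avail <- max(K_D - A_tdot_XB * u_dd * B, 0)
  A_ddot_XS <- scavenger_intake_capacity(V, K_D_avail, K_B, params)

  total_food <- V + K_D_avail + K_B
  VconsS <- if (total_food > 0) S * A_ddot_XS * V / total_food else 0
  dialect <- params$carrion_dialect %||% "literal"
  SgrowthD <- scavenger_carrion_growth(A_ddot_XS, S, K_D_avail,
                                       params$C_XS, total_food, dialect)
  SgrowthB <- scavenger_carrion_growth(A_ddot_XS, S, K_B,
                                       params$C_XS, total_food, dialect)

  VconsD <- D * holling2(V, params$A_VD, params$B_XX)
  c(
    Vgrowth = vegetation_growth(V, params),
    VconsD = VconsD, VconsB = VconsB, VconsS = VconsS,
    u_dd = u_dd, A_ddot_XB = A_ddot_XB, A_tdot_XB = A_tdot_XB,
    A_ddot_XS = A_ddot_XS,
    K_D = K_D, K_B = K_B, K_D_avail = K_D_avail,
    Dpred = Dpred, Bpred = Bpred, Dhunt = Dhunt, Bhunt = Bhunt,
    Ddeath = Ddeath, Bdeath = Bdeath,
    Sdeath = params$M_S * S, Wdeath = params$M_W * W,
    DgrowthV = VconsD * params$C_VD,
    BgrowthV = VconsB * params$C_VB,
    BgrowthD = BgrowthD,
    SgrowthV = VconsS * params$C_VS,
    SgrowthD = SgrowthD, SgrowthB = SgrowthB,
    WgrowthD = Dpred * params$C_XW * (1 - params$v),
    WgrowthB = Bpred * params$C_XW * (1 - params$v)
  )
}

#' Right-hand side of the trophic-web ODE system
#'
#' Assembles the five state derivatives from [flux_breakdown()].
#'
#' @param t Time (years); the system is autonomous, so `t` is unused.
#' @param state Named numeric state vector (`V`, `D`, `B`, `S`, `W`).
#' @param params A [scav_params()] set.
#' @return A list with `derivatives` (named numeric, ton ha^-1 yr^-1)
#'   and `fluxes` (the full [flux_breakdown()]).
#' @export
rhs <- function(t, state, params) {
  f <- flux_breakdown(state, params)
  derivatives <- c(
    V = f[["Vgrowth"]] - f[["VconsD"]] - f[["VconsB"]] - f[["VconsS"]],
    D = f[["DgrowthV"]] - f[["Dpred"]] - f[["Dhunt"]] - f[["Ddeath"]],
    B = f[["BgrowthV"]] + f[["BgrowthD"]] - f[["Bpred"]] - f[["Bhunt"]] -
      f[["Bdeath"]],
    S = f[["SgrowthV"]] + f[["SgrowthD"]] + f[["SgrowthB"]] - f[["Sdeath"]],
    W = f[["WgrowthD"]] + f[["WgrowthB"]] - f[["Wdeath"]]
  )
  list(derivatives = derivatives, fluxes = f)
}
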