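#' Model parameter set
#'
#' Constructs the full parameter set of the five-state trophic-web model
#' (vegetation V, deer D, boar B, facultative scavengers S, wolf W).
#' Defaults are the calibrated literature-derived values used throughout the
#' package; any subset can be overridden by name.
#'
#' Biomass densities are in ton per hectare, time in years, rates in
#' per-year units; conversion factors and diet/leftover fractions are
#' dimensionless and must lie in `[0, 1]`.
#'
#' @param ... Named parameter overrides, e.g. `scav_params(C_VS = 0.05)`.
#'   Unknown names are an error.
#'
#' @return A named list of class `scav_params` with elements:
#' \describe{
#'   \item{R0}{vegetation regrowth rate (yr^-1), default 4}
#'   \item{k0}{vegetation carrying capacity (ton ha^-1), default 10}
#'   \item{A_VD}{max vegetation ingestion per unit deer (yr^-1), default 23.5}
#'   \item{B_XX}{shared half-saturation density for all functional responses
#'     (ton ha^-1), default 10}
#'   \item{C_VD}{vegetation-to-deer conversion factor, default 0.025}
#'   \item{M_D}{deer baseline death rate (yr^-1), default 0.125}
#'   \item{A_XB}{max total ingestion per unit boar at the average carrion
#'     diet (yr^-1), default 20.15}
#'   \item{C_VB}{vegetation-to-boar conversion factor, default 0.055}
#'   \item{M_B}{boar baseline death rate (yr^-1), default 0.08}
#'   \item{u_a}{average deer-carrion portion of the boar diet, default 0.16}
#'   \item{u}{maximum deer-carrion portion of the boar diet, default 0.2}
#'   \item{B_u}{half-saturation of the boar carrion-portion response,
#'     default 0.1}
#'   \item{C_DB}{deer-carrion-to-boar conversion factor, default 0.069}
#'   \item{q}{exponential decay rate of prey natural mortality with
#'     predation pressure, default 10}
#'   \item{T_D, T_B}{hunting target biomasses (ton ha^-1), default 0.5}
#'   \item{H_D, H_B}{hunting rates (yr^-1), default 1}
#'   \item{L_D, L_B}{fractions of hunted biomass left in the field,
#'     default 0.5}
#'   \item{M_S}{scavenger death rate (yr^-1), default 0.2}
#'   \item{C_XS}{carrion-to-scavenger conversion factor, default 0.1}
#'   \item{M_W}{wolf death rate (yr^-1), default 0.2}
#'   \item{r}{max predation rate per unit wolf (yr^-1), default 96.6}
#'   \item{v}{fraction of predated biomass not consumed by wolves,
#'     default 0.32}
#'   \item{C_XW}{prey-to-wolf conversion factor, default 0.038}
#'   \item{A_XS}{max ingestion per unit scavenger (yr^-1), default 20}
#'   \item{C_VS}{vegetation-to-scavenger conversion factor, default 0.036}
#'   \item{carrion_dialect}{how scavenger carrion intake is capped:
#'     `"literal"` (default) caps each carrion channel at its own
#'     availability; `"proportional"` first apportions the scavengers'
#'     total intake capacity across food sources}
#' }
#'
#' @examples
#' p <- scav_params()
#' p$k0
#' scav_params(C_VS = 1.3 * scav_params()$C_VS)$C_VS
#' @export
scav_params <- function(...) {
  p <- list(
    R0 = 4, k0 = 10,
    A_VD = 23.5, B_XX = 10, C_VD = 0.025, M_D = 0.125,
    A_XB = 20.15, C_VB = 0.055, M_B = 0.08,
    u_a = 0.16, u = 0.2, B_u = 0.1, C_DB = 0.069,
    q = 10,
    T_D = 0.5, H_D = 1, L_D = 0.5,
    T_B = 0.5, H_B = 1, L_B = 0.5,
    M_S = 0.2, C_XS = 0.1,
    M_W = 0.2, r = 96.6, v = 0.32, C_XW = 0.038,
    A_XS = 20, C_VS = 0.036,
    carrion_dialect = "literal"
  )
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
}

# parameter names whose value is a fraction/conversion bounded by 1
fraction_params <- c(
  "C_VD", "C_VB", "C_DB", "C_XS", "C_XW", "C_VS",
  "u_a", "u", "L_D", "L_B", "v"
)

#' Validate a parameter set
#'
#' Checks non-negativity of all rates and densities, `[0, 1]` bounds on
#' fractions and conversion factors, the diet-portion ordering
#' `u_a <= u <= 1`, and strict positivity of the half-saturation constants
#' and the carrying capacity.
#'
#' @param p A list of parameters as produced by [scav_params()].
#' @return `p`, classed `scav_params`, invisibly usable in pipelines.
#' @export
validate_params <- function(p) {
  dialect <- p$carrion_dialect %||% "literal"
  if (!dialect %in% c("literal", "proportional")) {
    stop("carrion_dialect must be 'literal' or 'proportional'", call. = FALSE)
  }
  num <- p[setdiff(names(p), "carrion_dialect")]
  vals <- unlist(num)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("all parameters must be finite numbers", call. = FALSE)
  }
  bad <- names(vals)[vals < 0]
  if (length(bad)) {
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  over <- intersect(fraction_params, names(vals))
  bad <- over[vals[over] > 1]
  if (length(bad)) {
    stop("parameter(s) must be <= 1: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(p$u_a) && !is.null(p$u) && p$u_a > p$u) {
    stop("u_a must not exceed u", call. = FALSE)
  }
  for (nm in c("B_u", "B_XX", "k0")) {
    if (!is.null(p[[nm]]) && p[[nm]] <= 0) {
      stop(nm, " must be > 0", call. = FALSE)
    }
  }
  structure(p, class = "scav_params")
}

#' @export
print.scav_params <- function(x, ...) {
  cat("<scav_params>\n")
  num <- x[setdiff(names(x), "carrion_dialect")]
  print(tibble::tibble(parameter = names(num), value = unlist(num)), n = Inf)
  cat("carrion dialect:", x$carrion_dialect, "\n")
  invisible(x)
}

#' Derive an ingestion or predation rate from life-history values
#'
#' Converts an individual's annual food requirement and mean body weight
#' into a per-biomass maximum intake rate, optionally corrected for the
#' portion of killed biomass that the consumer does not eat (so that the
#' rate refers to biomass removed, not biomass ingested).
#'
#' @param annual_food_req Individual food requirement (kg per year).
#' @param mean_weight Mean individual body weight (kg); must be positive.
#' @param unconsumed_fraction Fraction of removed biomass not consumed,
#'   in `[0, 1)`; default 0.
#' @return The rate in yr^-1: `(annual_food_req / mean_weight) /
#'   (1 - unconsumed_fraction)`.
#' @examples
#' derive_rate_from_life_history(986, 42)          # deer vegetation intake
#' derive_rate_from_life_history(1209, 60)         # boar total intake
#' derive_rate_from_life_history(1642.5, 25, 0.32) # wolf predation rate
#' @export
derive_rate_from_life_history <- function(annual_food_req, mean_weight,
                                          unconsumed_fraction = 0) {
  if (any(mean_weight <= 0)) stop("mean_weight must be > 0", call. = FALSE)
  if (any(unconsumed_fraction < 0 | unconsumed_fraction >= 1)) {
    stop("unconsumed_fraction must be in [0, 1)", call. = FALSE)
  }
  (annual_food_req / mean_weight) / (1 - unconsumed_fraction)
}

#' Scale one parameter by a multiplier
#'
#' Returns a copy of `params` with the named parameter multiplied by
#' `factor`. Fractions and conversion factors are capped at 1 so that a
#' scaled parameter set remains valid.
#'
#' @param params A [scav_params()] set.
#' @param name Parameter name to scale.
#' @param factor Positive multiplier.
#' @return A new validated `scav_params` object.
#' @examples
#' scale_parameter(scav_params(), "C_VS", 1.3)$C_VS
#' @export
scale_parameter <- function(params, name, factor) {
  if (length(name) != 1L || !name %in% names(params) ||
      name == "carrion_dialect") {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  params[[name]] <- params[[name]] * factor
  if (name %in% fraction_params) {
    params[[name]] <- min(params[[name]], 1)
  }
  validate_params(params)
}

#' Read or write a parameter set as a flat YAML mapping
#'
#' The on-disk format is a flat key-to-value mapping whose keys are the
#' model symbols (`R0`, `k0`, `A_VD`, ...). Missing keys take their
#' defaults; unknown keys are an error.
#'
#' @param path File path.
#' @param params A `scav_params` object (for writing).
#' @return `read_params()` returns a validated `scav_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  scav_params(raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
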