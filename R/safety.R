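# Chemical safety scoring for the CO2 + ethanol-water co-solvent system.
# Mixture properties: mole-fraction-linear boiling point and Hansen
# parameter, and a Le Chatelier flash point (the temperature T at which
# sum_i x_i * gamma_i * Psat_i(T) / Psat_i(T_fp,i) = 1 over the flammable
# components). Four logistic hazard scores (flammability, toxicity,
# reactivity, explosiveness), each in [0, 100], sum to the Chemical
# Safety Total Score (CSTS), higher = more hazardous.

required_component_fields <- c("boiling_point", "antoine", "hansen_delta",
                               "density", "molar_mass", "flammable")

validate_component <- function(comp, name) {
  missing <- setdiff(required_component_fields, names(comp))
  if (length(missing))
    stop("component '", name, "' is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(comp$antoine) != 3L)
    stop("component '", name, "': antoine must be 3 constants (A, B, C)",
         call. = FALSE)
  if (!is.null(comp$nfpa_reactivity) &&
      !(comp$nfpa_reactivity %in% 0:4))
    stop("component '", name, "': nfpa_reactivity must be an integer 0-4",
         call. = FALSE)
  if (!is.null(comp$lel) && !is.null(comp$uel) &&
      !(comp$lel >= 0 && comp$lel <= comp$uel))
    stop("component '", name, "': need 0 <= lel <= uel", call. = FALSE)
  if (isTRUE(comp$flammable) && is.null(comp$flash_point))
    stop("component '", name, "': flammable components need a flash_point",
         call. = FALSE)
  comp$name <- name
  comp
}

#' Load solvent component properties
#'
#' Reads the per-component chemical properties (boiling point, flash
#' point, Antoine vapour-pressure constants in the mmHg/degC convention,
#' Hansen parameter, TLV-STEL, NFPA reactivity, explosive limits,
#' density, molar mass) plus the binary van Laar activity constants from
#' a YAML file. The packaged default describes ethanol (first component,
#' the "1" of the van Laar pair) and water.
#'
#' @param path YAML file; defaults to the packaged `solvents.yaml`.
#' @return Object of class `solvent_db`: list with `components` (named
#'   list of validated component property lists, in file order),
#'   `van_laar` (`a12`, `a21` for the first/second listed components) and
#'   `activity_model` default.
#' @export
solvent_db <- function(path = fixture_path("solvents.yaml")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$components) || length(raw$components) < 2L)
    stop("solvent config needs at least two components", call. = FALSE)
  comps <- mapply(validate_component, raw$components, names(raw$components),
                  SIMPLIFY = FALSE)
  structure(list(components = comps, van_laar = raw$van_laar,
                 activity_model = raw$activity_model %||% "van_laar"),
            class = "solvent_db")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Volume to mole fractions for a water-in-cosolvent blend
#'
#' Converts a % v/v water content into mole fractions using component
#' densities and molar masses: moles_i = volume_i * density_i /
#' molar_mass_i, normalized. Densities are taken at the conditions they
#' were tabulated for (20 degC handbook values in the packaged config).
#'
#' @param water_pct_vv Water content, % v/v in the blend (0-100).
#' @param water,cosolvent Component property lists with `density` (g/ml)
#'   and `molar_mass` (g/mol).
#' @return Named numeric: `x_water`, `x_cosolvent` (sum to 1).
#' @examples
#' db <- solvent_db()
#' vv_to_mole_fraction(30, db$components$water, db$components$ethanol)
#' @export
vv_to_mole_fraction <- function(water_pct_vv, water, cosolvent) {
  stopifnot(water_pct_vv >= 0, water_pct_vv <= 100)
  for (c_ in list(water, cosolvent))
    if (is.null(c_$density) || is.null(c_$molar_mass))
      stop("components need density and molar_mass for the volume-to-mole conversion",
           call. = FALSE)
  mw <- water_pct_vv * water$density / water$molar_mass
  mc <- (100 - water_pct_vv) * cosolvent$density / cosolvent$molar_mass
  x <- c(x_water = mw, x_cosolvent = mc) / (mw + mc)
  x
}

#' Specify a binary co-solvent mixture
#'
#' @param water_pct_vv Water content in the co-solvent, % v/v.
#' @param db A [solvent_db()]; must contain a `water` component and one
#'   other (the co-solvent).
#' @param mole_fractions Optional named numeric overriding the derived
#'   mole fractions (names = component names, summing to 1); the
#'   volume-based conversion is skipped.
#' @return Object of class `mixture_spec`: components (co-solvent first,
#'   matching the van Laar constant order of the config), `water_pct_vv`
#'   and mole fractions `x` (named by component).
#' @export
mixture_spec <- function(water_pct_vv, db = solvent_db(),
                         mole_fractions = NULL) {
  stopifnot(inherits(db, "solvent_db"))
  nm <- names(db$components)
  if (!"water" %in% nm) stop("solvent_db must contain 'water'", call. = FALSE)
  cos_name <- setdiff(nm, "water")[1]
  if (is.null(mole_fractions)) {
    xf <- vv_to_mole_fraction(water_pct_vv, db$components$water,
                              db$components[[cos_name]])
    x <- stats::setNames(c(xf[["x_cosolvent"]], xf[["x_water"]]),
                         c(cos_name, "water"))
  } else {
    stopifnot(abs(sum(mole_fractions) - 1) < 1e-8,
              all(names(mole_fractions) %in% nm))
    x <- mole_fractions[c(cos_name, "water")]
  }
  structure(list(components = db$components[c(cos_name, "water")],
                 water_pct_vv = water_pct_vv, x = x,
                 van_laar = db$van_laar),
            class = "mixture_spec")
}

#' Mixture boiling point (mole-fraction linear)
#'
#' @param mix A [mixture_spec()].
#' @return Boiling point estimate in degC, a convex combination of the
#'   component boiling points.
#' @export
mixture_boiling_point <- function(mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  sum(mix$x * vapply(mix$components, `[[`, numeric(1), "boiling_point"))
}

#' Mixture Hansen solubility parameter (mole-fraction linear)
#'
#' @param mix A [mixture_spec()].
#' @return Hansen parameter in MPa^0.5.
#' @export
hansen_mix <- function(mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  sum(mix$x * vapply(mix$components, `[[`, numeric(1), "hansen_delta"))
}

# Antoine vapour pressure, mmHg/degC convention
antoine_pressure <- function(antoine, temp_c) {
  10^(antoine[1] - antoine[2] / (antoine[3] + temp_c))
}

# van Laar activity coefficients for the binary (component 1 = first in
# the mixture, the co-solvent). Composition-dependent, temperature-free.
van_laar_gamma <- function(x1, a12, a21) {
  x2 <- 1 - x1
  if (x1 <= 0) return(c(exp(a12), 1))
  if (x2 <= 0) return(c(1, exp(a21)))
  d <- a12 * x1 + a21 * x2
  c(exp(a12 * (a21 * x2 / d)^2), exp(a21 * (a12 * x1 / d)^2))
}

#' Le Chatelier mixture flash point
#'
#' Solves for the temperature at which the flammable components' scaled
#' vapour pressures reach the ignitable threshold:
#' `sum_i x_i * gamma_i * Psat_i(T) / Psat_i(T_fp,i) = 1`, where the sum
#' runs over flammable components only (water contributes zero). The
#' activity coefficients come from the van Laar model by default
#' (ethanol-water is strongly non-ideal); `"ideal"` sets gamma = 1.
#'
#' @param mix A [mixture_spec()].
#' @param activity_model `"van_laar"` (default) or `"ideal"`.
#' @param bracket Temperature search interval in degC.
#' @param tol Solver tolerance on temperature (degC).
#' @return Flash point in degC.
#' @examples
#' db <- solvent_db()
#' mixture_flash_point(mixture_spec(20, db))
#' @export
mixture_flash_point <- function(mix, activity_model = c("van_laar", "ideal"),
                                bracket = c(-50, 150), tol = 1e-6) {
  stopifnot(inherits(mix, "mixture_spec"))
  activity_model <- match.arg(activity_model)
  flam <- vapply(mix$components, function(c_) isTRUE(c_$flammable), logical(1))
  if (!any(flam))
    stop("no flammable component: flash point undefined", call. = FALSE)

  gamma <- if (activity_model == "van_laar") {
    vl <- mix$van_laar
    if (is.null(vl$a12) || is.null(vl$a21))
      stop("van Laar constants missing from the solvent configuration",
           call. = FALSE)
    van_laar_gamma(mix$x[1], vl$a12, vl$a21)
  } else rep(1, length(mix$x))

  lhs <- function(temp_c) {
    s <- 0
    for (i in which(flam)) {
      c_ <- mix$components[[i]]
      s <- s + mix$x[i] * gamma[i] *
        antoine_pressure(c_$antoine, temp_c) /
        antoine_pressure(c_$antoine, c_$flash_point)
    }
    s - 1
  }
  lo <- lhs(bracket[1]); hi <- lhs(bracket[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop(sprintf("no flash point in bracket [%g, %g] degC", bracket[1],
                 bracket[2]), call. = FALSE)
  stats::uniroot(lhs, bracket, tol = tol)$root
}

#' Logistic hazard scores
#'
#' Each score maps a hazard-relevant property onto [0, 100] through a
#' calibrated logistic: flammability decreases with flash point
#' (`100 * (1 - 1/(1 + 3.37 e^(-0.024 x)))`, x in degC), toxicity
#' decreases with the TLV-STEL (`1 + 403.4288 e^(-0.012 x)`, x in ppm),
#' reactivity increases with the NFPA instability rating
#' (`100 / (1 + 270.43 e^(-2.8 x))`), and explosiveness increases with
#' the explosive range (`100 / (1 + 1096.63 e^(-0.14 x))`, x = UEL - LEL
#' in vol %). Higher scores mean more hazardous.
#'
#' @param flash_point_c Flash point in degC.
#' @return Score in [0, 100].
#' @export
score_flammability <- function(flash_point_c) {
  100 * (1 - 1 / (1 + 3.37 * exp(-0.024 * flash_point_c)))
}

#' @rdname score_flammability
#' @param tlv_stel_ppm Short-term exposure limit in ppm.
#' @export
score_toxicity <- function(tlv_stel_ppm) {
  100 * (1 - 1 / (1 + 403.4288 * exp(-0.012 * tlv_stel_ppm)))
}

#' @rdname score_flammability
#' @param nfpa NFPA reactivity/instability rating, integer 0-4.
#' @export
score_reactivity <- function(nfpa) {
  stopifnot(all(nfpa %in% 0:4))
  100 / (1 + 270.43 * exp(-2.8 * nfpa))
}

#' @rdname score_flammability
#' @param uel_minus_lel Explosive range UEL - LEL in vol %; use 0 for a
#'   component with no explosive range.
#' @export
score_explosiveness <- function(uel_minus_lel) {
  stopifnot(all(uel_minus_lel >= 0))
  100 / (1 + 1096.63 * exp(-0.14 * uel_minus_lel))
}

#' Chemical Safety Total Score for a co-solvent composition
#'
#' Computes the four logistic hazard scores and their sum (CSTS) for a
#' water-in-ethanol co-solvent. Only the flammability score varies with
#' composition, through the Le Chatelier mixture flash point; toxicity,
#' reactivity and explosiveness use the flammable component's parameters
#' unchanged (water carries no TLV/NFPA-flammability relevance), which
#' reproduces the observed pattern that those three scores are flat
#' across co-solvent ratios.
#'
#' @param water_pct_vv Water content in ethanol, % v/v.
#' @param db A [solvent_db()].
#' @param activity_model Passed to [mixture_flash_point()].
#' @param flash_point_method `"mixture"` (default, Le Chatelier solve) or
#'   `"pure_cosolvent"` (the flammable component's own flash point).
#' @return Object of class `safety_scores`: `s_fl`, `s_tx`, `s_r`,
#'   `s_exp` (each in [0, 100]), `csts` (their sum, in [0, 400]) and
#'   `inputs_used` (the x fed to each logistic).
#' @examples
#' csts(20)
#' @export
csts <- function(water_pct_vv, db = solvent_db(),
                 activity_model = c("van_laar", "ideal"),
                 flash_point_method = c("mixture", "pure_cosolvent")) {
  activity_model <- match.arg(activity_model)
  flash_point_method <- match.arg(flash_point_method)
  mix <- mixture_spec(water_pct_vv, db)
  flam <- mix$components[[which(vapply(mix$components, function(c_)
    isTRUE(c_$flammable), logical(1)))[1]]]

  fp <- if (flash_point_method == "mixture")
    mixture_flash_point(mix, activity_model)
  else flam$flash_point

  tlv <- flam$tlv_stel %||% NA_real_
  nfpa <- flam$nfpa_reactivity %||% 0L
  range_pct <- if (is.null(flam$uel) || is.null(flam$lel)) 0
               else flam$uel - flam$lel
  if (is.na(tlv))
    stop("flammable component lacks a TLV-STEL; cannot score toxicity",
         call. = FALSE)

  s_fl <- score_flammability(fp)
  s_tx <- score_toxicity(tlv)
  s_r <- score_reactivity(nfpa)
  s_exp <- score_explosiveness(range_pct)
  structure(list(
    s_fl = s_fl, s_tx = s_tx, s_r = s_r, s_exp = s_exp,
    csts = s_fl + s_tx + s_r + s_exp,
    inputs_used = list(flash_point_c = fp, tlv_stel_ppm = tlv, nfpa = nfpa,
                       uel_minus_lel = range_pct,
                       mole_fractions = mix$x,
                       activity_model = activity_model,
                       flash_point_method = flash_point_method),
    water_pct_vv = water_pct_vv
  ), class = "safety_scores")
}

#' @export
print.safety_scores <- function(x, ...) {
  cat(sprintf("Chemical safety scores at %.3g%% v/v water in co-solvent\n",
              x$water_pct_vv))
  cat(sprintf("  S_FL = %6.2f (flash point %.2f degC)\n", x$s_fl,
              x$inputs_used$flash_point_c))
  cat(sprintf("  S_TX = %6.2f  S_R = %6.2f  S_EXP = %6.2f\n",
              x$s_tx, x$s_r, x$s_exp))
  cat(sprintf("  CSTS = %.2f / 400\n", x$csts))
  invisible(x)
}
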