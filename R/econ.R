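# Operational cost model for the lab-scale SFE unit. Only variable
# operating costs are covered: raw materials (CRM), utilities (CUT) and
# labour (COL); fixed capital and waste treatment are out of scope. The
# three components combine as
#
#   OC = 2.73 * COL + 1.23 * (CUT + CRM)     [RM/year]
#
# the simplified operating-cost line of the Turton et al. costing scheme
# with fixed costs dropped.

#' Operational cost configuration
#'
#' Builds and validates the configuration for [operational_cost()]. All
#' arguments have defaults describing the case-study unit (Malaysian
#' Ringgit prices; 240 operating days/year, one 2-hour run per day,
#' process equipment powered 8 h/day and the chiller on continuous
#' 24-hour duty). The paper trail for the consumption assumptions is in
#' the package vignette.
#'
#' @param sample_price RM/kg of dried herb.
#' @param ethanol_price,bottle_volume RM per bottle and bottle volume (L).
#' @param co2_price,cylinder_mass RM per cylinder and cylinder mass (kg).
#' @param electricity_tariff Electricity price; unit given by
#'   `tariff_unit` (`"RM/kWh"`, or `"sen/kWh"` which is divided by 100 on
#'   load with a message).
#' @param tariff_unit `"RM/kWh"` (default) or `"sen/kWh"`.
#' @param labour_salary RM/month per operator.
#' @param n_operators Number of operators.
#' @param equipment_power Named vector of device powers in kW.
#' @param annual_hours Operating hours per year for process equipment.
#' @param equipment_hours Optional named vector of per-device hours
#'   overriding `annual_hours` (e.g. a continuously running chiller).
#' @param runs_per_year Extraction runs per year.
#' @param sample_mass kg of herb per run.
#' @param co2_mass kg of CO2 per run.
#' @param cosolvent_volume L of co-solvent (ethanol + water) per run.
#' @param run_duration Hours per run (metadata; utility hours are set by
#'   `annual_hours`/`equipment_hours`).
#' @param water_pct Default % v/v water in the co-solvent; only the
#'   ethanol share of the co-solvent volume is priced.
#' @return Object of class `cost_config` (a validated list).
#' @seealso [read_cost_config()] to load the same schema from YAML.
#' @export
cost_config <- function(sample_price = 70, ethanol_price = 86,
                        bottle_volume = 2.5, co2_price = 224,
                        cylinder_mass = 30, electricity_tariff = 0.365,
                        tariff_unit = "RM/kWh", labour_salary = 1800,
                        n_operators = 1,
                        equipment_power = c(chiller = 13.82, co2_pump = 0.75,
                                            cosolvent_pump = 0.37, bpr = 0.50,
                                            oven = 0.80, ambient = 0.60),
                        annual_hours = 1920,
                        equipment_hours = c(chiller = 5760),
                        runs_per_year = 240, sample_mass = 0.003,
                        co2_mass = 1.0, cosolvent_volume = 0.10,
                        run_duration = 2.0, water_pct = 20) {
  tariff_unit <- match.arg(tariff_unit, c("RM/kWh", "sen/kWh"))
  if (tariff_unit == "sen/kWh") {
    message("converting electricity tariff from sen/kWh to RM/kWh (/100)")
    electricity_tariff <- electricity_tariff / 100
    tariff_unit <- "RM/kWh"
  }
  cfg <- list(
    sample_price = sample_price, ethanol_price = ethanol_price,
    bottle_volume = bottle_volume, co2_price = co2_price,
    cylinder_mass = cylinder_mass, electricity_tariff = electricity_tariff,
    tariff_unit = tariff_unit, labour_salary = labour_salary,
    n_operators = n_operators, equipment_power = unlist(equipment_power),
    annual_hours = annual_hours,
    equipment_hours = if (is.null(equipment_hours)) NULL else unlist(equipment_hours),
    runs_per_year = runs_per_year, sample_mass = sample_mass,
    co2_mass = co2_mass, cosolvent_volume = cosolvent_volume,
    run_duration = run_duration, water_pct = water_pct
  )
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(num < 0))
    stop("cost configuration values must be non-negative; offending: ",
         paste(names(num)[num < 0], collapse = ", "), call. = FALSE)
  if (!(water_pct >= 0 && water_pct <= 100))
    stop("water_pct must be in [0, 100]", call. = FALSE)
  structure(cfg, class = "cost_config")
}

#' Load a cost configuration from YAML
#'
#' @param path YAML file with the [cost_config()] field names; omitted
#'   fields take the package defaults. The packaged default lives at
#'   `system.file("extdata", "cost_default.yaml", package = "sfeperf")`.
#' @return A `cost_config`.
#' @export
read_cost_config <- function(path = fixture_path("cost_default.yaml")) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cost_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown cost config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(cost_config, vals)
}

device_hours <- function(cfg) {
  h <- rep(cfg$annual_hours, length(cfg$equipment_power))
  names(h) <- names(cfg$equipment_power)
  if (!is.null(cfg$equipment_hours)) {
    idx <- intersect(names(cfg$equipment_hours), names(h))
    h[idx] <- cfg$equipment_hours[idx]
  }
  h
}

#' Annual operational cost and its breakdown
#'
#' Raw materials (CRM) annualize the per-run herb, CO2 and ethanol
#' consumption (the water share of the co-solvent is free); utilities
#' (CUT) sum device power x operating hours x tariff; labour (COL) is
#' 12 x monthly salary x operators. They combine as
#' `OC = 2.73 * COL + 1.23 * (CUT + CRM)` in RM/year.
#'
#' @param cfg A [cost_config()].
#' @param water_pct Optional % v/v water in ethanol overriding the
#'   config; the only per-condition knob of the default model (pressure
#'   and temperature are assumed not to change the per-run energy).
#' @return Object of class `cost_breakdown`: list with `crm`, `cut`,
#'   `col`, `oc` (RM/year) and `fractions` (shares of CRM+CUT+COL).
#' @examples
#' operational_cost(cost_config())
#' @export
operational_cost <- function(cfg, water_pct = NULL) {
  stopifnot(inherits(cfg, "cost_config"))
  w <- if (is.null(water_pct)) cfg$water_pct else water_pct
  if (w < 0 || w > 100) stop("water_pct must be in [0, 100]", call. = FALSE)

  ethanol_l_per_run <- cfg$cosolvent_volume * (1 - w / 100)
  crm <- cfg$runs_per_year * (
    cfg$sample_mass * cfg$sample_price +
      ethanol_l_per_run * cfg$ethanol_price / cfg$bottle_volume +
      cfg$co2_mass * cfg$co2_price / cfg$cylinder_mass
  )
  cut <- sum(cfg$equipment_power * device_hours(cfg)) * cfg$electricity_tariff
  col <- 12 * cfg$labour_salary * cfg$n_operators
  oc <- 2.73 * col + 1.23 * (cut + crm)

  total <- crm + cut + col
  fractions <- if (total > 0) c(crm = crm, cut = cut, col = col) / total
               else c(crm = NA_real_, cut = NA_real_, col = NA_real_)
  structure(list(crm = crm, cut = cut, col = col, oc = oc,
                 fractions = fractions, water_pct = w),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Operational cost (water %.3g%% v/v): OC = %.2f RM/year\n",
              x$water_pct, x$oc))
  comp <- c(CRM = x$crm, CUT = x$cut, COL = x$col)
  for (i in seq_along(comp))
    cat(sprintf("  %s = %10.2f RM/year (%.1f%%)\n", names(comp)[i], comp[i],
                100 * x$fractions[i]))
  invisible(x)
}

#' Per-device utility cost itemization
#'
#' @param cfg A [cost_config()].
#' @return Data frame (one row per device, sorted by cost, descending)
#'   with power, hours, annual cost and share of the utility bill; the
#'   top device is first.
#' @examples
#' utility_itemization(cost_config())[1, ]  # the chiller dominates
#' @export
utility_itemization <- function(cfg) {
  stopifnot(inherits(cfg, "cost_config"))
  hrs <- device_hours(cfg)
  cost <- cfg$equipment_power * hrs * cfg$electricity_tariff
  out <- data.frame(device = names(cfg$equipment_power),
                    power_kw = unname(cfg$equipment_power),
                    hours = unname(hrs),
                    cost_rm_year = unname(cost))
  out$share <- if (sum(cost) > 0) out$cost_rm_year / sum(cost) else NA_real_
  out[order(-out$cost_rm_year), , drop = FALSE]
}
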