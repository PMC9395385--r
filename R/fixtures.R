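# Packaged case-study data: the Gynura procumbens SFE central composite
# design (20 runs of pressure, temperature, water-in-ethanol with measured
# yield and solubility), reference solvent-mixture densities, and the
# qualitative equipment-hazard listings.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "sfeperf")
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Factor specifications of the case-study design
#'
#' Pressure (centre 21 MPa, factorial 18/24, axial 17/25), temperature
#' (centre 65 C, factorial 60/70, axial 58/72) and water content in
#' ethanol (centre 20 % v/v, factorial 10/30, axial 7/33). Coding steps
#' are the factorial half-ranges: 3 MPa, 5 C, 10 %. Axial levels are the
#' printed values; their coded distances are not equal across factors
#' (1.33, 1.40, 1.30), so the design is not rotatable.
#'
#' @return List of three [factor_spec()] objects.
#' @export
gp_factors <- function() {
  list(
    factor_spec("pressure_mpa", "MPa", center = 21, step = 3,
                axial_low = 17, axial_high = 25),
    factor_spec("temperature_c", "°C", center = 65, step = 5,
                axial_low = 58, axial_high = 72),
    factor_spec("water_pct", "% v/v", center = 20, step = 10,
                axial_low = 7, axial_high = 33)
  )
}

#' Case-study experiment table
#'
#' The 20 CCD runs with measured responses: overall yield (g/g %) and
#' solubility of the extract in CO2 (g/g, scaled by 10^3), in the original
#' run order (8 factorial, 6 axial, 6 centre replicates).
#'
#' @return Data frame with columns `run_id`, `pressure_mpa`,
#'   `temperature_c`, `water_pct`, `ccd_role`, `yield_pct`,
#'   `solubility_mg_g`.
#' @export
gp_runs <- function() {
  df <- utils::read.csv(fixture_path("gp_ccd_runs.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 20L)
  df
}

#' Case-study design as a `ccd_design`
#'
#' The packaged 20-run design in its printed run order (not the
#' factorial-axial-centre order that [ccd_design()] generates).
#'
#' @return A `ccd_design` object.
#' @export
gp_design <- function() {
  df <- gp_runs()
  new_ccd_design(gp_factors(),
                 df[c("run_id", "pressure_mpa", "temperature_c",
                      "water_pct", "ccd_role")])
}

#' Case-study responses
#'
#' @param response `"yield"` (g/g %) or `"solubility"` (g/g x 10^-3).
#' @return Data frame with `run_id` and `value`.
#' @export
gp_response <- function(response = c("yield", "solubility")) {
  response <- match.arg(response)
  df <- gp_runs()
  col <- if (response == "yield") "yield_pct" else "solubility_mg_g"
  data.frame(run_id = df$run_id, value = df[[col]])
}

#' Reference densities of water, ethanol and their mixtures
#'
#' Densities (g/ml x 10^-3 as printed, i.e. divide by 1000 for g/ml) at
#' 65 C and 17-25 MPa for water, ethanol, and 70/80/90 % v/v
#' ethanol-water. Reference data only; the safety module's default
#' volume-to-mole conversion uses 20 C handbook densities from the
#' solvent configuration.
#'
#' @return Data frame, one row per (temperature, pressure).
#' @export
gp_densities <- function() {
  utils::read.csv(fixture_path("gp_densities.csv"), stringsAsFactors = FALSE)
}

#' Qualitative equipment hazard listing
#'
#' Static risk register for the lab-scale SFE unit: the main pressure
#' equipment with its failure scenarios (BLEVE, overpressure) and hazard
#' types, plus the secondary-scenario chains that can follow a BLEVE.
#' These are descriptive only and take no part in the CSTS scoring, which
#' covers the co-solvent chemistry.
#'
#' @return List of two data frames: `equipment_risks` and
#'   `bleve_scenarios`.
#' @export
hazard_tables <- function() {
  equipment_risks <- data.frame(
    equipment = c("CO2 storage tank", "CO2 pump", "Co-solvent pump",
                  "Pressure vessel"),
    risk = c("BLEVE", "Overpressure", "Overpressure", "BLEVE; Overpressure"),
    hazard_types = c(
      "Chemical; Thermodynamic; Biological",
      "Chemical; Biological",
      "Chemical",
      "Chemical; Thermodynamic; Mechanical"),
    stringsAsFactors = FALSE
  )
  bleve_scenarios <- data.frame(
    main_scenario = "BLEVE",
    vector = c(rep("Overpressure", 5L), "BLEVE"),
    secondary_scenario = c("Flash fire", "Pool fire", "Jet fire",
                           "Fire ball", "Vapour cloud explosion (VCE)",
                           "Toxic release"),
    stringsAsFactors = FALSE
  )
  list(equipment_risks = equipment_risks, bleve_scenarios = bleve_scenarios)
}

#' MD5 checksums of the packaged fixture files
#'
#' The fixtures are verbatim transcriptions and must not drift; the test
#' suite compares these sums against frozen values.
#'
#' @return Named character vector of MD5 sums.
#' @export
fixture_checksums <- function() {
  files <- c("gp_ccd_runs.csv", "gp_densities.csv",
             "cost_default.yaml", "solvents.yaml")
  sums <- tools::md5sum(vapply(files, fixture_path, character(1)))
  names(sums) <- files
  sums
}
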