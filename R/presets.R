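#' Energy equivalent of oxygen
#'
#' Joules per mg of O2 used when converting respirometry rates to energetic
#' equivalents (1 mg O2 = 14.06 J).
#' @export
oxygen_joule <- 14.06

#' Summary parameters of a published thermal performance curve
#'
#' @param e_a activation energy, eV.
#' @param topt optimum temperature, degrees Celsius.
#' @param mrp maximal rate of performance (rate at `topt`), in `units`.
#' @param e_h deactivation energy, eV; must exceed `e_a`.
#' @param units character tag for the rate unit.
#' @param oxygen_factor multiplier converting one unit of this rate into
#'   mg O2 L^-1 min^-1 per individual (or per cell); used by the synthetic
#'   assay generator to translate per-capita rates into oxygen-probe slopes.
#' @return list of class `tpc_summary`.
#' @export
tpc_summary <- function(e_a, topt, mrp, e_h, units = "rate", oxygen_factor = 1) {
  if (e_a <= 0 || e_h <= e_a) stop("require e_h > e_a > 0")
  if (mrp <= 0) stop("mrp must be positive")
  if (topt < 0 || topt > 60) stop("topt outside plausible 0-60 C range")
  structure(list(e_a = e_a, topt = topt, mrp = mrp, e_h = e_h,
                 units = units, oxygen_factor = oxygen_factor),
            class = "tpc_summary")
}

#' Summary of a linear (or flat) rate-temperature response
#'
#' Exactly one of `intercept` or `tc_anchor` must be given. A `tc_anchor`
#' pins the otherwise unreported intercept at the crossover temperature where
#' the gain line equals a loss curve (see [derive_linear_intercept()]).
#'
#' @param slope rate units per degree Celsius (0 for a flat response).
#' @param intercept rate units, or `NULL` when anchored.
#' @param tc_anchor crossover temperature (Celsius), or `NULL`.
#' @param zero_slope logical; `TRUE` marks a slope constrained to zero.
#' @param units character unit tag.
#' @return list of class `linear_summary`.
#' @export
linear_summary <- function(slope, intercept = NULL, tc_anchor = NULL,
                           zero_slope = FALSE, units = "rate") {
  if (is.null(intercept) == is.null(tc_anchor)) {
    stop("provide exactly one of `intercept` or `tc_anchor`")
  }
  if (zero_slope && slope != 0) stop("zero_slope = TRUE requires slope = 0")
  structure(list(slope = slope, intercept = intercept, tc_anchor = tc_anchor,
                 zero_slope = zero_slope, units = units),
            class = "linear_summary")
}

#' Pin a linear gain line's intercept at a crossover temperature
#'
#' Solves `intercept = loss(tc_anchor) - slope * tc_anchor`, so that the
#' gain-to-loss ratio equals exactly 1 at the anchor temperature.
#'
#' @param linear a [linear_summary()] with a `tc_anchor`.
#' @param loss_fun function of temperature (Celsius) returning the loss rate
#'   in the same units as the gain line.
#' @return the derived intercept (rate units).
#' @export
derive_linear_intercept <- function(linear, loss_fun) {
  if (!is.null(linear$intercept)) return(linear$intercept)
  if (is.null(linear$tc_anchor)) stop("linear summary has neither intercept nor tc_anchor")
  loss_at <- loss_fun(linear$tc_anchor)
  if (!is.finite(loss_at)) stop("loss curve not evaluable at the anchor temperature")
  loss_at - linear$slope * linear$tc_anchor
}

default_noise_model <- function() {
  list(
    rate_cv = 0.10,          # multiplicative CV on the per-capita rate signal
    slope_noise_sd = 0,      # extra additive sd on oxygen slopes, mg O2 L^-1 min^-1
    control_noise_frac = 0.02, # additive control-slope sd, fraction of peak signal
    control_drift_frac = 0.02, # common per-block drift sd, fraction of peak signal
    density_cv = 0.05,       # multiplicative CV on measured cell densities
    control_growth = 0.02,   # fractional control density change over the assay
    is_noise_sd = 0.008      # residual sd of synthetic interaction-strength records
  )
}

#' Assemble a synthetic-assay scenario
#'
#' Bundles the published rate summaries, design constants and noise model
#' that parameterise the synthetic data generator for one species (resource)
#' or one consumer-resource pair.
#'
#' @param species_name organism (or pair) label.
#' @param rate_presets named list mapping rate kinds
#'   (`net_photosynthesis`, `respiration`, `ingestion`) to [tpc_summary()] or
#'   [linear_summary()] objects.
#' @param assimilation_efficiency fraction of ingested energy assimilated,
#'   in (0, 1].
#' @param per_cell_energy energy content of one resource cell, J.
#' @param initial_density resource density at assay start, cells per mL.
#' @param n_consumers consumers per treatment vial.
#' @param assay_temperatures assay temperatures, Celsius (distinct).
#' @param replicates_per_block,n_blocks design counts.
#' @param noise_model list of noise parameters; missing entries take the
#'   documented defaults.
#' @return list of class `scenario_preset`.
#' @export
scenario_preset <- function(species_name, rate_presets,
                            assimilation_efficiency = NA_real_,
                            per_cell_energy = NA_real_,
                            initial_density = NA_real_,
                            n_consumers = NA_integer_,
                            assay_temperatures,
                            replicates_per_block = 3, n_blocks = 2,
                            noise_model = list()) {
  if (anyDuplicated(assay_temperatures)) stop("assay temperatures must be distinct")
  if (replicates_per_block < 1 || n_blocks < 1) stop("replicate counts must be >= 1")
  if (!is.na(assimilation_efficiency) &&
      (assimilation_efficiency <= 0 || assimilation_efficiency > 1)) {
    stop("assimilation_efficiency must be in (0, 1]")
  }
  nm <- utils::modifyList(default_noise_model(), noise_model)
  if (any(unlist(nm[c("rate_cv", "slope_noise_sd", "control_noise_frac",
                      "control_drift_frac", "density_cv", "is_noise_sd")]) < 0)) {
    stop("noise standard deviations must be >= 0")
  }
  structure(list(
    species_name = species_name,
    rate_presets = rate_presets,
    assimilation_efficiency = assimilation_efficiency,
    per_cell_energy = per_cell_energy,
    initial_density = initial_density,
    n_consumers = n_consumers,
    assay_temperatures = sort(assay_temperatures),
    replicates_per_block = replicates_per_block,
    n_blocks = n_blocks,
    noise_model = nm
  ), class = "scenario_preset")
}

#' Built-in study scenarios
#'
#' Returns a ready-made [scenario_preset()] for one of the four study
#' configurations: the two algal resources (`"chlamydomonas"`,
#' `"desmodesmus"`) assayed at 14-42 degrees C, and the consumer pairs
#' (`"daphnia_on_chlamydomonas"`, `"daphnia_on_desmodesmus"`) assayed at
#' 14-36 degrees C. Rate summaries carry the published activation /
#' deactivation energies, optima and peak rates; ingestion lines carry the
#' published slopes with intercepts pinned at the published crossover
#' temperatures. `per_cell_energy` values are synthetic placeholder constants
#' (the cell-to-joule conversion was not published); every quantity the
#' package reports is a ratio or anchored line in which that constant cancels.
#'
#' @param name one of `"chlamydomonas"`, `"desmodesmus"`,
#'   `"daphnia_on_chlamydomonas"`, `"daphnia_on_desmodesmus"`.
#' @return a `scenario_preset`.
#' @export
thermal_preset <- function(name = c("chlamydomonas", "desmodesmus",
                                    "daphnia_on_chlamydomonas",
                                    "daphnia_on_desmodesmus")) {
  name <- match.arg(name)
  algal_temps <- seq(14, 42, by = 4)
  daphnia_temps <- c(14, 18, 22, 26, 30, 32, 34, 36)
  o2_energy_factor <- 1 / (oxygen_joule * 60) # J L^-1 h^-1 -> mg O2 L^-1 min^-1
  switch(name,
    chlamydomonas = scenario_preset(
      "Chlamydomonas reinhardtii",
      rate_presets = list(
        net_photosynthesis = tpc_summary(1.44, 31.66, 1.29, 5.27,
                                         units = "ng O2 L^-1 min^-1 cell^-1",
                                         oxygen_factor = 1e-6),
        respiration = tpc_summary(0.57, 38.99, 0.384, 13.73,
                                  units = "ng O2 L^-1 min^-1 cell^-1",
                                  oxygen_factor = 1e-6)
      ),
      initial_density = 4.5e5,
      assay_temperatures = algal_temps
    ),
    desmodesmus = scenario_preset(
      "Desmodesmus sp.",
      rate_presets = list(
        net_photosynthesis = tpc_summary(0.66, 27.40, 0.072, 1.66,
                                         units = "ng O2 L^-1 min^-1 cell^-1",
                                         oxygen_factor = 1e-6),
        respiration = tpc_summary(0.50, 39.34, 0.003, 20,
                                  units = "ng O2 L^-1 min^-1 cell^-1",
                                  oxygen_factor = 1e-6)
      ),
      initial_density = 1.3e6,
      assay_temperatures = algal_temps
    ),
    daphnia_on_chlamydomonas = scenario_preset(
      "Daphnia pulex on Chlamydomonas reinhardtii",
      rate_presets = list(
        respiration = tpc_summary(1.08, 29.40, 2.00, 1.99,
                                  units = "J L^-1 h^-1 daphnid^-1",
                                  oxygen_factor = o2_energy_factor),
        ingestion = linear_summary(-0.075, tc_anchor = 20.7,
                                   units = "J L^-1 h^-1 daphnid^-1"),
        is_line = linear_summary(-0.0007, tc_anchor = 20.7,
                                 units = "h^-1 daphnid^-1")
      ),
      assimilation_efficiency = 0.14,
      per_cell_energy = 5.4e-7,
      initial_density = 4.5e5,
      n_consumers = 5L,
      assay_temperatures = daphnia_temps
    ),
    daphnia_on_desmodesmus = scenario_preset(
      "Daphnia pulex on Desmodesmus sp.",
      rate_presets = list(
        respiration = tpc_summary(1.08, 29.40, 2.00, 1.99,
                                  units = "J L^-1 h^-1 daphnid^-1",
                                  oxygen_factor = o2_energy_factor),
        ingestion = linear_summary(0, tc_anchor = 22.5, zero_slope = TRUE,
                                   units = "J L^-1 h^-1 daphnid^-1"),
        is_line = linear_summary(0.0004, tc_anchor = 22.5,
                                 units = "h^-1 daphnid^-1")
      ),
      assimilation_efficiency = 0.10,
      per_cell_energy = 4.0e-7,
      initial_density = 1.3e6,
      n_consumers = 5L,
      assay_temperatures = daphnia_temps
    )
  )
}

#' Resolve a consumer preset's ingestion line in energy units
#'
#' Reconstructs the consumer respiration curve from the preset's summary
#' parameters and pins the ingestion line's intercept at the preset's
#' crossover anchor, so that ingestion equals respiration (gain/loss = 1)
#' exactly at the anchor temperature.
#'
#' @param preset a consumer-pair `scenario_preset`.
#' @param tref reference temperature for the reconstruction, Celsius.
#' @return list with elements `slope`, `intercept` (J L^-1 h^-1 daphnid^-1),
#'   `loss_params` (the consumer respiration `tpc_params`).
#' @export
pinned_ingestion_line <- function(preset, tref = 20) {
  ing <- preset$rate_presets$ingestion
  if (is.null(ing)) stop("preset has no ingestion component")
  loss <- reconstruct_tpc(preset$rate_presets$respiration, tref = tref)
  loss_fun <- function(x) {
    sharpe_schoolfield(x, loss$r_tref, loss$e_a, loss$e_h, loss$t_h, loss$tref)
  }
  list(slope = ing$slope,
       intercept = derive_linear_intercept(ing, loss_fun),
       loss_params = loss)
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset:", x$species_name, "\n")
  cat("  rates:", paste(names(x$rate_presets), collapse = ", "), "\n")
  cat("  temperatures:", paste(x$assay_temperatures, collapse = ", "), "C\n")
  cat("  design:", x$replicates_per_block, "replicates x", x$n_blocks, "blocks\n")
  invisible(x)
}
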