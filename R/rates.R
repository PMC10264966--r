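#' Oxygen slope of one respirometry series
#'
#' Ordinary least-squares slope of oxygen concentration against time for a
#' single vial.
#'
#' @param time_min reading times, minutes (strictly increasing, >= 3 points).
#' @param oxygen_mg_per_L oxygen readings, mg O2 L^-1.
#' @return slope in mg O2 L^-1 min^-1.
#' @export
oxygen_slope <- function(time_min, oxygen_mg_per_L) {
  if (length(time_min) < 3) stop("need at least 3 time points")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (stats::var(time_min) == 0) stop("degenerate times: zero variance")
  stats::cov(time_min, oxygen_mg_per_L) / stats::var(time_min)
}

check_units <- function(x, expected, what) {
  u <- attr(x, "units")
  if (!is.null(u) && !identical(u, expected)) {
    stop(what, ": expected units '", expected, "', got '", u, "'")
  }
}

rate_estimate <- function(value, units) {
  attr(value, "units") <- units
  value
}

#' Per-capita respiration rate from a control-corrected oxygen slope
#'
#' `rate = -(m_t - mean(control_slopes)) / d`: positive when the organism
#' vial loses oxygen faster than the same-block controls. `d` is the cell
#' density for algae or the number of consumers alive at the start for
#' consumer vials.
#'
#' @param m_t organism-vial oxygen slope, mg O2 L^-1 min^-1.
#' @param control_slopes slopes of controls from the *same* temporal block.
#' @param d per-capita denominator (> 0).
#' @return per-capita rate, mg O2 L^-1 min^-1 per individual (or cell), with
#'   a `units` attribute.
#' @export
respiration_rate <- function(m_t, control_slopes, d) {
  if (length(control_slopes) < 1) stop("no control slopes from the same block")
  if (!is.finite(d) || d <= 0) stop("denominator d must be positive")
  rate_estimate(-1 * (m_t - mean(control_slopes)) / d, "mg_O2_per_L_min_per_capita")
}

#' Per-capita net photosynthesis rate
#'
#' As [respiration_rate()] but without the sign flip: positive under net
#' oxygen production.
#'
#' @inheritParams respiration_rate
#' @export
net_photosynthesis_rate <- function(m_t, control_slopes, d) {
  if (length(control_slopes) < 1) stop("no control slopes from the same block")
  if (!is.finite(d) || d <= 0) stop("denominator d must be positive")
  rate_estimate((m_t - mean(control_slopes)) / d, "mg_O2_per_L_min_per_capita")
}

#' Per-capita raw ingestion rate from a grazing assay
#'
#' `rI = (D_T0 - D_T150 + (mean(C_T150) - mean(C_T0))) / (y * t)` with `t` in
#' hours: the density drop in a treatment vial, corrected by the mean change
#' in the same-block consumer-free controls (so resource growth masking
#' consumption is credited back).
#'
#' @param d_t0,d_t150 treatment densities at start and end, cells mL^-1.
#' @param controls_t0,controls_t150 same-block control densities at start and
#'   end (non-empty).
#' @param y consumers alive at the start (>= 1).
#' @param duration_min assay length, minutes (> 0).
#' @return rate in cells mL^-1 h^-1 per consumer, with `units` attribute.
#' @export
ingestion_raw <- function(d_t0, d_t150, controls_t0, controls_t150, y,
                          duration_min = 150) {
  if (length(controls_t0) < 1 || length(controls_t150) < 1) {
    stop("control densities from the same block are required")
  }
  if (y < 1) stop("y (consumers alive at start) must be >= 1")
  if (duration_min <= 0) stop("assay duration must be positive")
  t_h <- duration_min / 60
  rate_estimate(
    (d_t0 - d_t150 + (mean(controls_t150) - mean(controls_t0))) / (y * t_h),
    "cells_per_mL_h_per_capita"
  )
}

#' Convert an oxygen-based respiration rate to energetic units
#'
#' Multiplies by 14.06 J per mg O2 and by 60 min/h:
#' mg O2 L^-1 min^-1 -> J L^-1 h^-1.
#'
#' @param rate per-capita rate in mg O2 L^-1 min^-1 (units-tagged values are
#'   checked).
#' @return rate in J L^-1 h^-1 per individual.
#' @export
respiration_to_energy <- function(rate) {
  check_units(rate, "mg_O2_per_L_min_per_capita", "respiration_to_energy")
  rate_estimate(as.numeric(rate) * oxygen_joule * 60, "J_per_L_h_per_capita")
}

#' Inverse of [respiration_to_energy()]
#' @param rate per-capita rate in J L^-1 h^-1.
#' @return rate in mg O2 L^-1 min^-1 per individual.
#' @export
energy_to_respiration <- function(rate) {
  check_units(rate, "J_per_L_h_per_capita", "energy_to_respiration")
  rate_estimate(as.numeric(rate) / (oxygen_joule * 60), "mg_O2_per_L_min_per_capita")
}

#' Convert raw ingestion to assimilated energy units
#'
#' `I^E = rI * per_cell_energy * e * 1000`, where the factor 1000 converts
#' cells mL^-1 to cells L^-1 (applied exactly once, here), giving
#' J L^-1 h^-1 per consumer.
#'
#' @param ri raw ingestion, cells mL^-1 h^-1 per consumer.
#' @param per_cell_energy energy content of one resource cell, J.
#' @param e assimilation efficiency in (0, 1].
#' @return assimilated ingestion rate, J L^-1 h^-1 per consumer.
#' @export
ingestion_to_energy <- function(ri, per_cell_energy, e) {
  if (!is.finite(e) || e <= 0 || e > 1) stop("assimilation efficiency must be in (0, 1]")
  check_units(ri, "cells_per_mL_h_per_capita", "ingestion_to_energy")
  rate_estimate(as.numeric(ri) * per_cell_energy * e * 1000, "J_per_L_h_per_capita")
}

#' Convert a per-litre rate to a volume-corrected per-individual rate
#'
#' Published peak rates are quoted both per litre of assay volume and per
#' individual; this multiplies by the vial volume in litres.
#'
#' @param rate per-capita rate with a "per litre" dimension.
#' @param volume_mL assay volume, mL.
#' @return rate per individual (per-litre dimension removed).
#' @export
volume_correct <- function(rate, volume_mL = 5) {
  as.numeric(rate) * volume_mL / 1000
}

#' Per-capita rates from a table of oxygen series
#'
#' Applies [oxygen_slope()] to every vial and the block-matched control
#' correction to every organism vial of a respirometry table (the schema
#' written by [generate_oxygen_experiment()]). Corrections never pool across
#' temporal blocks; a missing same-block control is an error.
#'
#' @param series data frame with columns `replicate_id`, `block`, `role`,
#'   `temperature_C`, `time_min`, `oxygen_mg_per_L`,
#'   `n_organisms_or_density`.
#' @param rate_kind `"respiration"` or `"net_photosynthesis"`.
#' @return data frame of per-capita rates: `rate_kind`, `temperature_C`,
#'   `block`, `replicate_id`, `value`, `units`.
#' @export
compute_oxygen_rates <- function(series, rate_kind = c("respiration",
                                                       "net_photosynthesis")) {
  rate_kind <- match.arg(rate_kind)
  slopes <- do.call(rbind, lapply(split(series, series$replicate_id), function(v) {
    v <- v[order(v$time_min), ]
    data.frame(replicate_id = v$replicate_id[1], block = v$block[1],
               role = v$role[1], temperature_C = v$temperature_C[1],
               d = v$n_organisms_or_density[1],
               slope = oxygen_slope(v$time_min, v$oxygen_mg_per_L))
  }))
  org <- slopes[slopes$role == "organism", ]
  out <- do.call(rbind, lapply(seq_len(nrow(org)), function(i) {
    row <- org[i, ]
    ctrl <- slopes$slope[slopes$role == "control" &
                           slopes$block == row$block &
                           slopes$temperature_C == row$temperature_C]
    if (length(ctrl) == 0) {
      stop("no control slopes in block ", row$block, " at ",
           row$temperature_C, " C")
    }
    val <- if (rate_kind == "respiration") {
      respiration_rate(row$slope, ctrl, row$d)
    } else {
      net_photosynthesis_rate(row$slope, ctrl, row$d)
    }
    data.frame(rate_kind = rate_kind, temperature_C = row$temperature_C,
               block = row$block, replicate_id = row$replicate_id,
               value = as.numeric(val), units = attr(val, "units"))
  }))
  rownames(out) <- NULL
  out
}

#' Per-capita ingestion rates from a grazing-assay table
#'
#' Applies [ingestion_raw()] with block-matched control means to every
#' treatment vial (schema of [generate_ingestion_experiment()]); optionally
#' converts to assimilated energy units.
#'
#' @param ingestion data frame with the grazing-assay schema.
#' @param per_cell_energy,e if both supplied, rates are returned as
#'   assimilated energy (J L^-1 h^-1 per consumer); otherwise raw
#'   cells mL^-1 h^-1 per consumer.
#' @return data frame `rate_kind`, `temperature_C`, `block`, `replicate_id`,
#'   `value`, `units`.
#' @export
compute_ingestion_rates <- function(ingestion, per_cell_energy = NULL,
                                    e = NULL) {
  trt <- ingestion[ingestion$role == "treatment", ]
  out <- do.call(rbind, lapply(seq_len(nrow(trt)), function(i) {
    row <- trt[i, ]
    ctrl <- ingestion[ingestion$role == "control" &
                        ingestion$block == row$block &
                        ingestion$temperature_C == row$temperature_C, ]
    if (nrow(ctrl) == 0) {
      stop("no control replicates in block ", row$block, " at ",
           row$temperature_C, " C")
    }
    ri <- ingestion_raw(row$density_t0_cells_per_mL,
                        row$density_t150_cells_per_mL,
                        ctrl$density_t0_cells_per_mL,
                        ctrl$density_t150_cells_per_mL,
                        row$n_consumers, row$duration_min)
    val <- if (!is.null(per_cell_energy) && !is.null(e)) {
      ingestion_to_energy(ri, per_cell_energy, e)
    } else ri
    data.frame(rate_kind = "ingestion", temperature_C = row$temperature_C,
               block = row$block, replicate_id = row$replicate_id,
               value = as.numeric(val), units = attr(val, "units"))
  }))
  rownames(out) <- NULL
  out
}
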