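# Measured densities get multiplicative lognormal error with mean exactly 1,
# so control-corrected differences stay unbiased.
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a blocked respirometry experiment
#'
#' Generates oxygen time series for organism and control vials with the
#' design of the study assays: `replicates_per_block` organism vials and as
#' many medium-only controls per temporal block, at each assay temperature,
#' read every minute for 30 minutes. The organism vial's oxygen slope is the
#' signed per-capita rate (from the preset's reconstructed thermal
#' performance curve) times the cell density or consumer count, perturbed by
#' multiplicative rate noise, plus a block-common control drift shared with
#' the control vials.
#'
#' @param preset a [scenario_preset()] whose `rate_presets` contains a
#'   [tpc_summary()] for `rate_kind`.
#' @param rate_kind `"respiration"` or `"net_photosynthesis"`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param tref reference temperature used for the curve reconstruction.
#' @param survival_prob probability that each consumer survives acclimation
#'   (consumer presets only); vials record the number alive at start.
#' @return data frame with columns `replicate_id`, `block`, `role`
#'   (`organism`/`control`), `temperature_C`, `time_min`, `oxygen_mg_per_L`,
#'   `n_organisms_or_density`.
#' @export
generate_oxygen_experiment <- function(preset, rate_kind, seed, tref = 20,
                                       survival_prob = 1) {
  summary <- preset$rate_presets[[rate_kind]]
  if (is.null(summary) || !inherits(summary, "tpc_summary")) {
    stop("preset has no thermal-performance summary for rate kind '",
         rate_kind, "'")
  }
  set.seed(seed)
  params <- reconstruct_tpc(summary, tref = tref)
  sgn <- switch(rate_kind, respiration = -1, net_photosynthesis = 1,
                stop("unknown oxygen rate kind: ", rate_kind))
  is_consumer <- !is.na(preset$n_consumers)
  d0 <- if (is_consumer) preset$n_consumers else preset$initial_density
  nm <- preset$noise_model
  peak_slope <- summary$mrp * summary$oxygen_factor * d0
  times <- 0:30
  o2_start <- 8 # mg O2 L^-1, near air saturation

  rows <- list()
  rep_counter <- 0L
  for (temp in preset$assay_temperatures) {
    rate_t <- sharpe_schoolfield(temp, params$r_tref, params$e_a, params$e_h,
                                 params$t_h, params$tref) * summary$oxygen_factor
    for (b in seq_len(preset$n_blocks)) {
      drift <- stats::rnorm(1, 0, nm$control_drift_frac * abs(peak_slope))
      for (r in seq_len(preset$replicates_per_block)) {
        rep_counter <- rep_counter + 1L
        d <- if (is_consumer && survival_prob < 1) {
          max(1L, stats::rbinom(1, d0, survival_prob))
        } else d0
        slope <- sgn * rate_t * d * (1 + stats::rnorm(1, 0, nm$rate_cv)) +
          drift + stats::rnorm(1, 0, nm$slope_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate_id = sprintf("%s_T%g_B%d_R%d", rate_kind, temp, b, r),
          block = paste0("B", b), role = "organism", temperature_C = temp,
          time_min = times, oxygen_mg_per_L = o2_start + slope * times,
          n_organisms_or_density = d
        )
      }
      for (r in seq_len(preset$replicates_per_block)) {
        rep_counter <- rep_counter + 1L
        cslope <- drift + stats::rnorm(1, 0, nm$control_noise_frac * abs(peak_slope))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate_id = sprintf("%s_T%g_B%d_C%d", rate_kind, temp, b, r),
          block = paste0("B", b), role = "control", temperature_C = temp,
          time_min = times, oxygen_mg_per_L = o2_start + cslope * times,
          n_organisms_or_density = NA_real_
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a blocked grazing (ingestion) assay
#'
#' Generates start/end resource densities for consumer treatment vials and
#' consumer-free controls. Controls change by a fractional growth/settling
#' drift over the 150-minute assay; treatment vials additionally lose
#' `y * rI(T) * t` cells, where the per-capita raw ingestion rate `rI(T)`
#' (cells mL^-1 h^-1) is the preset's energy-unit ingestion line (pinned at
#' its crossover anchor) divided by assimilation efficiency, per-cell energy,
#' and the mL-to-L factor. Measured densities carry multiplicative lognormal
#' error with the preset's `density_cv`.
#'
#' @inheritParams generate_oxygen_experiment
#' @param duration_min assay duration, minutes.
#' @return data frame with columns `replicate_id`, `block`, `temperature_C`,
#'   `role` (`treatment`/`control`), `density_t0_cells_per_mL`,
#'   `density_t150_cells_per_mL`, `n_consumers`, `duration_min`.
#' @export
generate_ingestion_experiment <- function(preset, seed, tref = 20,
                                          duration_min = 150,
                                          survival_prob = 1) {
  if (is.null(preset$rate_presets$ingestion)) {
    stop("preset has no ingestion component")
  }
  set.seed(seed)
  line <- pinned_ingestion_line(preset, tref = tref)
  e <- preset$assimilation_efficiency
  pce <- preset$per_cell_energy
  nm <- preset$noise_model
  t_h <- duration_min / 60
  d_init <- preset$initial_density
  rows <- list()
  for (temp in preset$assay_temperatures) {
    i_energy <- line$intercept + line$slope * temp # J L^-1 h^-1 daphnid^-1
    ri_cells <- i_energy / (e * pce * 1000)        # cells mL^-1 h^-1 daphnid^-1
    for (b in seq_len(preset$n_blocks)) {
      for (r in seq_len(preset$replicates_per_block)) {
        y <- if (survival_prob < 1) {
          max(1L, stats::rbinom(1, preset$n_consumers, survival_prob))
        } else preset$n_consumers
        d_end <- d_init * (1 + nm$control_growth) - y * ri_cells * t_h
        rows[[length(rows) + 1L]] <- data.frame(
          replicate_id = sprintf("ing_T%g_B%d_R%d", temp, b, r),
          block = paste0("B", b), temperature_C = temp, role = "treatment",
          density_t0_cells_per_mL = d_init * rlnorm_mean1(1, nm$density_cv),
          density_t150_cells_per_mL = d_end * rlnorm_mean1(1, nm$density_cv),
          n_consumers = y, duration_min = duration_min
        )
      }
      for (r in seq_len(preset$replicates_per_block)) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate_id = sprintf("ing_T%g_B%d_C%d", temp, b, r),
          block = paste0("B", b), temperature_C = temp, role = "control",
          density_t0_cells_per_mL = d_init * rlnorm_mean1(1, nm$density_cv),
          density_t150_cells_per_mL = d_init * (1 + nm$control_growth) *
            rlnorm_mean1(1, nm$density_cv),
          n_consumers = 0L, duration_min = duration_min
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-capita interaction-strength records
#'
#' Draws hourly per-capita Dynamic-Index values along the pair preset's
#' linear interaction-strength trend with Gaussian residual noise. The line's
#' slope is the preset's published value; its level is anchored at the pair's
#' crossover temperature to the Dynamic Index implied by the preset's own
#' ingestion line and resource density there, since absolute levels were not
#' published.
#'
#' @inheritParams generate_oxygen_experiment
#' @param duration_min assay duration, minutes.
#' @return data frame with columns `pair`, `temperature_C`, `block`,
#'   `replicate_id`, `value` (h^-1 per consumer).
#' @export
generate_is_records <- function(preset, seed, tref = 20, duration_min = 150) {
  is_line <- preset$rate_presets$is_line
  if (is.null(is_line)) stop("preset has no interaction-strength line")
  set.seed(seed)
  intercept <- implied_is_intercept(preset, tref = tref,
                                    duration_min = duration_min)
  nm <- preset$noise_model
  n_rep <- preset$replicates_per_block
  rows <- list()
  for (temp in preset$assay_temperatures) {
    mu <- intercept + is_line$slope * temp
    for (b in seq_len(preset$n_blocks)) {
      vals <- mu + stats::rnorm(n_rep, 0, nm$is_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = preset$species_name, temperature_C = temp,
        block = paste0("B", b),
        replicate_id = sprintf("is_T%g_B%d_R%d", temp, b, seq_len(n_rep)),
        value = vals
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Intercept of the IS line: the Dynamic Index implied by the preset's pinned
# ingestion line and resource density at the crossover anchor, minus
# slope * anchor.
implied_is_intercept <- function(preset, tref = 20, duration_min = 150) {
  is_line <- preset$rate_presets$is_line
  anchor <- is_line$tc_anchor
  if (is.null(anchor)) return(is_line$intercept)
  line <- pinned_ingestion_line(preset, tref = tref)
  t_h <- duration_min / 60
  y <- preset$n_consumers
  ri_cells <- (line$intercept + line$slope * anchor) /
    (preset$assimilation_efficiency * preset$per_cell_energy * 1000)
  n_dens <- preset$initial_density
  d_dens <- n_dens - y * ri_cells * t_h
  if (d_dens <= 0) stop("implied consumption exceeds resource density at anchor")
  dynamic_index(n_dens, d_dens, y, t_h) - is_line$slope * anchor
}

#' Write a scenario's synthetic tables to CSV
#'
#' @param tables named list of data frames (e.g. `oxygen_series`,
#'   `ingestion`, `is_records`).
#' @param dir output directory, created if needed.
#' @return invisibly, the written file paths.
#' @export
write_scenario_csvs <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
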