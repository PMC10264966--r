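#' Configuration for an end-to-end pipeline run
#'
#' @param pairs consumer-resource pair preset names (see [thermal_preset()]).
#' @param seed master integer seed; each stage derives its own recorded seed.
#' @param tref reference temperature, Celsius.
#' @param grid_step prediction grid step, Celsius.
#' @param n_boot bootstrap resamples for TPC confidence intervals (0 skips
#'   the bootstrap).
#' @param boot_level bootstrap confidence level.
#' @param alpha significance level for the zero-slope ingestion gate and the
#'   IS slope test.
#' @param smooth_window derivative smoothing window, degrees C.
#' @param trend_eps CREB trend tolerance (NULL for the 1%-of-range default).
#' @param multistart TPC fit multistart count.
#' @param exclude replicate ids to drop from interaction-strength records.
#' @param out_dir output directory, or NULL to skip writing files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pairs = c("daphnia_on_chlamydomonas",
                                      "daphnia_on_desmodesmus"),
                            seed = 1, tref = 20, grid_step = 0.001,
                            n_boot = 0, boot_level = 0.95, alpha = 0.05,
                            smooth_window = 0.5, trend_eps = NULL,
                            multistart = 20, exclude = NULL, out_dir = NULL) {
  structure(list(pairs = pairs, seed = as.integer(seed), tref = tref,
                 grid_step = grid_step, n_boot = n_boot,
                 boot_level = boot_level, alpha = alpha,
                 smooth_window = smooth_window, trend_eps = trend_eps,
                 multistart = multistart, exclude = exclude,
                 out_dir = out_dir),
            class = "pipeline_config")
}

resource_of <- function(pair_name) {
  sub("^daphnia_on_", "", pair_name)
}

# simulate -> rates -> TPC fit for one oxygen-based rate
fit_oxygen_stage <- function(preset, rate_kind, seed, config, to_energy = FALSE) {
  series <- generate_oxygen_experiment(preset, rate_kind, seed = seed,
                                       tref = config$tref)
  rates <- compute_oxygen_rates(series, rate_kind)
  if (to_energy) {
    rates$value <- rates$value * oxygen_joule * 60
    rates$units <- "J_per_L_h_per_capita"
  }
  fit <- fit_tpc(rates, tref = config$tref, multistart = config$multistart,
                 seed = seed + 1L)
  if (config$n_boot > 0) {
    fit <- bootstrap_cis(fit, n_boot = config$n_boot,
                         level = config$boot_level, seed = seed + 2L)
  }
  list(series = series, rates = rates, fit = fit)
}

#' Run the full analysis pipeline on synthetic study data
#'
#' Executes, for each configured consumer-resource pair: synthetic assay
#' generation (respirometry for resource photosynthesis/respiration and
#' consumer respiration; grazing assays for ingestion), per-capita rate
#' computation with block-matched control correction, Sharpe-Schoolfield and
#' linear model fitting, fine-grid prediction, energetic balances with
#' Tm/Tc/intra-mismatch, interspecific mismatch regions, the CREB and its
#' trend, Dynamic-Index interaction strength with the temperature-by-species
#' regression, and the concordance check between predicted and measured IS
#' trends. When `config$out_dir` is set, writes CSV tables, a JSON mismatch
#' report and a run manifest.
#'
#' @param config a [pipeline_config()].
#' @return a named list (`species`, `pairs`, `interaction`, `manifest`) with
#'   all derived quantities.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed0 <- config$seed * 1000L
  seeds <- list()
  species_out <- list()
  pair_out <- list()
  resource_results <- list()
  consumer_resp <- NULL
  is_records <- list()
  tables <- list()

  for (i in seq_along(config$pairs)) {
    pair_name <- config$pairs[i]
    pair_preset <- thermal_preset(pair_name)
    res_name <- resource_of(pair_name)
    res_preset <- thermal_preset(res_name)

    # resource stage (computed once per distinct resource)
    if (is.null(resource_results[[res_name]])) {
      sp <- seed0 + 10L * i
      seeds[[paste0(res_name, "_photosynthesis")]] <- sp + 1L
      seeds[[paste0(res_name, "_respiration")]] <- sp + 4L
      p_stage <- fit_oxygen_stage(res_preset, "net_photosynthesis", sp + 1L, config)
      r_stage <- fit_oxygen_stage(res_preset, "respiration", sp + 4L, config)
      resource_results[[res_name]] <- list(p = p_stage, r = r_stage)
      tables[[paste0(res_name, "_rates")]] <- rbind(p_stage$rates, r_stage$rates)
    }

    # consumer respiration (shared across pairs; the same animal)
    if (is.null(consumer_resp)) {
      seeds$consumer_respiration <- seed0 + 7L
      consumer_resp <- fit_oxygen_stage(pair_preset, "respiration",
                                        seed0 + 7L, config, to_energy = TRUE)
      tables$consumer_respiration_rates <- consumer_resp$rates
    }

    # ingestion stage
    ing_seed <- seed0 + 100L + i
    seeds[[paste0(pair_name, "_ingestion")]] <- ing_seed
    ingestion <- generate_ingestion_experiment(pair_preset, seed = ing_seed,
                                               tref = config$tref)
    ing_rates <- compute_ingestion_rates(ingestion,
                                         per_cell_energy = pair_preset$per_cell_energy,
                                         e = pair_preset$assimilation_efficiency)
    ing_fit <- fit_linear_rate(ing_rates, alpha = config$alpha)
    tables[[paste0(pair_name, "_ingestion_rates")]] <- ing_rates

    # prediction grids and balances
    res_range <- range(res_preset$assay_temperatures)
    con_range <- range(pair_preset$assay_temperatures)
    res_balance <- energetic_balance(
      predict_grid(resource_results[[res_name]]$p$fit, res_range[1], res_range[2],
                   config$grid_step),
      predict_grid(resource_results[[res_name]]$r$fit, res_range[1], res_range[2],
                   config$grid_step),
      species = res_preset$species_name,
      gain_kind = "net_photosynthesis", loss_kind = "respiration")
    res_balance_con <- energetic_balance(
      predict_grid(resource_results[[res_name]]$p$fit, con_range[1], con_range[2],
                   config$grid_step),
      predict_grid(resource_results[[res_name]]$r$fit, con_range[1], con_range[2],
                   config$grid_step),
      species = res_preset$species_name,
      gain_kind = "net_photosynthesis", loss_kind = "respiration")
    con_balance <- energetic_balance(
      predict_grid(ing_fit, con_range[1], con_range[2], config$grid_step),
      predict_grid(consumer_resp$fit, con_range[1], con_range[2], config$grid_step),
      species = "Daphnia pulex", gain_kind = "ingestion", loss_kind = "respiration")

    if (is.null(species_out[[res_name]])) {
      species_out[[res_name]] <- list(
        species = res_preset$species_name,
        tm = find_tm(res_balance), tc = find_tc(res_balance),
        intra_tm = intra_tm(res_balance, config$smooth_window))
    }
    con_tm <- find_tm(con_balance)
    con_tc <- find_tc(con_balance)

    regions <- inter_tm(con_balance, res_balance_con, config$smooth_window)
    creb_curve <- creb(con_balance, res_balance_con)
    trend <- classify_trend(creb_curve, eps = config$trend_eps,
                            smooth_window = config$smooth_window)
    predicted <- predict_is_trend(trend)

    seeds[[paste0(pair_name, "_is")]] <- ing_seed # IS derives from ingestion
    is_records[[pair_name]] <- is_from_ingestion(ingestion, pair = pair_name)
    tables[[paste0(pair_name, "_creb")]] <- data.frame(
      temperature_C = creb_curve$temperature_C, creb_value = creb_curve$value)

    pair_out[[pair_name]] <- list(
      pair = pair_preset$species_name,
      consumer_tm = con_tm, consumer_tc = con_tc,
      ingestion_model = ing_fit,
      inter_tm = regions, creb_trend = trend, predicted_is = predicted)
  }

  all_is <- do.call(rbind, is_records)
  rownames(all_is) <- NULL
  is_model <- is_regression(all_is, exclude = config$exclude)
  tables$is_records <- all_is

  for (pair_name in names(pair_out)) {
    srow <- is_model$slopes[is_model$slopes$pair == pair_name, ]
    pair_out[[pair_name]]$is_slope <- srow$slope
    pair_out[[pair_name]]$is_p_value <- srow$p_value
    pair_out[[pair_name]]$concordance <- concordance(
      pair_out[[pair_name]]$predicted_is, srow$slope, srow$p_value,
      alpha = config$alpha)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermomatch")),
    master_seed = config$seed,
    stage_seeds = seeds,
    config = unclass(config)
  )
  result <- list(species = species_out, pairs = pair_out,
                 interaction = is_model, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scenario_csvs(tables, config$out_dir)
    jsonlite::write_json(summarize_run(result),
                         file.path(config$out_dir, "mismatch_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# flatten a run_all() result into JSON-friendly scalars
summarize_run <- function(result) {
  list(
    species = lapply(result$species, function(s) list(
      species = s$species, tm = s$tm$tm, tm_boundary = s$tm$boundary,
      tc = s$tc$tc, always_deficit = s$tc$always_deficit,
      intra_tm = s$intra_tm)),
    pairs = lapply(result$pairs, function(p) list(
      pair = p$pair, consumer_tm = p$consumer_tm$tm,
      consumer_tm_boundary = p$consumer_tm$boundary,
      consumer_tc = p$consumer_tc$tc,
      ingestion_slope = p$ingestion_model$slope,
      ingestion_constrained_zero = p$ingestion_model$constrained_zero,
      region1 = p$inter_tm$region1, region2 = p$inter_tm$region2,
      creb_trend = p$creb_trend, predicted_is = p$predicted_is$direction,
      is_slope = p$is_slope, is_p_value = p$is_p_value,
      concordance = p$concordance)),
    interaction_F = result$interaction$interaction_F,
    interaction_p = result$interaction$interaction_p
  )
}
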