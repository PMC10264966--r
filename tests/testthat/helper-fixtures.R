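# shared fixtures for the suite

# a preset with all noise switched off (exact round trips)
noise_free <- function(name) {
  pr <- thermal_preset(name)
  pr$noise_model$rate_cv <- 0
  pr$noise_model$slope_noise_sd <- 0
  pr$noise_model$control_noise_frac <- 0
  pr$noise_model$control_drift_frac <- 0
  pr$noise_model$density_cv <- 0
  pr$noise_model$is_noise_sd <- 0
  pr
}

# random valid TPC summary (Eh > Ea > 0, plausible optimum)
random_tpc_summary <- function() {
  e_a <- runif(1, 0.3, 2)
  tpc_summary(e_a = e_a, topt = runif(1, 15, 40), mrp = 10^runif(1, -2, 2),
              e_h = e_a + runif(1, 0.3, 10))
}

# balance curve straight from numeric vectors
balance_from_values <- function(temps, gain, loss, species = "toy") {
  energetic_balance(data.frame(temperature_C = temps, value = gain),
                    data.frame(temperature_C = temps, value = loss),
                    species = species)
}

# reconstructed resource P/Rr balance on a grid
resource_balance <- function(name, t_min = 14, t_max = 42, step = 0.001) {
  pr <- thermal_preset(name)
  energetic_balance(
    predict_grid(reconstruct_tpc(pr$rate_presets$net_photosynthesis), t_min, t_max, step),
    predict_grid(reconstruct_tpc(pr$rate_presets$respiration), t_min, t_max, step),
    species = pr$species_name,
    gain_kind = "net_photosynthesis", loss_kind = "respiration")
}

# consumer I/Rc balance with the pinned ingestion line
consumer_balance <- function(pair_name, t_min = 14, t_max = 36, step = 0.001) {
  pp <- thermal_preset(pair_name)
  line <- pinned_ingestion_line(pp)
  gain <- predict_grid(
    structure(list(slope = line$slope, intercept = line$intercept),
              class = "linear_rate_fit"), t_min, t_max, step)
  loss <- predict_grid(line$loss_params, t_min, t_max, step)
  energetic_balance(gain, loss, species = "Daphnia pulex",
                    gain_kind = "ingestion", loss_kind = "respiration")
}
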