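test_that("pinned ingestion intercepts make gain equal loss exactly at the anchor", {
  # zero slope anchored at 22.5 C: intercept equals the loss there
  pp <- thermal_preset("daphnia_on_desmodesmus")
  line <- pinned_ingestion_line(pp)
  loss <- line$loss_params
  loss_at <- function(x) sharpe_schoolfield(x, loss$r_tref, loss$e_a,
                                            loss$e_h, loss$t_h, loss$tref)
  expect_equal(line$intercept, loss_at(22.5))
  # negative slope anchored at 20.7: ratio = 1 there
  pc <- thermal_preset("daphnia_on_chlamydomonas")
  lc <- pinned_ingestion_line(pc)
  lossc <- lc$loss_params
  gain_at_anchor <- lc$intercept + lc$slope * 20.7
  loss_at_anchor <- sharpe_schoolfield(20.7, lossc$r_tref, lossc$e_a,
                                       lossc$e_h, lossc$t_h, lossc$tref)
  expect_equal(gain_at_anchor / loss_at_anchor, 1, tolerance = 1e-12)
  # constant loss: intercept is that constant whatever the anchor
  flat <- linear_summary(0, tc_anchor = 31.4, zero_slope = TRUE)
  expect_equal(derive_linear_intercept(flat, function(x) 0.7), 0.7)
  expect_error(derive_linear_intercept(linear_summary(0.1, intercept = NULL,
                                                      tc_anchor = NULL),
                                       function(x) 1))
})

test_that("generation is reproducible under a fixed seed and varies across seeds", {
  pr <- thermal_preset("chlamydomonas")
  a <- generate_oxygen_experiment(pr, "respiration", seed = 11)
  b <- generate_oxygen_experiment(pr, "respiration", seed = 11)
  expect_identical(a, b)
  c <- generate_oxygen_experiment(pr, "respiration", seed = 12)
  expect_false(identical(a$oxygen_mg_per_L, c$oxygen_mg_per_L))
  pp <- thermal_preset("daphnia_on_chlamydomonas")
  i1 <- generate_ingestion_experiment(pp, seed = 3)
  i2 <- generate_ingestion_experiment(pp, seed = 3)
  expect_identical(i1, i2)
  s1 <- generate_is_records(pp, seed = 4)
  expect_identical(s1, generate_is_records(pp, seed = 4))
})

test_that("the experiment tables carry the blocked assay design", {
  pr <- thermal_preset("desmodesmus")
  ox <- generate_oxygen_experiment(pr, "net_photosynthesis", seed = 2)
  expect_setequal(unique(ox$temperature_C), seq(14, 42, 4))
  per_vial <- table(ox$replicate_id)
  expect_true(all(per_vial == 31)) # 0..30 min every minute
  one_cell <- ox[ox$temperature_C == 22 & ox$block == "B1", ]
  expect_equal(sum(one_cell$role == "organism") / 31, 3)
  expect_equal(sum(one_cell$role == "control") / 31, 3)
  ing <- generate_ingestion_experiment(thermal_preset("daphnia_on_desmodesmus"),
                                       seed = 2)
  expect_equal(nrow(ing), 8 * 2 * (3 + 3))
  expect_true(all(ing$duration_min == 150))
  expect_true(all(ing$n_consumers[ing$role == "treatment"] >= 1))
})

test_that("noise-free generation round-trips the preset rates exactly", {
  # oxygen -> per-capita rate, both rate kinds, both organism types
  for (name in c("chlamydomonas", "desmodesmus")) {
    pr <- noise_free(name)
    for (kind in c("respiration", "net_photosynthesis")) {
      params <- reconstruct_tpc(pr$rate_presets[[kind]])
      ox <- generate_oxygen_experiment(pr, kind, seed = 1)
      rt <- compute_oxygen_rates(ox, kind)
      truth <- sharpe_schoolfield(rt$temperature_C, params$r_tref, params$e_a,
                                  params$e_h, params$t_h, params$tref) *
        pr$rate_presets[[kind]]$oxygen_factor
      expect_equal(rt$value, truth, tolerance = 1e-9)
    }
  }
  # consumer respiration in energy units
  pp <- noise_free("daphnia_on_chlamydomonas")
  ox <- generate_oxygen_experiment(pp, "respiration", seed = 1)
  rt <- compute_oxygen_rates(ox, "respiration")
  params <- reconstruct_tpc(pp$rate_presets$respiration)
  truth <- sharpe_schoolfield(rt$temperature_C, params$r_tref, params$e_a,
                              params$e_h, params$t_h, params$tref)
  expect_equal(rt$value * oxygen_joule * 60, truth, tolerance = 1e-9)
})

test_that("noise-free ingestion recovers the pinned energy line exactly", {
  for (pair in c("daphnia_on_chlamydomonas", "daphnia_on_desmodesmus")) {
    pp <- noise_free(pair)
    pp$noise_model$control_growth <- 0
    line <- pinned_ingestion_line(pp)
    ing <- generate_ingestion_experiment(pp, seed = 1)
    rts <- compute_ingestion_rates(ing, pp$per_cell_energy,
                                   pp$assimilation_efficiency)
    expect_equal(rts$value, line$intercept + line$slope * rts$temperature_C,
                 tolerance = 1e-9)
  }
})

test_that("control drift cancels in expectation in the corrected rates", {
  # many replicates at one temperature: mean corrected rate within 3 SE of truth
  pr <- thermal_preset("chlamydomonas")
  pr$assay_temperatures <- c(14, 18, 22, 26, 30) # >= 5 needed only for fits
  pr$replicates_per_block <- 50
  ox <- generate_oxygen_experiment(pr, "respiration", seed = 99)
  rt <- compute_oxygen_rates(ox, "respiration")
  params <- reconstruct_tpc(pr$rate_presets$respiration)
  for (temp in pr$assay_temperatures) {
    v <- rt$value[rt$temperature_C == temp] * 1e6 # back to preset units
    truth <- sharpe_schoolfield(temp, params$r_tref, params$e_a, params$e_h,
                                params$t_h, params$tref)
    expect_lt(abs(mean(v) - truth), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("zero-slope ingestion yields non-significant temperature dependence in most runs", {
  hits <- vapply(1:50, function(s) {
    pp <- thermal_preset("daphnia_on_desmodesmus")
    ing <- generate_ingestion_experiment(pp, seed = 600 + s)
    rts <- compute_ingestion_rates(ing, pp$per_cell_energy,
                                   pp$assimilation_efficiency)
    fit <- fit_linear_rate(rts, alpha = 0.05)
    fit$constrained_zero
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("consumer survival option exercises small live counts", {
  pp <- thermal_preset("daphnia_on_chlamydomonas")
  ox <- generate_oxygen_experiment(pp, "respiration", seed = 5,
                                   survival_prob = 0.7)
  d <- ox$n_organisms_or_density[ox$role == "organism"]
  expect_true(all(d >= 1 & d <= 5))
  expect_true(any(d < 5))
})

test_that("written CSV tables re-read to the in-memory values", {
  dir <- tempfile("tm_csv_")
  pr <- thermal_preset("chlamydomonas")
  ox <- generate_oxygen_experiment(pr, "respiration", seed = 8)
  paths <- write_scenario_csvs(list(oxygen_series = ox), dir)
  back <- utils::read.csv(paths[["oxygen_series"]])
  expect_equal(back$oxygen_mg_per_L, ox$oxygen_mg_per_L)
  expect_equal(back$replicate_id, ox$replicate_id)
})
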