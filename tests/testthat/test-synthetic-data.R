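# Synthetic coastline generator: determinism, emulation targets, injected
# ground truth, physical bounds.

test_that("config validation names the offending field", {
  expect_error(synth_config(n_cells = 10, n_reefs = 20), "n_reefs")
  expect_error(synth_config(years = 2010), "years")
  expect_error(synth_config(heatwave_year = 1990), "heatwave_year")
  expect_error(synth_config(heatwave_anomaly_C = -1), "heatwave_anomaly_C")
  expect_error(synth_config(noise_sd = list(trajectory = -1, heatwave = 8,
                                            cover_obs = 1)), "noise_sd")
  expect_error(synth_config(truth_ordinal = list(C = c(1, -1),
                                                 B = c(a = 1))), "truth_ordinal")
})

test_that("identical config and seed give identical bundles", {
  b1 <- small_bundle(seed = 5, n_cells = 60, n_reefs = 12)
  b2 <- small_bundle(seed = 5, n_cells = 60, n_reefs = 12)
  expect_identical(b1$survey_table, b2$survey_table)
  expect_identical(b1$driver_table, b2$driver_table)
  expect_identical(b1$truth$category, b2$truth$category)
  b3 <- small_bundle(seed = 6, n_cells = 60, n_reefs = 12)
  expect_false(identical(b1$survey_table, b3$survey_table))
})

test_that("reefs sit at distinct cells and inputs cover all years", {
  b <- small_bundle(seed = 5, n_cells = 60, n_reefs = 12)
  expect_equal(anyDuplicated(b$reefs$cell), 0)
  yr <- as.integer(format(b$sst$dates, "%Y"))
  expect_equal(sort(unique(yr)), 2000:2019)
  # SST series daily and gap-free
  expect_equal(length(b$sst$dates),
               as.integer(as.Date("2019-12-31") - as.Date("2000-01-01")) + 1)
  # loads non-negative, right-skewed
  expect_true(all(b$osds_sources$effluent_l_yr >= 0))
  skew <- mean(b$osds_sources$effluent_l_yr) >
    median(b$osds_sources$effluent_l_yr)
  expect_true(skew)
  # every reef has a survey in every scheduled benthic year
  tab <- table(b$survey_table$reef_id[b$survey_table$variable == "coral_cover"])
  expect_true(all(tab == length(b$truth$benthic_years)))
})

test_that("heatwave year SST is indistinguishable from others when the anomaly is zero", {
  cfg <- synth_config(n_cells = 40, n_reefs = 8, heatwave_anomaly_C = 0,
                      truth_trajectory_effects = numeric(0),
                      truth_heatwave_effects = list(intercept = -20,
                                                    effects = numeric(0)),
                      truth_ordinal = list(C = c(-1, 1), B = numeric(0)),
                      rng_seed = 19)
  b <- generate_coast(cfg)
  yr <- as.integer(format(b$sst$dates, "%Y"))
  summer_means <- vapply(2000:2019, function(y)
    sst_summary(b$sst$regional[yr == y])$mean, numeric(1))
  hwv <- summer_means[2015 - 1999]
  others <- summer_means[-(2015 - 1999)]
  expect_lt(abs(hwv - mean(others)), 3 * sd(others))
})

test_that("default anomaly reproduces the ~2.2 degC above-normal heatwave signature", {
  b <- generate_coast(synth_config(n_cells = 40, n_reefs = 8, rng_seed = 19))
  yr <- as.integer(format(b$sst$dates, "%Y"))
  max7 <- vapply(2000:2019, function(y)
    max(stats::filter(b$sst$regional[yr == y], rep(1 / 7, 7), sides = 2),
        na.rm = TRUE), numeric(1))
  above_normal <- max7[2015 - 1999] - mean(max7[-(2015 - 1999)])
  expect_lt(abs(above_normal - 2.2), 0.35)
  # regional 7-day peak near 29.4 degC
  expect_lt(abs(max7[2015 - 1999] - 29.4), 0.5)
  # heat stress well past the 8-DHW severe-bleaching threshold
  expect_gt(dhw(b$sst$regional[yr == 2015], b$sst$mmm), 8)
})

test_that("generated category frequencies converge to the truth marginals", {
  # zero-slope truth with C = logit(0.25), logit(0.75): marginals (25/50/25)
  cfg <- synth_config(n_cells = 2200, n_reefs = 2000,
                      truth_trajectory_effects = numeric(0),
                      truth_heatwave_effects = list(intercept = -20,
                                                    effects = numeric(0)),
                      truth_ordinal = list(C = qlogis(c(0.25, 0.75)),
                                           B = numeric(0)),
                      rng_seed = 23)
  b <- generate_outcomes(generate_coast(cfg))
  freq <- prop.table(table(b$truth$category))
  expect_lt(abs(freq[["low"]] - 0.25), 0.02)
  expect_lt(abs(freq[["moderate"]] - 0.50), 0.02)
  expect_lt(abs(freq[["high"]] - 0.25), 0.02)
})

test_that("named zero slopes also give the closed-form marginals through the full path", {
  cfg <- synth_config(n_cells = 320, n_reefs = 300,
                      truth_ordinal = list(C = qlogis(c(0.25, 0.75)),
                                           B = c(fish_scraper = 0,
                                                 wastewater_effluent = 0)),
                      rng_seed = 29)
  b <- generate_outcomes(generate_coast(cfg))
  freq <- prop.table(table(b$truth$category))
  expect_lt(abs(freq[["low"]] - 0.25), 0.08)
  expect_lt(abs(freq[["high"]] - 0.25), 0.08)
})

test_that("zero effects and zero noise classify every reef as no-change", {
  cfg <- synth_config(n_cells = 40, n_reefs = 10,
                      truth_trajectory_effects = numeric(0),
                      truth_heatwave_effects = list(intercept = 0,
                                                    effects = numeric(0)),
                      truth_ordinal = list(C = c(-1, 1), B = numeric(0)),
                      noise_sd = list(trajectory = 0, heatwave = 0,
                                      cover_obs = 0),
                      rng_seed = 31)
  b <- generate_outcomes(generate_coast(cfg))
  expect_true(all(abs(b$truth$slope) < 1e-12))
  cw <- b$survey_table[b$survey_table$variable == "coral_cover", ]
  first <- cw$value[cw$year == min(cw$year)]
  last <- cw$value[cw$year == 2014]
  cls <- classify_trajectory(first, last)
  expect_true(all(cls$class == "no-change"))
})

test_that("an injected scraper effect raises scraper biomass on positive reefs", {
  cfg <- synth_config(n_cells = 220, n_reefs = 200,
                      truth_trajectory_effects = c(fish_scraper = 0.8),
                      truth_heatwave_effects = list(intercept = -20,
                                                    effects = numeric(0)),
                      truth_ordinal = list(C = c(-1, 1), B = numeric(0)),
                      years = 2010:2016, heatwave_year = 2015,
                      rng_seed = 37)
  b <- generate_outcomes(generate_coast(cfg))
  agg <- aggregate_drivers(b$driver_table, "trajectory", cfg$years,
                           cfg$heatwave_year)
  cw <- b$survey_table[b$survey_table$variable == "coral_cover", ]
  first <- cw$value[cw$year == min(cw$year)]
  last <- cw$value[cw$year == 2014]
  cls <- classify_trajectory(first, last, cutoff = 0.5)
  pos <- cls$class == "positive"; neg <- cls$class == "negative"
  expect_gt(sum(pos), 10); expect_gt(sum(neg), 10)
  expect_gt(mean(agg$fish_scraper[pos]), mean(agg$fish_scraper[neg]))
})

test_that("covers stay within [0, 100] and loads stay non-negative", {
  b <- small_bundle(seed = 5, n_cells = 60, n_reefs = 12)
  cov_rows <- grepl("cover", b$survey_table$variable)
  expect_true(all(b$survey_table$value[cov_rows] >= 0 &
                    b$survey_table$value[cov_rows] <= 100))
  load_vars <- c("wastewater_effluent", "nutrient_input", "sediment_input",
                 "urban_runoff", "rainfall_annual", "rainfall_peak",
                 "fish_total", "fish_scraper", "wave_power", "population")
  lv <- b$driver_table$value[b$driver_table$variable %in% load_vars]
  expect_true(all(lv >= 0))
  expect_true(all(b$driver_table$value[b$driver_table$variable == "gear_rank"]
                  %in% 1:6))
})

test_that("missing driver inputs are reported by name", {
  b <- generate_coast(synth_config(n_cells = 40, n_reefs = 8, rng_seed = 3))
  b$rainfall <- NULL
  expect_error(generate_outcomes(b), "rainfall")
})
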