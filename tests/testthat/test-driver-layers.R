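# Driver-layer operations: allometric biomass, dispersal kernel, load
# routing, interpolation, rainfall/sediment metrics, SST statistics, DHW,
# wave exposure, population and gear ranks.

test_that("fish biomass matches the allometric conversion and a per-fish oracle", {
  one <- data.frame(species = "sp", count = 1, tl_cm = 10, a = 0.01, b = 3,
                    guild = "other")
  # 0.01 * 10^3 = 10 g over 10,000 m2 (1 ha) -> 0.01 kg/ha
  expect_equal(fish_biomass(one, area_m2 = 10000), 0.01)
  # zero length contributes zero
  zero <- transform(one, tl_cm = 0)
  expect_equal(fish_biomass(zero, area_m2 = 125), 0)
  # mixed school over a 125 m2 belt equals the brute-force loop
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    obs <- data.frame(species = paste0("s", 1:n),
                      count = sample(1:9, n, replace = TRUE),
                      tl_cm = round(runif(n, 5, 40), 1),
                      a = runif(n, 0.005, 0.03),
                      b = runif(n, 2.8, 3.1),
                      guild = sample(c("scraper", "grazer", "other"), n, TRUE))
    expect_equal(fish_biomass(obs, area_m2 = 125),
                 fish_biomass_oracle(obs, 125))
  }
  # guild filtering restricts the sum
  obs <- data.frame(species = c("p", "q"), count = c(2, 3), tl_cm = c(20, 10),
                    a = c(0.02, 0.01), b = c(3, 3),
                    guild = c("scraper", "grazer"))
  expect_equal(fish_biomass(obs, 125, guilds = "scraper"),
               fish_biomass_oracle(obs[1, ], 125))
  # missing constants error names the species
  obs$a[2] <- NA
  expect_error(fish_biomass(obs, 125), "q")
})

test_that("dispersal kernel has the fixed 2-km decay and is strictly monotone", {
  expect_equal(dispersal_weight(0), 1)
  expect_equal(dispersal_weight(2000), exp(-4.5), tolerance = 1e-12)
  expect_equal(dispersal_weight(2000 / 3), exp(-0.5), tolerance = 1e-12)
  d <- seq(0, 5000, by = 50)
  w <- dispersal_weight(d)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(dispersal_weight(-1), "0")
})

test_that("wastewater loads route to entry cells with kernel ratios and scale linearly", {
  cells <- data.frame(cell = 0:20, position_m = (0:20 + 0.5) * 100)
  none <- wastewater_load(data.frame(entry_cell = integer(),
                                     effluent_l_yr = numeric(),
                                     nitrogen_kg_yr = numeric(),
                                     within_one_year_travel = logical()), cells)
  expect_true(all(none$effluent_l_ha_yr == 0))
  src <- data.frame(entry_cell = 0, effluent_l_yr = 1000, nitrogen_kg_yr = 10,
                    within_one_year_travel = TRUE)
  out <- wastewater_load(src, cells)
  # receiving cell at distance 0 gets the full load over the 1-ha cell
  expect_equal(out$effluent_l_ha_yr[1], 1000)
  # cell 2,000 m away is in the kernel ratio 1 : exp(-4.5)
  expect_equal(out$effluent_l_ha_yr[21] / out$effluent_l_ha_yr[1], exp(-4.5),
               tolerance = 1e-10)
  # linearity in source load
  out2 <- wastewater_load(transform(src, effluent_l_yr = 3000,
                                    nitrogen_kg_yr = 30), cells)
  expect_equal(out2$effluent_l_ha_yr, 3 * out$effluent_l_ha_yr)
  # sources beyond the one-year travel time are excluded
  out3 <- wastewater_load(transform(src, within_one_year_travel = FALSE), cells)
  expect_true(all(out3$effluent_l_ha_yr == 0))
  expect_error(wastewater_load(transform(src, entry_cell = 99), cells), "99")
})

test_that("golf nutrient input applies 585 kg/ha x 32% leaching and decays inland", {
  cells <- data.frame(cell = 0:10, position_m = (0:10 + 0.5) * 100)
  golf0 <- data.frame(entry_cell = 5, area_ha = 1, inland_distance_m = 0)
  out <- nutrient_input(NULL, golf0, cells)
  # shoreline course delivers 585 * 0.32 = 187.2 kg/yr at its entry cell
  expect_equal(max(out$nitrogen_kg_ha_yr), 187.2)
  # moving the same course inland strictly decreases delivered N
  dists <- c(0, 250, 500, 1000, 2000)
  tot <- vapply(dists, function(d)
    sum(nutrient_input(NULL, transform(golf0, inland_distance_m = d),
                       cells)$nitrogen_kg_ha_yr), numeric(1))
  expect_true(all(diff(tot) < 0))
  # zero golf area leaves the OSDS layer untouched
  osds_n <- runif(11)
  out2 <- nutrient_input(osds_n, transform(golf0, area_ha = 0), cells)
  expect_equal(out2$nitrogen_kg_ha_yr, osds_n)
  expect_error(nutrient_input(NULL, transform(golf0, area_ha = -1), cells), ">= 0")
})

test_that("impervious snapshots interpolate linearly and aggregate alongshore", {
  cells <- data.frame(cell = 0:2, position_m = c(50, 5150, 20050))
  snaps <- rbind(data.frame(cell = 0:2, year = 2010, impervious_ha = c(100, 0, 0)),
                 data.frame(cell = 0:2, year = 2014, impervious_ha = c(200, 0, 0)))
  out <- urban_runoff(snaps, cells, 2008:2016, window_m = 1000)
  c0 <- out[out$cell == 0, ]
  expect_equal(c0$impervious_ha[c0$year == 2012], 150)  # midpoint
  expect_equal(c0$impervious_ha[c0$year == 2008], 100)  # constant extrapolation
  expect_equal(c0$impervious_ha[c0$year == 2016], 200)
  # 10-km window picks up the neighbour cell, not the far one
  out10 <- urban_runoff(snaps, cells, 2010, window_m = 10000)
  expect_equal(out10$impervious_ha[out10$cell == 1], 100)
  expect_equal(out10$impervious_ha[out10$cell == 2], 0)
  # piecewise-linear on three uneven snapshots equals approx()
  snaps3 <- data.frame(cell = 0, year = c(2000, 2006, 2015),
                       impervious_ha = c(10, 40, 31))
  cells1 <- cells[1, ]
  got <- urban_runoff(snaps3, cells1, 2000:2015, window_m = 100)$impervious_ha
  expect_equal(got, approx(c(2000, 2006, 2015), c(10, 40, 31), 2000:2015)$y)
  expect_error(urban_runoff(snaps3[1, ], cells1, 2000:2015), ">= 2 snapshot")
})

test_that("rainfall metrics: annual totals, sliding 3-day peak, gap detection", {
  d <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
  out <- rainfall_metrics(d, rep(1, 365))
  expect_equal(out$annual_m3_ha, 365)
  expect_equal(out$peak3day_m3_ha, 3)
  v <- rep(0, 365); v[100] <- 30
  expect_equal(rainfall_metrics(d, v)$peak3day_m3_ha, 30)
  v2 <- c(5, 1, 1, 9, 9, 9, rep(0, 359))
  expect_equal(rainfall_metrics(d, v2)$peak3day_m3_ha, 27)
  # exhaustive-window oracle on random data
  set.seed(9)
  v3 <- rgamma(365, 0.5, 0.2)
  peaks <- vapply(1:363, function(i) sum(v3[i:(i + 2)]), numeric(1))
  expect_equal(rainfall_metrics(d, v3)$peak3day_m3_ha, max(peaks))
  expect_error(rainfall_metrics(d[-50], rep(1, 364)), "missing days")
})

test_that("sediment ratings curve scales with discharge and preserves the long-term mean", {
  q <- c(`2001` = 1, `2002` = 2, `2003` = 1)
  out <- sediment_input(100, q, beta = 1)
  expect_equal(out$sediment_kg_ha[2] / out$sediment_kg_ha[1], 2)
  expect_equal(mean(out$sediment_kg_ha), 100)
  const <- sediment_input(100, c(`2001` = 5, `2002` = 5), beta = 1.5)
  expect_equal(const$sediment_kg_ha, c(100, 100))
  # beta = 2 with Q ratios (0.5, 1, 2) gives relative loads (0.25, 1, 4)
  out2 <- sediment_input(100, c(a = 0.5, b = 1, c = 2) * 3, beta = 2)
  expect_equal(out2$sediment_kg_ha / out2$sediment_kg_ha[2], c(0.25, 1, 4),
               tolerance = 1e-12)
  expect_error(sediment_input(100, c(`2001` = 0, `2002` = 0)), "all-zero")
})

test_that("top-event means summarize episodic series", {
  expect_equal(top_events_mean(c(5, 1, 9, 7, 3), 3), mean(c(9, 7, 5)))
  expect_equal(top_events_mean(c(2, 1), 5), 1.5)  # k capped at n
})

test_that("summer SST window centres on the smoothed maximum with earliest tie-break", {
  const <- sst_summary(rep(26, 365))
  expect_equal(const$mean, 26)
  expect_equal(const$sd, 0)
  # sinusoid peaking at day 200: window spans days 156-245
  s <- 26 + 2 * cos(2 * pi * ((1:365) - 200) / 365)
  out <- sst_summary(s)
  expect_equal(out$centre, 200)
  expect_equal(unname(out$window), c(156, 245))
  expect_equal(out$mean, mean(s[156:245]))
  expect_equal(out$sd, sd(s[156:245]))
  # two identical peaks: earliest chosen
  two <- rep(25, 365); two[100:106] <- 27; two[300:306] <- 27
  expect_lt(sst_summary(two)$centre, 150)
  expect_error(sst_summary(rep(26, 50)), "97")
})

test_that("DHW follows the CRW accumulation rule and is translation-covariant", {
  expect_equal(dhw(rep(27, 120), 27), 0)
  # 2 degC hotspot held 84 days = 24 degC-weeks
  expect_equal(dhw(rep(29, 84), 27), 24)
  # below the 1 degC floor nothing accumulates
  expect_equal(dhw(rep(27.5, 120), 27), 0)
  set.seed(5)
  s <- 27 + cumsum(rnorm(200, 0, 0.3))
  expect_equal(dhw(s, 27), dhw(s + 3.7, 27 + 3.7))
  expect_gte(dhw(s, 27), 0)
  expect_error(dhw(rep(27, 10), 27), "84")
  expect_error(dhw(rep(27, 100), NA), "MMM")
})

test_that("wave exposure takes the mean at or above the 97.5th percentile", {
  expect_equal(wave_power_metric(rep(10, 365)), 10)
  expect_equal(wave_power_metric(rep(0, 365)), 0)
  # 1..365 under type-7: threshold 1 + 364 * 0.975 = 355.9 -> mean(356:365)
  expect_equal(wave_power_metric(1:365), 360.5)
  expect_error(wave_power_metric(1:10), "40")
})

test_that("population within radius is a geometric sum, linear in density", {
  grid <- expand.grid(x = seq(-20000, 20000, 1000), y = seq(0, 10000, 1000))
  grid$pop <- 1
  got <- population_within(grid, 0, 0, radius_m = 15000)
  inside <- sum(grid$x^2 + grid$y^2 <= 15000^2)
  expect_equal(got, inside)
  grid$pop <- 2.5
  expect_equal(population_within(grid, 0, 0, 15000), 2.5 * inside)
  grid$pop <- 0
  expect_equal(population_within(grid, 0, 0), 0)
  expect_error(population_within(grid[0, ], 0, 0), "empty")
})

test_that("gear ranks map the six regulation combinations and reject others", {
  expect_equal(gear_rank(no_take = TRUE), 1L)
  expect_equal(gear_rank(no_lay_net = TRUE, no_spear = TRUE, no_aquarium = TRUE), 2L)
  expect_equal(gear_rank(no_lay_net = TRUE, no_aquarium = TRUE), 3L)
  expect_equal(gear_rank(no_lay_net = TRUE), 4L)
  expect_equal(gear_rank(no_aquarium = TRUE), 5L)
  expect_equal(gear_rank(), 6L)
  expect_error(gear_rank(no_take = TRUE, open_access = TRUE), "contradictory")
  expect_error(gear_rank(no_spear = TRUE), "outside")
})
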