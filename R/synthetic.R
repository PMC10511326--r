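# Synthetic coastline / reef generator: seeded raw driver inputs and reef
# outcomes with known injected effects, so every analysis stage can be
# verified end to end without the original survey region's data.

#' Configuration for the synthetic coastline generator
#'
#' Defines the study conditions the generator emulates: a 100-m alongshore
#' coastal lattice, reefs at distinct cells, a two-decade span with one
#' marine heatwave year (default anomaly 2.2 deg C over a 90-day summer
#' window, giving a regional peak near 29.4 deg C), right-skewed
#' (log-normal) land-based loads, gamma rainfall with a seasonal cycle,
#' sinusoid + AR(1) sea surface temperature, and known per-driver effects
#' injected into the three outcome stages.
#'
#' @param n_cells number of 100-m alongshore cells.
#' @param n_reefs number of reefs (<= `n_cells`).
#' @param years inclusive calendar-year range (span >= 2).
#' @param heatwave_year heatwave year (within `years`).
#' @param heatwave_anomaly_C boxcar SST anomaly (deg C) in the heatwave
#'   year's summer window.
#' @param sst_base_C,sst_amplitude_C,sst_peak_doy annual SST sinusoid:
#'   base, amplitude and day-of-year of the seasonal peak. Defaults give a
#'   climatological summer peak near 27.2 deg C so the default anomaly
#'   peaks near 29.4 deg C.
#' @param sst_ar1_phi,sst_noise_sd AR(1) day-to-day SST noise parameters.
#' @param truth_trajectory_effects named vector: per-SD linear effects of
#'   standardized drivers on the pre-disturbance cover slope (percentage
#'   points per year).
#' @param truth_heatwave_effects list with `intercept` (mean percentage
#'   difference) and named `effects` (per-SD effects on the heatwave
#'   percentage-difference response).
#' @param truth_ordinal list with intercepts `C` (length 2, increasing)
#'   and named slopes `B` of the generating proportional-odds model (the
#'   [fit_proportional_odds()] parameterization: positive slopes favour
#'   high reef-builder cover).
#' @param noise_sd list of noise standard deviations: `trajectory`
#'   (slope, pp/yr), `heatwave` (percentage-difference residual),
#'   `cover_obs` (survey observation noise, pp).
#' @param rng_seed integer seed; one global seed feeds a hierarchical
#'   stream-per-table scheme.
#' @return validated object of class `"synth_config"`.
#' @export
synth_config <- function(n_cells = 200, n_reefs = 55, years = 2000:2019,
                         heatwave_year = 2015, heatwave_anomaly_C = 2.2,
                         sst_base_C = 25.95, sst_amplitude_C = 1.25,
                         sst_peak_doy = 258, sst_ar1_phi = 0.8,
                         sst_noise_sd = 0.15,
                         truth_trajectory_effects = c(
                           fish_scraper = 0.5, fish_grazer = 0.3,
                           fish_total = 0.3, wastewater_effluent = -0.4,
                           nutrient_input = -0.3, urban_runoff = -0.4),
                         truth_heatwave_effects = list(
                           intercept = -20,
                           effects = c(chla = 8, urban_runoff = -8,
                                       sediment_input = -5, fish_scraper = 3,
                                       fish_total = 3)),
                         truth_ordinal = list(
                           C = c(-1.0, 1.5),
                           B = c(fish_scraper = 1.2, wastewater_effluent = -1.0)),
                         noise_sd = list(trajectory = 0.3, heatwave = 8,
                                         cover_obs = 1.5),
                         rng_seed = 1) {
  cfg <- list(n_cells = n_cells, n_reefs = n_reefs, years = years,
              heatwave_year = heatwave_year,
              heatwave_anomaly_C = heatwave_anomaly_C,
              sst_base_C = sst_base_C, sst_amplitude_C = sst_amplitude_C,
              sst_peak_doy = sst_peak_doy, sst_ar1_phi = sst_ar1_phi,
              sst_noise_sd = sst_noise_sd,
              truth_trajectory_effects = truth_trajectory_effects,
              truth_heatwave_effects = truth_heatwave_effects,
              truth_ordinal = truth_ordinal,
              noise_sd = noise_sd, rng_seed = rng_seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  assert_number(cfg$n_cells, "n_cells", lower = 1)
  assert_number(cfg$n_reefs, "n_reefs", lower = 1)
  if (cfg$n_reefs > cfg$n_cells)
    stop_input("invalid config: n_reefs (%d) exceeds n_cells (%d)",
               cfg$n_reefs, cfg$n_cells)
  if (length(cfg$years) < 2L)
    stop_input("invalid config: years must span >= 2 calendar years")
  if (!cfg$heatwave_year %in% cfg$years)
    stop_input("invalid config: heatwave_year %d outside years %d-%d",
               cfg$heatwave_year, min(cfg$years), max(cfg$years))
  if (cfg$heatwave_anomaly_C < 0)
    stop_input("invalid config: heatwave_anomaly_C must be >= 0")
  bad_sd <- names(cfg$noise_sd)[vapply(cfg$noise_sd, function(s) s < 0, logical(1))]
  if (length(bad_sd))
    stop_input("invalid config: negative noise_sd for %s", paste(bad_sd, collapse = ", "))
  to <- cfg$truth_ordinal
  if (length(to$C) != 2L || diff(to$C) <= 0)
    stop_input("invalid config: truth_ordinal$C must be two increasing intercepts")
  if (length(to$B) && (is.null(names(to$B)) || any(names(to$B) == "")))
    stop_input("invalid config: truth_ordinal$B must be a named vector")
  assert_number(cfg$rng_seed, "rng_seed")
  invisible(cfg)
}

# hierarchical stream-per-table seeds derived from the one global seed
synth_streams <- function(rng_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  nms <- c("layout", "sources", "impervious", "rainfall", "sst", "waves",
           "population", "regulations", "ocean_colour", "fish", "trajectory",
           "heatwave", "ordinal")
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(nms)), nms)
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic coastline and its raw driver inputs
#'
#' Produces every raw input the driver layers consume: OSDS and
#' golf-course point sources (log-normal loads), impervious-surface
#' snapshots, daily rainfall per watershed (gamma, seasonal), daily SST
#' (sinusoid + AR(1) + boxcar heatwave anomaly), daily wave power, a
#' population grid with snapshot years, gear regulations, monthly ocean
#' colour, and per-reef fish observations. Deterministic given the
#' config's `rng_seed`.
#'
#' @param config a [synth_config()].
#' @return object of class `"synthetic_bundle"`; see the fields in the
#'   source for the exact schemas (all plain data.frames/vectors).
#' @export
generate_coast <- function(config) {
  if (!inherits(config, "synth_config")) stop_input("config must be a synth_config")
  validate_synth_config(config)
  streams <- synth_streams(config$rng_seed)
  years <- config$years
  n_cells <- as.integer(config$n_cells)
  cells <- data.frame(cell = 0:(n_cells - 1),
                      position_m = (0:(n_cells - 1) + 0.5) * 100)

  reefs <- with_stream(streams[["layout"]], {
    idx <- sort(sample(n_cells, config$n_reefs))
    data.frame(reef_id = sprintf("reef_%03d", seq_len(config$n_reefs)),
               cell = cells$cell[idx],
               position_m = cells$position_m[idx],
               depth_m = round(stats::runif(config$n_reefs, 5, 18), 1))
  })

  # point sources cluster around a few "towns" so land-based loads vary
  # alongshore; loads are right-skewed log-normal
  src <- with_stream(streams[["sources"]], {
    n_towns <- max(2L, round(n_cells / 70))
    towns <- sort(stats::runif(n_towns, 0, max(cells$position_m)))
    n_osds <- max(5L, round(n_cells * 0.6))
    centre <- sample(towns, n_osds, replace = TRUE)
    pos <- pmin(pmax(centre + stats::rnorm(n_osds, 0, 1500), 0), max(cells$position_m))
    osds <- data.frame(
      entry_cell = cells$cell[pmax(1, pmin(n_cells, ceiling(pos / 100)))],
      effluent_l_yr = stats::rlnorm(n_osds, log(2e5), 0.9),
      nitrogen_kg_yr = stats::rlnorm(n_osds, log(25), 0.8),
      inland_distance_m = stats::rexp(n_osds, 1 / 600),
      within_one_year_travel = stats::runif(n_osds) < 0.85)
    n_golf <- max(1L, round(n_cells / 60))
    gpos <- sample(towns, n_golf, replace = TRUE) + stats::rnorm(n_golf, 0, 2000)
    gpos <- pmin(pmax(gpos, 0), max(cells$position_m))
    golf <- data.frame(
      entry_cell = cells$cell[pmax(1, pmin(n_cells, ceiling(gpos / 100)))],
      area_ha = stats::rlnorm(n_golf, log(40), 0.5),
      inland_distance_m = stats::runif(n_golf, 100, 2000))
    list(osds = osds, golf = golf, towns = towns)
  })

  impervious <- with_stream(streams[["impervious"]], {
    snap_years <- unique(pmin(pmax(c(min(years), min(years) + 5, min(years) + 10,
                                     max(years) - 2), min(years)), max(years)))
    base <- numeric(n_cells)
    for (tw in src$towns)
      base <- base + 30 * exp(-(cells$position_m - tw)^2 / (2 * 3000^2))
    base <- base * stats::rlnorm(n_cells, 0, 0.3)
    do.call(rbind, lapply(seq_along(snap_years), function(j) {
      growth <- 1 + 0.03 * (snap_years[j] - min(years))
      data.frame(cell = cells$cell, year = snap_years[j],
                 impervious_ha = base * growth)
    }))
  })

  n_sheds <- max(2L, ceiling(n_cells / 25))
  shed_of_cell <- pmin(n_sheds, (cells$cell %/% 25) + 1L)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  rainfall <- with_stream(streams[["rainfall"]], {
    season <- 1 + 0.8 * cos(2 * pi * (doy - 15) / 365.25)  # wet winters
    lapply(seq_len(n_sheds), function(w) {
      shed_scale <- stats::rlnorm(1, log(6), 0.4)
      wet <- stats::runif(length(dates)) < 0.30
      amt <- ifelse(wet, stats::rgamma(length(dates), shape = 0.8,
                                       scale = shed_scale * season), 0)
      data.frame(date = dates, rain_m3_ha = amt)
    })
  })
  sediment_longterm <- with_stream(streams[["rainfall"]] + 1L,
                                   stats::rlnorm(n_sheds, log(800), 0.6))

  sst <- with_stream(streams[["sst"]], {
    seasonal <- config$sst_base_C +
      config$sst_amplitude_C * cos(2 * pi * (doy - config$sst_peak_doy) / 365.25)
    ar <- stats::filter(stats::rnorm(length(dates), 0, config$sst_noise_sd),
                        config$sst_ar1_phi, method = "recursive")
    yr <- as.integer(format(dates, "%Y"))
    anomaly <- ifelse(yr == config$heatwave_year &
                        abs(doy - config$sst_peak_doy) <= 45,
                      config$heatwave_anomaly_C, 0)
    regional <- seasonal + as.numeric(ar) + anomaly
    # MMM from the deterministic seasonal climatology (max monthly mean)
    one_year <- data.frame(
      month = as.integer(format(dates[yr == min(years)], "%m")),
      sst = seasonal[yr == min(years)])
    mmm <- max(tapply(one_year$sst, one_year$month, mean))
    list(dates = dates, regional = regional, mmm = mmm,
         reef_offset = stats::setNames(stats::rnorm(nrow(reefs), 0, 0.1),
                                       reefs$reef_id))
  })

  waves <- with_stream(streams[["waves"]], {
    regional <- stats::rlnorm(length(dates), log(2), 0.7) *
      (1 + 0.5 * cos(2 * pi * (doy - 20) / 365.25))
    list(dates = dates, regional = regional,
         reef_scale = stats::setNames(stats::rlnorm(nrow(reefs), 0, 0.3),
                                      reefs$reef_id))
  })

  population <- with_stream(streams[["population"]], {
    gx <- seq(500, max(cells$position_m), by = 1000)
    gy <- seq(500, 9500, by = 1000)
    grid <- expand.grid(x = gx, y = gy)
    pop0 <- numeric(nrow(grid))
    for (tw in src$towns)
      pop0 <- pop0 + 4000 * exp(-((grid$x - tw)^2 + grid$y^2) / (2 * 4000^2))
    pop0 <- pop0 * stats::rlnorm(nrow(grid), 0, 0.4)
    snap_years <- seq(min(years), max(years), by = 5)
    pop <- vapply(snap_years, function(yy)
      pop0 * (1 + 0.01 * (yy - min(years))), numeric(nrow(grid)))
    list(grid = grid, years = snap_years, pop = pop)
  })

  regulations <- with_stream(streams[["regulations"]], {
    rank <- sample(1:6, nrow(reefs), replace = TRUE,
                   prob = c(0.08, 0.10, 0.12, 0.20, 0.15, 0.35))
    flags <- list(
      `1` = c(TRUE, TRUE, TRUE, TRUE), `2` = c(FALSE, TRUE, TRUE, TRUE),
      `3` = c(FALSE, TRUE, FALSE, TRUE), `4` = c(FALSE, TRUE, FALSE, FALSE),
      `5` = c(FALSE, FALSE, FALSE, TRUE), `6` = c(FALSE, FALSE, FALSE, FALSE))
    fl <- t(vapply(rank, function(r) flags[[as.character(r)]], logical(4)))
    data.frame(reef_id = reefs$reef_id, no_take = fl[, 1], no_lay_net = fl[, 2],
               no_spear = fl[, 3], no_aquarium = fl[, 4])
  })

  ocean_colour <- with_stream(streams[["ocean_colour"]], {
    reef_chla <- stats::rlnorm(nrow(reefs), log(0.15), 0.5)
    grid <- expand.grid(reef_id = reefs$reef_id, year = years, month = 1:12,
                        stringsAsFactors = FALSE)
    grid$chla_mg_m3 <- reef_chla[match(grid$reef_id, reefs$reef_id)] *
      stats::rlnorm(nrow(grid), 0, 0.25) *
      (1 + 0.3 * cos(2 * pi * (grid$month - 2) / 12))
    grid$irradiance_E_m2_d <- 45 - 25 * grid$chla_mg_m3 /
      max(grid$chla_mg_m3) + stats::rnorm(nrow(grid), 0, 2)
    grid
  })

  fish_obs <- with_stream(streams[["fish"]], {
    species <- data.frame(
      species = sprintf("sp_%02d", 1:12),
      a = round(stats::runif(12, 0.008, 0.03), 4),
      b = round(stats::runif(12, 2.85, 3.05), 3),
      guild = c("scraper", "scraper", "grazer", "grazer", "browser", "browser",
                "other-herbivore", "other-herbivore", rep("other", 4)),
      mean_tl = stats::runif(12, 12, 30),
      base_count = stats::runif(12, 2, 8))
    # latent per-reef assemblage quality (log-normal multipliers per guild)
    lat <- cbind(scraper = stats::rlnorm(nrow(reefs), 0, 0.6),
                 grazer = stats::rlnorm(nrow(reefs), 0, 0.5),
                 browser = stats::rlnorm(nrow(reefs), 0, 0.5),
                 other = stats::rlnorm(nrow(reefs), 0, 0.4))
    rownames(lat) <- reefs$reef_id
    fish_years <- years[years >= min(years) + 3]
    rows <- expand.grid(reef_id = reefs$reef_id, year = fish_years,
                        species = species$species, stringsAsFactors = FALSE)
    rows <- merge(rows, species, by = "species")
    g <- ifelse(rows$guild %in% c("scraper", "grazer", "browser"),
                rows$guild, "other")
    rows$count <- stats::rpois(nrow(rows),
                               rows$base_count * lat[cbind(rows$reef_id, g)])
    rows <- rows[rows$count > 0, ]
    rows$tl_cm <- round(rows$mean_tl * stats::rlnorm(nrow(rows), 0, 0.2), 1)
    rows$area_m2 <- 125
    rows[, c("reef_id", "year", "species", "count", "tl_cm", "a", "b",
             "guild", "area_m2")]
  })

  structure(list(config = config, streams = streams, cells = cells,
                 reefs = reefs, osds_sources = src$osds,
                 golf_sources = src$golf, impervious_snapshots = impervious,
                 watershed_of_cell = shed_of_cell, rainfall = rainfall,
                 sediment_longterm = sediment_longterm, sst = sst,
                 waves = waves, population = population,
                 regulations = regulations, ocean_colour = ocean_colour,
                 fish_obs = fish_obs),
            class = "synthetic_bundle")
}

#' Compute the per-reef, per-year driver table from a synthetic bundle
#'
#' Runs every driver-layer operation on the bundle's raw inputs and
#' assembles the annual factor table (long format: `reef_id`, `year`,
#' `variable`, `value`). Deterministic given the bundle.
#'
#' @param bundle a `"synthetic_bundle"` from [generate_coast()].
#' @return long-format data.frame of drivers; cached on the bundle by
#'   [generate_outcomes()].
#' @export
build_driver_table <- function(bundle) {
  if (!inherits(bundle, "synthetic_bundle")) stop_input("expected a synthetic_bundle")
  cfg <- bundle$config
  years <- cfg$years
  reefs <- bundle$reefs
  cells <- bundle$cells
  n_reefs <- nrow(reefs)

  ww <- wastewater_load(bundle$osds_sources, cells)
  nut <- nutrient_input(ww$nitrogen_kg_ha_yr, bundle$golf_sources, cells)
  reef_row <- match(reefs$cell, cells$cell)
  urb <- urban_runoff(bundle$impervious_snapshots, cells, years)

  yr_dates <- as.integer(format(bundle$rainfall[[1]]$date, "%Y"))
  shed_rain <- lapply(bundle$rainfall, function(r)
    rainfall_metrics(r$date, r$rain_m3_ha))
  shed_sed <- lapply(seq_along(shed_rain), function(w) {
    q <- stats::setNames(shed_rain[[w]]$peak3day_m3_ha, shed_rain[[w]]$year)
    sediment_input(bundle$sediment_longterm[w], q)
  })

  sst_dates_yr <- as.integer(format(bundle$sst$dates, "%Y"))
  wave_dates_yr <- as.integer(format(bundle$waves$dates, "%Y"))

  pop_by_reef <- vapply(seq_len(n_reefs), function(i) {
    counts <- vapply(seq_along(bundle$population$years), function(j)
      population_within(data.frame(bundle$population$grid,
                                   pop = bundle$population$pop[, j]),
                        x = reefs$position_m[i], y = 0),
      numeric(1))
    interpolate_years(bundle$population$years, counts, years)
  }, numeric(length(years)))

  ranks <- vapply(seq_len(n_reefs), function(i) {
    r <- bundle$regulations[i, ]
    gear_rank(r$no_take, r$no_lay_net, r$no_spear, r$no_aquarium)
  }, integer(1))

  rows <- list()
  add <- function(reef_id, year, variable, value)
    rows[[length(rows) + 1L]] <<- data.frame(reef_id = reef_id, year = year,
                                             variable = variable, value = value)
  fo <- bundle$fish_obs
  for (i in seq_len(n_reefs)) {
    rid <- reefs$reef_id[i]
    shed <- bundle$watershed_of_cell[reef_row[i]]
    sr <- shed_rain[[shed]]; sd_tab <- shed_sed[[shed]]
    reef_sst_off <- bundle$sst$reef_offset[[rid]]
    wscale <- bundle$waves$reef_scale[[rid]]
    for (y in years) {
      sst_y <- bundle$sst$regional[sst_dates_yr == y] + reef_sst_off
      ss <- sst_summary(sst_y)
      add(rid, y, "sst_mean", ss$mean)
      add(rid, y, "sst_sd", ss$sd)
      add(rid, y, "dhw_max", dhw(sst_y, bundle$sst$mmm))
      add(rid, y, "wave_power",
          wave_power_metric(bundle$waves$regional[wave_dates_yr == y] * wscale))
      add(rid, y, "rainfall_annual", sr$annual_m3_ha[sr$year == y])
      add(rid, y, "rainfall_peak", sr$peak3day_m3_ha[sr$year == y])
      add(rid, y, "sediment_input", sd_tab$sediment_kg_ha[sd_tab$year == y])
      oc <- bundle$ocean_colour[bundle$ocean_colour$reef_id == rid &
                                  bundle$ocean_colour$year == y, ]
      add(rid, y, "chla", mean(oc$chla_mg_m3))
      add(rid, y, "irradiance", mean(oc$irradiance_E_m2_d))
      obs_y <- fo[fo$reef_id == rid & fo$year == y, ]
      if (nrow(obs_y)) {
        add(rid, y, "fish_total", fish_biomass(obs_y))
        add(rid, y, "fish_herbivore",
            fish_biomass(obs_y, guilds = c("scraper", "grazer", "browser",
                                           "other-herbivore")))
        add(rid, y, "fish_scraper", fish_biomass(obs_y, guilds = "scraper"))
        add(rid, y, "fish_grazer", fish_biomass(obs_y, guilds = "grazer"))
        add(rid, y, "fish_browser", fish_biomass(obs_y, guilds = "browser"))
      }
    }
    add(rid, years, "population", pop_by_reef[, i])
    add(rid, years, "wastewater_effluent",
        rep(ww$effluent_l_ha_yr[reef_row[i]], length(years)))
    add(rid, years, "nutrient_input",
        rep(nut$nitrogen_kg_ha_yr[reef_row[i]], length(years)))
    u_i <- urb[urb$cell == reefs$cell[i], ]
    add(rid, years, "urban_runoff", u_i$impervious_ha[match(years, u_i$year)])
    add(rid, years, "gear_rank", rep(ranks[i], length(years)))
    add(rid, years, "depth", rep(reefs$depth_m[i], length(years)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# declarative aggregation windows per analysis stage, relative to the
# configured year range and heatwave year
driver_windows <- function(stage, years, heatwave_year) {
  y0 <- min(years); y1 <- max(years)
  fish0 <- y0 + 3
  switch(stage,
    trajectory = list(
      fish = list(years = fish0:(heatwave_year - 1), fun = "mean"),
      chronic = list(years = y0:(heatwave_year - 1), fun = "mean"),
      episodic = list(years = y0:(heatwave_year - 1), fun = "top5"),
      colour = list(years = (y0 + 2):(heatwave_year - 2), fun = "max"),
      gear = list(years = fish0, fun = "first"),
      dhw = NULL),
    heatwave = list(
      fish = list(years = (heatwave_year - 1):(heatwave_year + 1), fun = "mean"),
      chronic = list(years = (heatwave_year - 3):(heatwave_year + 1), fun = "mean"),
      episodic = list(years = (heatwave_year - 9):(heatwave_year + 1), fun = "top3"),
      colour = list(years = heatwave_year, fun = "mean"),
      gear = list(years = heatwave_year - 1, fun = "first"),
      dhw = list(years = heatwave_year, fun = "max"),
      sst = list(years = y0:(heatwave_year - 1), fun = "mean")),
    persistence = list(
      fish = list(years = (heatwave_year + 1):y1, fun = "mean"),
      chronic = list(years = (heatwave_year + 1):y1, fun = "mean"),
      episodic = list(years = (heatwave_year - 9):y1, fun = "top3"),
      colour = list(years = (heatwave_year + 1):y1, fun = "mean"),
      gear = list(years = heatwave_year + 1, fun = "first"),
      dhw = list(years = heatwave_year, fun = "max"),
      sst = list(years = y0:(y1 - 1), fun = "mean")),
    stop_input("unknown stage '%s'", stage))
}

window_fun <- function(fun) {
  switch(fun,
         mean = function(x) mean(x, na.rm = TRUE),
         max = function(x) max(x, na.rm = TRUE),
         first = function(x) x[1],
         top5 = function(x) top_events_mean(x, 5),
         top3 = function(x) top_events_mean(x, 3))
}

#' Aggregate the annual driver table into per-reef stage predictors
#'
#' Collapses the long-format annual driver table into one row per reef
#' using the stage-specific aggregation windows: survey-period means for
#' fish and chronic (pollution/climate) factors, top-event means for the
#' episodic factors (sediment, wave power; top five pre-disturbance, top
#' three for later stages), the heatwave-year maximum for DHW, the
#' designation-year value for gear restrictions, and climatology
#' maxima/means for ocean colour.
#'
#' @param driver_table long-format driver table from
#'   [build_driver_table()].
#' @param stage `"trajectory"`, `"heatwave"` or `"persistence"`.
#' @param years,heatwave_year the configured year range and heatwave year.
#' @return wide data.frame, one row per reef (`reef_id` column plus one
#'   column per driver).
#' @export
aggregate_drivers <- function(driver_table, stage, years, heatwave_year) {
  win <- driver_windows(stage, years, heatwave_year)
  group_of <- c(fish_total = "fish", fish_herbivore = "fish",
                fish_scraper = "fish", fish_grazer = "fish",
                fish_browser = "fish",
                population = "chronic", wastewater_effluent = "chronic",
                nutrient_input = "chronic", urban_runoff = "chronic",
                rainfall_annual = "chronic", rainfall_peak = "chronic",
                sediment_input = "episodic", wave_power = "episodic",
                chla = "colour", irradiance = "colour",
                gear_rank = "gear", depth = "gear",
                sst_mean = if (is.null(win$sst)) "chronic" else "sst",
                sst_sd = if (is.null(win$sst)) "chronic" else "sst",
                dhw_max = if (is.null(win$dhw)) "chronic" else "dhw")
  reef_ids <- unique(driver_table$reef_id)
  out <- data.frame(reef_id = reef_ids)
  for (v in names(group_of)) {
    spec <- win[[group_of[[v]]]]
    f <- window_fun(spec$fun)
    sub <- driver_table[driver_table$variable == v &
                          driver_table$year %in% spec$years, ]
    vals <- vapply(reef_ids, function(r) {
      x <- sub$value[sub$reef_id == r]
      if (length(x)) f(x) else NA_real_
    }, numeric(1))
    out[[v]] <- vals
  }
  out
}

#' Generate reef outcomes from known injected effects
#'
#' Realizes the three response structures on top of the generated drivers:
#' (i) a pre-disturbance coral-cover slope per reef that is a linear
#' combination of the configured effects on standardized drivers plus
#' noise, unrolled into a survey time series; (ii) a heatwave
#' percentage-difference response from the configured smooth/linear
#' effects, applied to the post-heatwave survey; and (iii) a
#' post-disturbance reef-builder category drawn from the configured
#' proportional-odds model. Covers are simulated on the percent scale and
#' clipped to `[0, 100]`; clipping events are counted in
#' `truth$n_clipped`.
#'
#' @param bundle a `"synthetic_bundle"` (drivers already generated).
#' @param config the same [synth_config()] used for the bundle (defaults
#'   to the bundle's own).
#' @return the bundle with `survey_table` (long benthic survey data),
#'   `driver_table` (cached) and `truth` (injected effects, per-reef
#'   slopes, heatwave responses, ordinal linear predictors, drawn
#'   categories) attached.
#' @export
generate_outcomes <- function(bundle, config = bundle$config) {
  if (!inherits(bundle, "synthetic_bundle")) stop_input("expected a synthetic_bundle")
  needed <- c("osds_sources", "rainfall", "sst", "waves", "fish_obs")
  absent <- needed[vapply(needed, function(f) is.null(bundle[[f]]), logical(1))]
  if (length(absent))
    stop_input("missing driver inputs: %s (run generate_coast first)",
               paste(absent, collapse = ", "))
  any_effects <- length(config$truth_trajectory_effects) > 0 ||
    length(config$truth_heatwave_effects$effects) > 0 ||
    length(config$truth_ordinal$B) > 0
  drv <- bundle$driver_table %||%
    (if (any_effects) build_driver_table(bundle) else NULL)
  years <- config$years
  hw <- config$heatwave_year
  reefs <- bundle$reefs
  n <- nrow(reefs)
  n_clipped <- 0L
  clip <- function(x) {
    n_clipped <<- n_clipped + sum(x < 0 | x > 100)
    pmin(pmax(x, 0), 100)
  }
  dropped_effects <- character()
  # standardized stage drivers for the injected effects; zero-variance
  # drivers (possible on very short coasts) are dropped and recorded
  std_stage <- function(stage, eff_names) {
    agg <- aggregate_drivers(drv, stage, years, hw)
    miss <- setdiff(eff_names, names(agg))
    if (length(miss))
      stop_input("missing driver inputs for effects: %s", paste(miss, collapse = ", "))
    sub <- agg[, eff_names, drop = FALSE]
    sds <- vapply(sub, stats::sd, numeric(1))
    const <- names(sub)[!is.finite(sds) | sds < 1e-10]
    if (length(const)) {
      dropped_effects <<- union(dropped_effects, paste0(stage, ":", const))
      sub <- sub[setdiff(names(sub), const)]
    }
    if (ncol(sub) == 0L) return(matrix(0, nrow(agg), 0))
    as.matrix(standardize_columns(sub))
  }

  beta_tr <- config$truth_trajectory_effects
  slope <- with_stream(bundle$streams[["trajectory"]], {
    base <- if (length(beta_tr)) {
      z <- std_stage("trajectory", names(beta_tr))
      as.numeric(z %*% beta_tr[colnames(z)])
    } else numeric(n)
    base + stats::rnorm(n, 0, config$noise_sd$trajectory)
  })

  hw_eff <- config$truth_heatwave_effects
  delta_pct <- with_stream(bundle$streams[["heatwave"]], {
    base <- rep(hw_eff$intercept, n)
    if (length(hw_eff$effects)) {
      z <- std_stage("heatwave", names(hw_eff$effects))
      base <- base + as.numeric(z %*% hw_eff$effects[colnames(z)])
    }
    pmax(base + stats::rnorm(n, 0, config$noise_sd$heatwave), -100)
  })

  to <- config$truth_ordinal
  ord <- with_stream(bundle$streams[["ordinal"]], {
    eta <- if (length(to$B)) {
      z <- std_stage("persistence", names(to$B))
      as.numeric(z %*% to$B[colnames(z)])
    } else numeric(n)
    p_low <- stats::plogis(to$C[1] - eta)
    p_lowmod <- stats::plogis(to$C[2] - eta)
    u <- stats::runif(n)
    category <- ifelse(u <= p_low, "low", ifelse(u <= p_lowmod, "moderate", "high"))
    builder <- ifelse(category == "low", stats::runif(n, 4, 15),
                      ifelse(category == "moderate", stats::runif(n, 16, 32),
                             stats::runif(n, 33, 52)))
    list(eta = eta,
         category = factor(category, levels = c("low", "moderate", "high"),
                           ordered = TRUE),
         builder_cover = builder)
  })

  first_b <- min(years) + 3
  benthic_years <- sort(unique(c(first_b, first_b + 4, first_b + 8,
                                 hw - 1, hw, hw + 1, hw + 2, max(years))))
  benthic_years <- benthic_years[benthic_years %in% years]
  survey <- with_stream(bundle$streams[["trajectory"]] + 1L, {
    start <- stats::rnorm(n, 36, 4)
    rows <- list()
    for (i in seq_len(n)) {
      prev <- NA_real_
      for (y in benthic_years) {
        if (y <= hw) {
          cov <- start[i] + slope[i] * (y - first_b) +
            stats::rnorm(1, 0, config$noise_sd$cover_obs)
        } else if (y == hw + 1) {
          pre <- start[i] + slope[i] * (hw - first_b)
          cov <- pre * (1 + delta_pct[i] / 100) +
            stats::rnorm(1, 0, config$noise_sd$cover_obs)
        } else if (y == max(years)) {
          # reef-builder cover = hard coral + crustose coralline algae
          cov <- 0.7 * ord$builder_cover[i]
        } else {
          cov <- prev + stats::rnorm(1, 0, config$noise_sd$cover_obs)
        }
        cov <- clip(cov)
        prev <- cov
        rows[[length(rows) + 1L]] <-
          data.frame(reef_id = reefs$reef_id[i], year = y,
                     variable = "coral_cover", value = cov)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(reef_id = reefs$reef_id[i], year = max(years),
                   variable = "cca_cover",
                   value = clip(0.3 * ord$builder_cover[i]))
      rows[[length(rows) + 1L]] <-
        data.frame(reef_id = reefs$reef_id[i], year = max(years),
                   variable = "builder_cover", value = clip(ord$builder_cover[i]))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  bundle$driver_table <- drv
  bundle$survey_table <- survey
  bundle$truth <- list(trajectory_effects = beta_tr,
                       heatwave_effects = hw_eff, ordinal = to,
                       slope = stats::setNames(slope, reefs$reef_id),
                       delta_pct = stats::setNames(delta_pct, reefs$reef_id),
                       eta_post = stats::setNames(ord$eta, reefs$reef_id),
                       category = stats::setNames(ord$category, reefs$reef_id),
                       builder_cover = stats::setNames(ord$builder_cover,
                                                       reefs$reef_id),
                       benthic_years = benthic_years,
                       dropped_effects = dropped_effects,
                       n_clipped = n_clipped)
  bundle
}
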