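# Driver layers: per-reef / per-cell annual human-impact and environmental
# factors computed from raw coastal inputs. Cells are 100 m alongshore
# (1 ha each); distances in metres; years are calendar years.

#' Fish biomass density from belt-transect observations
#'
#' Converts individual fish observations to biomass density using the
#' allometric length-weight conversion W = a * TL^b (W in grams, TL total
#' length in cm, a and b species-specific constants), sums over retained
#' observations and scales to kg per hectare. Life-history groups poorly
#' captured by visual surveys (cryptic, nocturnal, pelagic schooling
#' species) are expected to have been excluded upstream; an optional guild
#' filter restricts the sum to herbivore functional guilds (scraper,
#' grazer, browser).
#'
#' @param obs data.frame with columns `species`, `count`, `tl_cm`, `a`,
#'   `b`, `guild` (one observation may represent several fish via `count`).
#' @param area_m2 surveyed area in square metres (single positive value).
#'   Default 125, a 25 m x 5 m belt transect.
#' @param guilds optional character vector of guilds to retain (e.g.
#'   `c("scraper")`); `NULL` keeps all observations.
#' @return biomass density in kg per hectare (scalar).
#' @export
fish_biomass <- function(obs, area_m2 = 125, guilds = NULL) {
  assert_number(area_m2, "area_m2", lower = .Machine$double.eps)
  obs <- as.data.frame(obs)
  need <- c("species", "count", "tl_cm", "a", "b")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop_input("obs lacks column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(guilds)) {
    if (!"guild" %in% names(obs)) stop_input("guild filter requested but obs has no 'guild' column")
    obs <- obs[obs$guild %in% guilds, , drop = FALSE]
  }
  if (nrow(obs) == 0L) return(0)
  bad <- is.na(obs$a) | is.na(obs$b)
  if (any(bad))
    stop_input("missing length-weight constants for species: %s",
               paste(unique(obs$species[bad]), collapse = ", "))
  if (any(obs$count < 1)) stop_input("counts must be >= 1")
  if (any(obs$tl_cm < 0)) stop_input("total length must be >= 0")
  if (any(obs$a <= 0)) stop_input("length-weight 'a' must be > 0")
  grams <- sum(obs$count * obs$a * obs$tl_cm^obs$b)
  # g / m2 -> kg / ha: (g/1000) / (m2/10000) = 10 * g / m2
  10 * grams / area_m2
}

#' Gaussian coastal dispersal weight
#'
#' Offshore/alongshore dispersal kernel for land-based loads:
#' `exp(-d^2 / (2 sigma^2))`. The default scale `sigma = 2000/3` m makes
#' the weight at 2 km equal `exp(-4.5)` (about 0.011), operationalizing a
#' plume that approaches zero at 2 km from its shoreline entry point.
#'
#' @param distance_m distance(s) in metres, >= 0.
#' @param sigma kernel scale in metres (> 0).
#' @return weights in (0, 1], same length as `distance_m`.
#' @export
dispersal_weight <- function(distance_m, sigma = 2000 / 3) {
  assert_number(sigma, "sigma", lower = .Machine$double.eps)
  if (any(!is.finite(distance_m)) || any(distance_m < 0))
    stop_input("distances must be finite and >= 0")
  exp(-distance_m^2 / (2 * sigma^2))
}

check_sources <- function(sources, cells) {
  sources <- as.data.frame(sources)
  cells <- as.data.frame(cells)
  if (!all(c("cell", "position_m") %in% names(cells)))
    stop_input("cells needs columns 'cell' and 'position_m'")
  if (nrow(sources)) {
    if (!"entry_cell" %in% names(sources) || any(is.na(sources$entry_cell)))
      stop_input("every source needs a shoreline 'entry_cell'")
    if (!all(sources$entry_cell %in% cells$cell))
      stop_input("source entry cell(s) not on the coastline lattice: %s",
                 paste(setdiff(sources$entry_cell, cells$cell), collapse = ", "))
  }
  list(sources = sources, cells = cells)
}

# spread per-source shoreline loads alongshore by the dispersal kernel;
# returns a per-cell vector (load units per ha; cells are 1 ha)
disperse_alongshore <- function(load, entry_cell, cells, sigma, cell_area_ha = 1) {
  out <- numeric(nrow(cells))
  if (!length(load)) return(out)
  pos <- cells$position_m
  entry_pos <- cells$position_m[match(entry_cell, cells$cell)]
  for (s in seq_along(load)) {
    w <- dispersal_weight(abs(pos - entry_pos[s]), sigma = sigma)
    out <- out + load[s] * w
  }
  out / cell_area_ha
}

#' Wastewater effluent and nitrogen loads per coastal cell
#'
#' Assigns each onsite sewage disposal system (OSDS) load to its nearest
#' shoreline entry cell and spreads it along the coast with the Gaussian
#' dispersal kernel. Only sources flagged as lying within a one-year
#' groundwater travel time of the coast contribute. Loads are divided by
#' the 1-ha cell area, yielding l per ha per yr (effluent) and kg per ha
#' per yr (nitrogen). The kernel is applied per source without
#' renormalization, so a receiving cell at distance 0 sees the full load.
#'
#' @param sources data.frame of point sources with columns `entry_cell`,
#'   `effluent_l_yr`, `nitrogen_kg_yr` and logical `within_one_year_travel`.
#' @param cells data.frame with `cell` (index) and `position_m` (alongshore
#'   centre).
#' @param sigma dispersal kernel scale (m).
#' @return data.frame `cell`, `effluent_l_ha_yr`, `nitrogen_kg_ha_yr`.
#' @export
wastewater_load <- function(sources, cells, sigma = 2000 / 3) {
  chk <- check_sources(sources, cells)
  sources <- chk$sources; cells <- chk$cells
  if (nrow(sources)) {
    if (!"within_one_year_travel" %in% names(sources))
      stop_input("sources need a 'within_one_year_travel' flag")
    sources <- sources[sources$within_one_year_travel, , drop = FALSE]
    if (any(sources$effluent_l_yr < 0, na.rm = TRUE) ||
        any(sources$nitrogen_kg_yr < 0, na.rm = TRUE))
      stop_input("source loads must be >= 0")
  }
  data.frame(
    cell = cells$cell,
    effluent_l_ha_yr = disperse_alongshore(sources$effluent_l_yr,
                                           sources$entry_cell, cells, sigma),
    nitrogen_kg_ha_yr = disperse_alongshore(sources$nitrogen_kg_yr,
                                            sources$entry_cell, cells, sigma)
  )
}

#' Nutrient input per coastal cell from OSDS and golf courses
#'
#' Golf-course nitrogen is the course area (ha) times an annual
#' application rate (default 585 kg per ha) times a leaching rate (default
#' 32%), attenuated by a Gaussian inland-distance decay before reaching
#' its shoreline entry cell, then dispersed alongshore like wastewater.
#' The total per-cell nutrient input adds the OSDS nitrogen layer.
#'
#' @param osds_nitrogen per-cell OSDS nitrogen (kg/ha/yr), aligned with
#'   `cells` rows (e.g. from [wastewater_load()]); may be `NULL` for zero.
#' @param golf_sources data.frame with `entry_cell`, `area_ha`,
#'   `inland_distance_m`.
#' @param cells coastal lattice as in [wastewater_load()].
#' @param application_rate_kg_ha annual nitrogen application rate.
#' @param leaching_rate fraction of applied nitrogen that leaches.
#' @param sigma alongshore dispersal scale (m).
#' @param inland_sigma inland decay scale (m).
#' @return data.frame `cell`, `nitrogen_kg_ha_yr` (OSDS + golf).
#' @export
nutrient_input <- function(osds_nitrogen, golf_sources, cells,
                           application_rate_kg_ha = 585, leaching_rate = 0.32,
                           sigma = 2000 / 3, inland_sigma = 1000) {
  chk <- check_sources(golf_sources, cells)
  golf <- chk$sources; cells <- chk$cells
  if (is.null(osds_nitrogen)) osds_nitrogen <- numeric(nrow(cells))
  if (length(osds_nitrogen) != nrow(cells))
    stop_input("osds_nitrogen must align with cells (%d values for %d cells)",
               length(osds_nitrogen), nrow(cells))
  golf_cell <- numeric(nrow(cells))
  if (nrow(golf)) {
    if (any(golf$area_ha < 0)) stop_input("golf areas must be >= 0")
    delivered <- golf$area_ha * application_rate_kg_ha * leaching_rate *
      dispersal_weight(golf$inland_distance_m, sigma = inland_sigma)
    golf_cell <- disperse_alongshore(delivered, golf$entry_cell, cells, sigma)
  }
  data.frame(cell = cells$cell, nitrogen_kg_ha_yr = osds_nitrogen + golf_cell)
}

#' Annual impervious-surface area per cell (urban runoff proxy)
#'
#' Aggregates per-cell impervious area within an alongshore window
#' (default 10 km) of each cell, then fills the years between land-cover
#' snapshots by linear interpolation (constant extrapolation outside the
#' snapshot range). At least two snapshot years are required.
#'
#' @param snapshots data.frame `cell`, `year`, `impervious_ha` (raw
#'   per-cell impervious area in each snapshot year).
#' @param cells coastal lattice (`cell`, `position_m`).
#' @param years integer years wanted in the output.
#' @param window_m half-width of the aggregation window (m).
#' @return data.frame `cell`, `year`, `impervious_ha` (aggregated).
#' @export
urban_runoff <- function(snapshots, cells, years, window_m = 10000) {
  snapshots <- as.data.frame(snapshots)
  cells <- as.data.frame(cells)
  snap_years <- sort(unique(snapshots$year))
  if (length(snap_years) < 2L)
    stop_input("urban runoff interpolation needs >= 2 snapshot years, got %d",
               length(snap_years))
  pos <- cells$position_m
  # aggregate within the alongshore window for each snapshot year
  agg <- matrix(0, nrow(cells), length(snap_years))
  for (j in seq_along(snap_years)) {
    s <- snapshots[snapshots$year == snap_years[j], , drop = FALSE]
    v <- numeric(nrow(cells))
    v[match(s$cell, cells$cell)] <- s$impervious_ha
    agg[, j] <- vapply(seq_len(nrow(cells)), function(i)
      sum(v[abs(pos - pos[i]) <= window_m]), numeric(1))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(cell = cells$cell[i], year = years,
               impervious_ha = interpolate_years(snap_years, agg[i, ], years))
  }))
  rownames(out) <- NULL
  out
}

#' Annual and peak rainfall metrics per drainage
#'
#' From a gap-free daily rainfall series (volume per drainage area,
#' m^3/ha), computes per calendar year the annual total and the peak
#' 3-day rainfall (maximum over all sliding 3-day windows within the
#' year).
#'
#' @param dates `Date` vector (daily, gap-free within each year).
#' @param values daily rainfall (m^3/ha), same length as `dates`.
#' @return data.frame `year`, `annual_m3_ha`, `peak3day_m3_ha`.
#' @export
rainfall_metrics <- function(dates, values) {
  if (length(dates) != length(values)) stop_input("dates/values length mismatch")
  dates <- as.Date(dates)
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  yr <- as.integer(format(dates, "%Y"))
  out <- lapply(sort(unique(yr)), function(y) {
    d <- dates[yr == y]; v <- values[yr == y]
    full <- seq(min(d), max(d), by = "day")
    gaps <- setdiff(as.character(full), as.character(d))
    if (length(gaps))
      stop_input("missing days in %d: %s%s", y,
                 paste(utils::head(gaps, 5), collapse = ", "),
                 if (length(gaps) > 5) sprintf(" (+%d more)", length(gaps) - 5) else "")
    if (length(v) < 3L) stop_input("year %d has fewer than 3 days", y)
    roll3 <- v[1:(length(v) - 2)] + v[2:(length(v) - 1)] + v[3:length(v)]
    data.frame(year = y, annual_m3_ha = sum(v), peak3day_m3_ha = max(roll3))
  })
  do.call(rbind, out)
}

#' Discharge-modulated annual sediment input
#'
#' Scales a watershed's long-term mean sediment load over time with annual
#' discharge via an approximate ratings curve
#' `load_t = mean * (Q_t / Qbar)^beta`, then rescales so that the
#' multi-year mean of the modulated loads equals the long-term mean.
#'
#' @param longterm_mean long-term mean annual sediment load (kg/ha).
#' @param discharge named numeric vector of annual discharge (names =
#'   years); must be non-negative with a positive mean.
#' @param beta ratings-curve exponent (> 0, default 1.5).
#' @return data.frame `year`, `sediment_kg_ha`.
#' @export
sediment_input <- function(longterm_mean, discharge, beta = 1.5) {
  assert_number(longterm_mean, "longterm_mean", lower = 0)
  assert_number(beta, "beta", lower = .Machine$double.eps)
  if (any(discharge < 0)) stop_input("discharge must be >= 0")
  if (all(discharge == 0)) stop_input("all-zero discharge: ratings curve undefined")
  raw <- longterm_mean * (discharge / mean(discharge))^beta
  scaled <- if (mean(raw) > 0) raw * longterm_mean / mean(raw) else raw
  yrs <- suppressWarnings(as.integer(names(discharge)))
  if (is.null(names(discharge)) || anyNA(yrs)) yrs <- seq_along(discharge)
  data.frame(year = yrs, sediment_kg_ha = unname(scaled))
}

#' Summertime SST mean and variability
#'
#' Locates the day with the maximum 7-day moving-mean SST (earliest day on
#' ties) and computes the mean and standard deviation over the 90-day
#' window centred there (centre - 44 to centre + 45 days). The window is
#' truncated at the series bounds; truncation is recorded in the result.
#'
#' @param sst daily SST (deg C) for one year; at least 97 values.
#' @return list with `mean`, `sd`, `centre` (index of the smoothed
#'   maximum), `window` (start/end indices) and `truncated` flag.
#' @export
sst_summary <- function(sst) {
  if (length(sst) < 97L)
    stop_input("sst_summary needs >= 97 daily values, got %d", length(sst))
  sm <- as.numeric(stats::filter(sst, rep(1 / 7, 7), sides = 2))
  centre <- which.max(sm)  # which.max takes the earliest on exact ties
  lo <- centre - 44L; hi <- centre + 45L
  truncated <- lo < 1L || hi > length(sst)
  lo <- max(1L, lo); hi <- min(length(sst), hi)
  win <- sst[lo:hi]
  list(mean = mean(win), sd = stats::sd(win), centre = centre,
       window = c(start = lo, end = hi), truncated = truncated)
}

#' Maximum degree heating weeks
#'
#' NOAA Coral Reef Watch convention: the daily hotspot is SST minus the
#' maximum monthly mean climatology (MMM); hotspots of at least 1 deg C
#' accumulate over a trailing 84-day (12-week) window, divided by 7 to
#' give deg C-weeks. Returns the maximum over all complete windows.
#'
#' @param sst daily SST (deg C); at least 84 values.
#' @param mmm maximum monthly mean climatology (deg C, scalar).
#' @return maximum DHW (deg C-weeks, >= 0).
#' @export
dhw <- function(sst, mmm) {
  if (missing(mmm) || is.null(mmm) || !is.finite(mmm))
    stop_input("MMM climatology is required for DHW")
  n <- length(sst)
  if (n < 84L) stop_input("DHW needs >= 84 daily values, got %d", n)
  hs <- sst - mmm
  acc <- ifelse(hs >= 1, hs, 0)
  cs <- cumsum(acc)
  win <- (cs[84:n] - c(0, cs)[(84:n) - 83]) / 7
  max(win)
}

#' Annual wave exposure statistic
#'
#' Mean of the daily maximum wave-power values at or above the year's
#' 97.5th percentile (linear-interpolation percentile convention). This
#' reads "mean of the top 97.5%" as the mean of the values above the
#' 97.5th percentile, i.e. the extreme-event tail.
#'
#' @param values daily maximum wave power (kW/m) for one year (>= 40
#'   values).
#' @return scalar statistic (kW/m).
#' @export
wave_power_metric <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 40L)
    stop_input("wave metric needs >= 40 daily values, got %d", length(values))
  q <- stats::quantile(values, 0.975, type = 7, names = FALSE)
  mean(values[values >= q])
}

#' Population within a radius of a coastal cell
#'
#' Sums gridded population whose grid-cell centres lie within `radius_m`
#' of the query point (Euclidean distance in a common projected frame).
#'
#' @param grid data.frame `x`, `y` (m), `pop` (persons per grid cell).
#' @param x,y query point coordinates (m).
#' @param radius_m search radius (default 15 km).
#' @return person count (scalar).
#' @export
population_within <- function(grid, x, y, radius_m = 15000) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop_input("empty population grid")
  d2 <- (grid$x - x)^2 + (grid$y - y)^2
  sum(grid$pop[d2 <= radius_m^2])
}

#' Fishing gear-restriction rank
#'
#' Maps regulation flags to the six-level gear-restriction ordering:
#' (1) full no-take; (2) no lay net, spear or aquarium; (3) no lay net or
#' aquarium; (4) no lay net; (5) no aquarium; (6) open to all gear types.
#' Flag combinations outside this scheme (e.g. a spear-only prohibition)
#' are not rankable and raise an error, as does the contradiction of a
#' no-take area declared open to fishing.
#'
#' @param no_take full no-take designation.
#' @param no_lay_net,no_spear,no_aquarium individual gear prohibitions.
#' @param open_access explicit open-access designation (contradicts
#'   `no_take`).
#' @return integer rank in 1..6.
#' @export
gear_rank <- function(no_take = FALSE, no_lay_net = FALSE, no_spear = FALSE,
                      no_aquarium = FALSE, open_access = FALSE) {
  flags <- c(no_take, no_lay_net, no_spear, no_aquarium, open_access)
  if (any(is.na(flags))) stop_input("regulation flags must be TRUE/FALSE")
  if (no_take && open_access)
    stop_input("contradictory flags: no-take area declared open access")
  if (no_take) return(1L)
  if (no_lay_net && no_spear && no_aquarium) return(2L)
  if (no_lay_net && no_aquarium && !no_spear) return(3L)
  if (no_lay_net && !no_spear && !no_aquarium) return(4L)
  if (no_aquarium && !no_lay_net && !no_spear) return(5L)
  if (!no_lay_net && !no_spear && !no_aquarium) return(6L)
  stop_input("gear-prohibition combination outside the six-level ranking scheme")
}
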