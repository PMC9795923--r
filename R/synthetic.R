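# Seeded synthetic migration world: stations, species, ground-truth
# phenology, radar nightly passage series and weekly abundance surfaces.
# Every generator draws from a stream derived by stable hashing of
# (root seed, entity ids) so outputs are reproducible under reordering.

GAUSSIAN_HALF_WIDTH <- sqrt(2 * log(2))  # half-max lead of a Gaussian pulse, in sd units

#' Derive a reproducible per-entity RNG seed
#'
#' Folds the root seed and any number of entity identifiers into a 31-bit
#' integer by polynomial string hashing, so each (seed, station, species,
#' year) combination gets its own stable stream regardless of the order in
#' which entities are simulated.
#'
#' @param seed Root integer seed.
#' @param ... Entity identifiers (coerced to character).
#' @return A single integer suitable for [set.seed()].
#' @export
entity_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Per-order species default parameters
#'
#' The configured defaults table behind [generate_species()]: seasonal peak
#' dates (ordinal), the magnitude of the latitudinal timing slope (days per
#' degree; applied with positive sign in spring and negative in autumn), and
#' pulse width. Anseriformes (waterfowl) peak earlier in spring and later in
#' autumn than Passeriformes, matching their known early-spring/late-autumn
#' migration timing.
#'
#' @return A data.frame with one row per taxonomic order.
#' @export
species_defaults <- function() {
  data.frame(
    order            = c("Anseriformes", "Charadriiformes", "Passeriformes", "other"),
    base_spring_peak = c(85, 140, 125, 120),
    base_autumn_peak = c(305, 240, 265, 270),
    latitude_slope   = c(1.0, 1.2, 1.3, 1.1),
    peak_width       = c(14, 12, 13, 14),
    stringsAsFactors = FALSE
  )
}

# archetype mixture per order (documented constants, not calibrated values)
.archetype_probs <- function(order) {
  switch(order,
    Anseriformes    = c(passage = 0.50, breeder = 0.10, winterer = 0.35, resident = 0.05),
    Charadriiformes = c(passage = 0.70, breeder = 0.15, winterer = 0.10, resident = 0.05),
    Passeriformes   = c(passage = 0.45, breeder = 0.40, winterer = 0.05, resident = 0.10),
    c(passage = 0.40, breeder = 0.30, winterer = 0.15, resident = 0.15)
  )
}

#' Generate a synthetic radar-station network
#'
#' Stations are stratified across the three flyway longitude bands and
#' across latitude (span >= 15 degrees for n >= 5), emulating the contiguous
#' US network. Each station carries the true seasonal passage-pulse peak
#' dates implied by the latitudinal progression of migration (spring later
#' at higher latitude, autumn earlier).
#'
#' @param n Number of stations (>= 1).
#' @param seed Root integer seed.
#' @param longitudes Optional vector of length `n` forcing station
#'   longitudes (latitude and peaks still generated).
#' @return A data.frame: station_id, latitude, longitude, flyway,
#'   spring_peak, autumn_peak.
#' @export
generate_stations <- function(n, seed = 1L, longitudes = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(entity_seed(seed, "stations"))
  band <- rep(c("western", "central", "eastern"), length.out = n)
  lon <- numeric(n)
  lon[band == "western"] <- stats::runif(sum(band == "western"), -125, -103.5)
  lon[band == "central"] <- stats::runif(sum(band == "central"), -103, -90)
  lon[band == "eastern"] <- stats::runif(sum(band == "eastern"), -89.5, -67)
  if (!is.null(longitudes)) {
    if (length(longitudes) != n) stop("`longitudes` must have length n", call. = FALSE)
    lon <- as.numeric(longitudes)
  }
  # systematic (stratified) latitudes with jitter confined to the stratum
  strata <- sample.int(n)
  lat <- 24.5 + 24 * (strata - 0.5 + 0.8 * (stats::runif(n) - 0.5)) / n
  out <- data.frame(
    station_id = sprintf("S%03d", seq_len(n)),
    latitude = lat,
    longitude = lon,
    flyway = assign_flyway(lon),
    stringsAsFactors = FALSE
  )
  out$spring_peak <- 120 + 1.3 * (out$latitude - 37)
  out$autumn_peak <- 270 - 1.0 * (out$latitude - 37)
  out
}

#' Generate a synthetic species pool
#'
#' Taxonomic orders are allocated by largest-remainder rounding of
#' `order_mix`; per-species parameters are the per-order defaults of
#' [species_defaults()] with bounded jitter, a lognormal detectability and
#' an order-specific archetype (passage / breeder / winterer / resident).
#'
#' @param n Number of species (0 allowed).
#' @param order_mix Named proportions over
#'   (Passeriformes, Charadriiformes, Anseriformes, other); must sum to 1.
#' @param seed Root integer seed.
#' @return A data.frame: species_id, order, archetype, base_spring_peak,
#'   base_autumn_peak, latitude_slope, peak_width, detectability.
#' @export
generate_species <- function(n,
                             order_mix = c(Passeriformes = 0.57,
                                           Charadriiformes = 0.16,
                                           Anseriformes = 0.13,
                                           other = 0.14),
                             seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    stop("`n` must be a single nonnegative count", call. = FALSE)
  }
  if (any(order_mix < 0) || abs(sum(order_mix) - 1) > 1e-9) {
    stop("`order_mix` must be nonnegative proportions summing to 1", call. = FALSE)
  }
  n <- as.integer(n)
  empty <- data.frame(species_id = character(0), order = character(0),
                      archetype = character(0), base_spring_peak = numeric(0),
                      base_autumn_peak = numeric(0), latitude_slope = numeric(0),
                      peak_width = numeric(0), detectability = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  if (is.null(names(order_mix))) {
    names(order_mix) <- c("Passeriformes", "Charadriiformes", "Anseriformes", "other")[seq_along(order_mix)]
  }
  # largest-remainder allocation
  raw <- n * order_mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  orders <- rep(names(counts), times = counts)
  defs <- species_defaults()
  def_row <- function(o) if (o %in% defs$order) defs[defs$order == o, ] else defs[defs$order == "other", ]
  set.seed(entity_seed(seed, "species"))
  rows <- lapply(seq_len(n), function(i) {
    o <- orders[i]
    d <- def_row(o)
    jit <- function(sd_days) max(-12, min(12, stats::rnorm(1, 0, sd_days)))
    data.frame(
      species_id = sprintf("SP%03d", i),
      order = o,
      archetype = sample(names(.archetype_probs(o)), 1, prob = .archetype_probs(o)),
      base_spring_peak = d$base_spring_peak + jit(4),
      base_autumn_peak = d$base_autumn_peak + jit(4),
      latitude_slope = max(0.2, d$latitude_slope * exp(stats::rnorm(1, 0, 0.15))),
      peak_width = max(5, d$peak_width * exp(stats::rnorm(1, 0, 0.15))),
      detectability = exp(stats::rnorm(1, 0, 0.4)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# seasonal pulse-peak position for a species at a station
.species_peak <- function(species, station, season) {
  lat <- station$latitude
  if (season == "spring") {
    species$base_spring_peak + species$latitude_slope * (lat - 37)
  } else {
    species$base_autumn_peak - species$latitude_slope * (lat - 37)
  }
}

#' Ground-truth half-max date for a (station, species, season)
#'
#' The true half-max follows from the archetype's closed-form seasonal
#' shape: a Gaussian passage pulse reaches half maximum at
#' `peak - width * sqrt(2 ln 2)` on its rising edge; a breeder's logistic
#' rise crosses half its plateau exactly at its midpoint (the spring peak
#' date), as does the winterer's autumn return; residents have no defined
#' phenology (NA). Dates are clipped to the seasonal window.
#'
#' @param station One-row station data.frame (from [generate_stations()]).
#' @param species One-row species data.frame (from [generate_species()]).
#' @param season `"spring"` or `"autumn"`.
#' @return Ordinal date (numeric scalar), or NA for residents.
#' @export
true_phenology <- function(station, species, season) {
  season <- match.arg(season, c("spring", "autumn"))
  p <- .species_peak(species, station, season)
  w <- season_window(season)
  d <- switch(species$archetype,
    passage  = p - species$peak_width * GAUSSIAN_HALF_WIDTH,
    breeder  = p,   # logistic midpoint (rising in spring, falling in autumn)
    winterer = p,   # mirrored logistic midpoints
    resident = NA_real_,
    stop("unknown archetype: ", species$archetype, call. = FALSE)
  )
  if (is.na(d)) return(NA_real_)
  min(max(d, w[1]), w[2])
}

#' Simulate nightly radar passage for one station and season
#'
#' Nightly migrant passage is a seasonal Gaussian pulse centred on the
#' station's true peak date, scaled per year by a lognormal random
#' intercept (amplitude, not timing, unless `timing_jitter_sd > 0`) and
#' perturbed by multiplicative lognormal observation noise. All values are
#' nonnegative by construction.
#'
#' @param station One-row station data.frame.
#' @param season `"spring"` or `"autumn"`.
#' @param years Integer vector of years.
#' @param noise_sd_log Nightly lognormal noise sd (log scale), >= 0.
#' @param year_effect_sd Year random-intercept sd (log scale), >= 0.
#' @param seed Root integer seed.
#' @param peak_sd_days Pulse width (Gaussian sd, days).
#' @param amplitude Pulse peak passage (birds per km per night).
#' @param timing_jitter_sd Optional per-year timing jitter sd (days);
#'   defaults to 0 so truth dates stay well-defined.
#' @return A data.frame: station_id, year, ordinal_date, passage.
#' @export
simulate_radar_nights <- function(station, season, years,
                                  noise_sd_log = 0.3, year_effect_sd = 0.25,
                                  seed = 1L, peak_sd_days = 15, amplitude = 200,
                                  timing_jitter_sd = 0) {
  season <- match.arg(season, c("spring", "autumn"))
  if (noise_sd_log < 0 || year_effect_sd < 0 || timing_jitter_sd < 0) {
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  }
  w <- season_window(season)
  days <- w[1]:w[2]
  peak <- if (season == "spring") station$spring_peak else station$autumn_peak
  out <- lapply(years, function(yr) {
    set.seed(entity_seed(seed, station$station_id, season, yr))
    year_mult <- exp(stats::rnorm(1, 0, year_effect_sd))
    shift <- if (timing_jitter_sd > 0) stats::rnorm(1, 0, timing_jitter_sd) else 0
    pulse <- amplitude * exp(-(days - peak - shift)^2 / (2 * peak_sd_days^2))
    noise <- exp(stats::rnorm(length(days), 0, noise_sd_log))
    data.frame(station_id = station$station_id, year = yr,
               ordinal_date = days, passage = pulse * year_mult * noise,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# archetype seasonal shape on ordinal dates (unit plateau / peak scale)
.archetype_shape <- function(d, archetype, p_spring, p_autumn, width, ripple = 0.1) {
  k <- width / 2  # logistic steepness
  switch(archetype,
    passage = exp(-(d - p_spring)^2 / (2 * width^2)) +
              exp(-(d - p_autumn)^2 / (2 * width^2)),
    breeder = stats::plogis((d - p_spring) / k) * stats::plogis(-(d - p_autumn) / k),
    winterer = 1 - stats::plogis((d - p_spring) / k) * stats::plogis(-(d - p_autumn) / k),
    resident = 1 + ripple * sin(2 * pi * d / 365),
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
}

#' Simulate a weekly relative-abundance surface slice around one station
#'
#' Generates species x week x cell relative abundance on a regular grid of
#' cell centroids (default spacing 2.96 km) in a local tangent plane around
#' the station. Weekly values follow the species archetype shape evaluated
#' at the 52 week midpoints (ordinal days 4, 11, ..., 361), scaled by
#' detectability and perturbed by multiplicative Gaussian noise truncated
#' at zero.
#'
#' @param species One-row species data.frame.
#' @param station One-row station data.frame.
#' @param n_cells Number of grid cells (>= 1).
#' @param obs_noise_cv Coefficient of variation of the per cell-week noise.
#' @param seed Root integer seed.
#' @param cell_spacing_km Grid spacing (km).
#' @param ripple Resident seasonal ripple amplitude.
#' @param shift_days Shift applied to this species' true peak dates (days);
#'   used to inject a known cross-platform phenology offset.
#' @return A data.frame: species_id, station_id, cell_id, cell_latitude,
#'   cell_longitude, week_midpoint_ordinal, abundance.
#' @export
simulate_ebird_weekly <- function(species, station, n_cells = 9,
                                  obs_noise_cv = 0.1, seed = 1L,
                                  cell_spacing_km = 2.96, ripple = 0.1,
                                  shift_days = 0) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (obs_noise_cv < 0) stop("`obs_noise_cv` must be nonnegative", call. = FALSE)
  weeks <- 4 + 7 * (0:51)
  p_s <- .species_peak(species, station, "spring") + shift_days
  p_a <- .species_peak(species, station, "autumn") + shift_days
  shape <- .archetype_shape(weeks, species$archetype, p_s, p_a,
                            species$peak_width, ripple)
  base <- species$detectability * shape
  # regular grid of cell centroids around the station
  side <- ceiling(sqrt(n_cells))
  offs <- (seq_len(side) - (side + 1) / 2) * cell_spacing_km
  grid <- expand.grid(dx = offs, dy = offs)[seq_len(n_cells), , drop = FALSE]
  km_per_deg_lat <- 111.32
  km_per_deg_lon <- 111.32 * cos(station$latitude * pi / 180)
  set.seed(entity_seed(seed, "ebird", station$station_id, species$species_id))
  out <- lapply(seq_len(n_cells), function(ci) {
    noise <- if (obs_noise_cv > 0) {
      pmax(0, 1 + stats::rnorm(length(weeks), 0, obs_noise_cv))
    } else rep(1, length(weeks))
    data.frame(
      species_id = species$species_id,
      station_id = station$station_id,
      cell_id = sprintf("%s_%s_C%02d", station$station_id, species$species_id, ci),
      cell_latitude = station$latitude + grid$dy[ci] / km_per_deg_lat,
      cell_longitude = station$longitude + grid$dx[ci] / km_per_deg_lon,
      week_midpoint_ordinal = weeks,
      abundance = base * noise,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Simulate a complete synthetic migration world
#'
#' Ties the station, species, radar and weekly-abundance generators together
#' under one root seed and records the ground-truth half-max dates for every
#' (station, season) radar series and (station, species, season) abundance
#' series. `ebird_shift_days` injects a known offset into all abundance
#' truths while leaving radar output untouched, for sign-convention and
#' offset-recovery experiments. Defaults mirror the study conditions the
#' pipeline targets: 143 stations, 293 species in a 57/16/13/14 order mix,
#' and 17 years of nightly radar data.
#'
#' @param n_stations,n_species,years World size.
#' @param n_cells Abundance grid cells per station.
#' @param noise_sd_log,year_effect_sd Radar noise parameters (log scale).
#' @param obs_noise_cv Abundance noise coefficient of variation.
#' @param order_mix Species order proportions.
#' @param seasons Seasons to simulate.
#' @param seed Root integer seed.
#' @param ebird_shift_days Days added to every abundance truth.
#' @param radar_peak_sd_days Radar pulse width (days).
#' @return An object of class `phenomatch_world`: list with elements
#'   stations, species, truth, radar_nights, ebird_weekly.
#' @export
simulate_world <- function(n_stations = 143, n_species = 293,
                           years = 2002:2018, n_cells = 9,
                           noise_sd_log = 0.3, year_effect_sd = 0.25,
                           obs_noise_cv = 0.1,
                           order_mix = c(Passeriformes = 0.57,
                                         Charadriiformes = 0.16,
                                         Anseriformes = 0.13,
                                         other = 0.14),
                           seasons = c("spring", "autumn"),
                           seed = 1L, ebird_shift_days = 0,
                           radar_peak_sd_days = 15) {
  stations <- generate_stations(n_stations, seed = seed)
  species <- generate_species(n_species, order_mix = order_mix, seed = seed)
  radar <- list(); ebird <- list(); truth <- list()
  for (si in seq_len(nrow(stations))) {
    st <- stations[si, ]
    for (season in seasons) {
      radar[[length(radar) + 1L]] <- simulate_radar_nights(
        st, season, years, noise_sd_log = noise_sd_log,
        year_effect_sd = year_effect_sd, seed = seed,
        peak_sd_days = radar_peak_sd_days)
      peak <- if (season == "spring") st$spring_peak else st$autumn_peak
      truth[[length(truth) + 1L]] <- data.frame(
        platform = "radar", station_id = st$station_id, species_id = "ALL",
        season = season,
        true_halfmax = peak - radar_peak_sd_days * GAUSSIAN_HALF_WIDTH,
        stringsAsFactors = FALSE)
    }
    for (pi in seq_len(nrow(species))) {
      sp <- species[pi, ]
      ebird[[length(ebird) + 1L]] <- simulate_ebird_weekly(
        sp, st, n_cells = n_cells, obs_noise_cv = obs_noise_cv,
        seed = seed, shift_days = ebird_shift_days)
      for (season in seasons) {
        tt <- true_phenology(st, sp, season)
        truth[[length(truth) + 1L]] <- data.frame(
          platform = "ebird", station_id = st$station_id,
          species_id = sp$species_id, season = season,
          true_halfmax = if (is.na(tt)) NA_real_ else
            min(max(tt + ebird_shift_days, season_window(season)[1]),
                season_window(season)[2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    stations = stations,
    species = species,
    truth = do.call(rbind, truth),
    radar_nights = do.call(rbind, radar),
    ebird_weekly = do.call(rbind, ebird)
  ), class = "phenomatch_world")
}

#' @export
print.phenomatch_world <- function(x, ...) {
  cat("Synthetic migration world\n")
  cat(sprintf("  stations: %d   species: %d\n", nrow(x$stations), nrow(x$species)))
  cat(sprintf("  radar nights: %d rows   weekly abundance: %d rows\n",
              nrow(x$radar_nights), nrow(x$ebird_weekly)))
  invisible(x)
}
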