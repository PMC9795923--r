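# Pipeline orchestration: configuration defaults, per-platform half-max
# tables, the cross-platform comparison report, schema validation and the
# end-to-end run_all() driver with flat-CSV artifacts and a manifest.

#' Default pipeline configuration
#'
#' Defaults reproduce the analysis settings of the study design: 37.5-km
#' buffers, adjusted-R^2 retention threshold 0.25, basis dimension 20,
#' seasonal windows 1 March-15 June and 1 August-15 November, and a
#' synthetic world of 143 stations, 293 species and 17 years. Any element
#' can be overridden via named arguments, e.g.
#' `pipeline_config(seed = 7, simulate = list(n_stations = 12))`.
#'
#' @param seed Root seed for the whole run.
#' @param ... Named blocks (`simulate`, `radar`, `ebird`, `phenology`,
#'   `comparison`) whose elements override the defaults.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(n_stations = 143L, n_species = 293L, years = 2002:2018,
                    n_cells = 9L, noise_sd_log = 0.3, year_effect_sd = 0.25,
                    obs_noise_cv = 0.1,
                    order_mix = c(Passeriformes = 0.57, Charadriiformes = 0.16,
                                  Anseriformes = 0.13, other = 0.14),
                    ebird_shift_days = 0),
    radar = list(wavelength_cm = 10.7, km2 = 0.93, rcs_cm2 = 11,
                 scan_interval_h = 0.5, bin_depth_km = 0.1),
    ebird = list(radius_km = 37.5),
    phenology = list(r2_min = 0.25, basis_dim = 20L),
    comparison = list(alpha = 0.05, level = 0.95)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Radar half-max table for a set of stations
#'
#' Fits the seasonal smooth (year random intercepts) per station and season
#' on nightly passage and extracts the retained half-max estimate. Stations
#' whose fit is refused (too few nights, singular design) are skipped with
#' a message.
#'
#' @param radar_nights Nightly passage table (station_id, year,
#'   ordinal_date, passage).
#' @param seasons Seasons to process.
#' @param basis_dim,r2_min Phenology settings.
#' @return Half-max data.frame: platform, station_id, species_id ("ALL"),
#'   season, d_max, d_half, edge, r2_adjusted, retained, reason.
#' @export
radar_halfmax_table <- function(radar_nights, seasons = c("spring", "autumn"),
                                basis_dim = 20, r2_min = 0.25) {
  rows <- list()
  for (sid in unique(radar_nights$station_id)) {
    sub <- radar_nights[radar_nights$station_id == sid, , drop = FALSE]
    for (season in seasons) {
      nights <- filter_season(sub, season)
      est <- tryCatch(
        estimate_halfmax(nights$ordinal_date, nights$passage, season,
                         year_labels = nights$year, basis_dim = basis_dim,
                         season_range = season_window(season),
                         platform = "radar", r2_min = r2_min),
        phenomatch_fit_refused = function(e) {
          message(sprintf("radar %s %s: %s", sid, season, conditionMessage(e)))
          NULL
        })
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        platform = "radar", station_id = sid, species_id = "ALL",
        season = season, d_max = est$d_max, d_half = est$d_half,
        edge = est$edge, r2_adjusted = est$r2_adjusted,
        retained = isTRUE(est$retained), reason = est$reason,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_halfmax())
  do.call(rbind, rows)
}

#' Abundance half-max table for buffer-averaged weekly series
#'
#' Fits the seasonal smooth per (species, station, season) on weekly mean
#' abundance over the wide fit windows (4 Jan-28 Jun; 6 Jul-28 Dec),
#' extracts the half-max with the early-peak falling-edge fallback, and
#' applies the retention filter. Absent species (all-zero series) are
#' skipped.
#'
#' @param station_weekly Buffer-averaged series from [buffer_mean()].
#' @param seasons Seasons to process.
#' @param basis_dim,r2_min Phenology settings.
#' @return Half-max data.frame (see [radar_halfmax_table()]).
#' @export
ebird_halfmax_table <- function(station_weekly, seasons = c("spring", "autumn"),
                                basis_dim = 20, r2_min = 0.25) {
  rows <- list()
  if (nrow(station_weekly) > 0L) {
    key <- interaction(station_weekly$species_id, station_weekly$station_id,
                       drop = TRUE)
    for (sl in split(station_weekly, key)) {
      if (all(sl$mean_abundance == 0)) next
      for (season in seasons) {
        fw <- fit_window(season, "ebird")
        sub <- sl[sl$week_midpoint_ordinal >= fw[1] &
                    sl$week_midpoint_ordinal <= fw[2], , drop = FALSE]
        est <- tryCatch(
          estimate_halfmax(sub$week_midpoint_ordinal, sub$mean_abundance,
                           season, basis_dim = basis_dim, season_range = fw,
                           platform = "ebird", r2_min = r2_min),
          phenomatch_fit_refused = function(e) NULL)
        if (is.null(est)) next
        rows[[length(rows) + 1L]] <- data.frame(
          platform = "ebird", station_id = sl$station_id[1],
          species_id = sl$species_id[1], season = season,
          d_max = est$d_max, d_half = est$d_half, edge = est$edge,
          r2_adjusted = est$r2_adjusted, retained = isTRUE(est$retained),
          reason = est$reason, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_halfmax())
  do.call(rbind, rows)
}

.empty_halfmax <- function() {
  data.frame(platform = character(0), station_id = character(0),
             species_id = character(0), season = character(0),
             d_max = integer(0), d_half = integer(0), edge = character(0),
             r2_adjusted = numeric(0), retained = logical(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Buffer-average a whole synthetic world's abundance surfaces
#'
#' @param world A `phenomatch_world`.
#' @param radius_km Buffer radius (km).
#' @return Combined station-weekly data.frame over all stations.
#' @export
aggregate_world_ebird <- function(world, radius_km = 37.5) {
  out <- lapply(seq_len(nrow(world$stations)), function(si) {
    st <- world$stations[si, ]
    slice <- world$ebird_weekly[world$ebird_weekly$station_id == st$station_id, ,
                                drop = FALSE]
    buffer_mean(slice, st, radius_km = radius_km)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(buffer_mean(world$ebird_weekly[0, ],
                                       world$stations[1, ], radius_km))
  rownames(res) <- NULL
  res
}

#' Cross-platform comparison report for one season
#'
#' Builds station records and reports, for the all-species grouping plus
#' each taxonomic order and each flyway: Pearson r with Fisher-z CI and the
#' offset mean +/- SD. Groups with fewer than 4 stations (or zero retained
#' records) are reported with NA statistics rather than dropped.
#'
#' @param halfmax Half-max table (both platforms).
#' @param stations Station table.
#' @param species Species table (for order groups); may be NULL.
#' @param season `"spring"` or `"autumn"`.
#' @param level Confidence level.
#' @return data.frame: season, group, n, r, df, p, ci_low, ci_high,
#'   offset_mean, offset_sd.
#' @export
compare_platforms <- function(halfmax, stations, species = NULL, season,
                              level = 0.95) {
  groups <- list(all = list(order = NULL, flyway = NULL))
  if (!is.null(species)) {
    for (o in intersect(c("Anseriformes", "Charadriiformes", "Passeriformes"),
                        unique(species$order))) {
      groups[[paste0("order:", o)]] <- list(order = o, flyway = NULL)
    }
  }
  for (fw in c("western", "central", "eastern")) {
    groups[[paste0("flyway:", fw)]] <- list(order = NULL, flyway = fw)
  }
  rows <- lapply(names(groups), function(gname) {
    gr <- groups[[gname]]
    rec <- suppressWarnings(build_station_records(
      halfmax, stations, season, species = species, order = gr$order))
    if (!is.null(gr$flyway)) rec <- rec[rec$flyway == gr$flyway, , drop = FALSE]
    base <- data.frame(season = season, group = gname, n = nrow(rec),
                       r = NA_real_, df = NA_integer_, p = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       offset_mean = NA_real_, offset_sd = NA_real_,
                       stringsAsFactors = FALSE)
    if (nrow(rec) >= 1L) {
      base$offset_mean <- mean(rec$offset_days)
      base$offset_sd <- stats::sd(rec$offset_days)
    }
    if (nrow(rec) >= 4L &&
        stats::var(rec$radar_halfmax) > 0 &&
        stats::var(rec$ebird_mean_halfmax) > 0) {
      ct <- pearson_with_ci(rec$radar_halfmax, rec$ebird_mean_halfmax,
                            level = level, group = gname)
      base$r <- ct$r; base$df <- ct$df; base$p <- ct$p
      base$ci_low <- ct$ci_low; base$ci_high <- ct$ci_high
    }
    base
  })
  do.call(rbind, rows)
}

# ---- schema validation ---------------------------------------------------

.schemas <- function() {
  list(
    stations = list(
      cols = c("station_id", "latitude", "longitude", "flyway"),
      unique_key = "station_id",
      checks = list(
        latitude = function(x) x >= 24 & x <= 49,
        longitude = function(x) x >= -180 & x < 0,
        flyway = function(x) x %in% c("western", "central", "eastern"))),
    species = list(
      cols = c("species_id", "order", "archetype", "base_spring_peak",
               "base_autumn_peak", "latitude_slope", "peak_width",
               "detectability"),
      unique_key = "species_id",
      checks = list(peak_width = function(x) x > 0,
                    detectability = function(x) x >= 0)),
    truth = list(
      cols = c("platform", "station_id", "species_id", "season",
               "true_halfmax"),
      unique_key = c("platform", "station_id", "species_id", "season"),
      checks = list(season = function(x) x %in% c("spring", "autumn"))),
    radar_nights = list(
      cols = c("station_id", "year", "ordinal_date", "passage"),
      unique_key = c("station_id", "year", "ordinal_date"),
      checks = list(passage = function(x) x >= 0,
                    ordinal_date = function(x) x >= 1 & x <= 365)),
    ebird_weekly = list(
      cols = c("species_id", "station_id", "cell_id", "week_midpoint_ordinal",
               "abundance"),
      unique_key = c("species_id", "station_id", "cell_id",
                     "week_midpoint_ordinal"),
      checks = list(abundance = function(x) x >= 0,
                    week_midpoint_ordinal = function(x) x >= 1 & x <= 365)),
    station_weekly = list(
      cols = c("species_id", "station_id", "week_midpoint_ordinal",
               "mean_abundance", "n_cells"),
      unique_key = c("species_id", "station_id", "week_midpoint_ordinal"),
      checks = list(mean_abundance = function(x) x >= 0,
                    n_cells = function(x) x >= 1)),
    halfmax = list(
      cols = c("platform", "station_id", "species_id", "season", "d_max",
               "d_half", "edge", "r2_adjusted", "retained", "reason"),
      unique_key = c("platform", "station_id", "species_id", "season"),
      checks = list(platform = function(x) x %in% c("radar", "ebird"),
                    season = function(x) x %in% c("spring", "autumn"))),
    scan_profiles = list(
      cols = c("station_id", "timestamp", "year", "ordinal_date",
               "height_bin_lower_m", "groundspeed_kmh"),
      unique_key = c("station_id", "timestamp", "height_bin_lower_m"),
      checks = list(
        height_bin_lower_m = function(x) x %in% seq(0, 2900, by = 100),
        groundspeed_kmh = function(x) x >= 0))
  )
}

#' Validate a pipeline CSV against its schema
#'
#' Checks column presence, value ranges (dates within the calendar,
#' nonnegative abundances and passage, longitudes negative, ...) and
#' uniqueness keys. Violations are reported, never silently coerced. The
#' scan-profile schema additionally requires 30 height bins per
#' station-scan and at least one of the dbz / eta columns.
#'
#' @param path CSV file path.
#' @param schema_name One of stations, species, truth, radar_nights,
#'   ebird_weekly, station_weekly, halfmax, scan_profiles.
#' @return List of class `schema_validation`: `ok` (logical) and
#'   `violations` (character vector, empty when ok).
#' @export
validate_schema <- function(path, schema_name) {
  schemas <- .schemas()
  schema_name <- match.arg(schema_name, names(schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- schemas[[schema_name]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- character(0)
  missing <- setdiff(sc$cols, names(df))
  if (length(missing) > 0L) {
    v <- c(v, sprintf("missing column: %s", missing))
  }
  for (col in names(sc$checks)) {
    if (!col %in% names(df)) next
    bad <- !sc$checks[[col]](df[[col]]) | is.na(df[[col]])
    if (any(bad)) {
      v <- c(v, sprintf("column %s: %d value(s) out of range", col, sum(bad)))
    }
  }
  keys <- intersect(sc$unique_key, names(df))
  if (length(keys) == length(sc$unique_key) && nrow(df) > 0L) {
    dup <- duplicated(df[, keys, drop = FALSE])
    if (any(dup)) {
      v <- c(v, sprintf("duplicate rows on key (%s): %d",
                        paste(keys, collapse = ", "), sum(dup)))
    }
  }
  if (schema_name == "scan_profiles" && nrow(df) > 0L) {
    if (!any(c("dbz", "eta") %in% names(df))) {
      v <- c(v, "missing column: dbz or eta")
    }
    if (all(c("station_id", "timestamp") %in% names(df))) {
      nb <- tapply(df$height_bin_lower_m,
                   interaction(df$station_id, df$timestamp, drop = TRUE),
                   function(x) length(unique(x)))
      if (any(nb != 30L)) {
        v <- c(v, sprintf("%d scan(s) without exactly 30 height bins",
                          sum(nb != 30L)))
      }
    }
  }
  structure(list(ok = length(v) == 0L, violations = v, schema = schema_name),
            class = "schema_validation")
}

#' @export
print.schema_validation <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("schema %s: ok\n", x$schema))
  } else {
    cat(sprintf("schema %s: %d violation(s)\n", x$schema, length(x$violations)))
    for (v in x$violations) cat("  -", v, "\n")
  }
  invisible(x)
}

# ---- end-to-end driver ---------------------------------------------------

# stable 31-bit polynomial hash of the deparsed config, for the manifest
.config_hash <- function(cfg) {
  txt <- paste(deparse(cfg, control = "all"), collapse = "\n")
  h <- 17
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline on a synthetic world
#'
#' Executes simulate -> radar phenology -> buffer aggregation -> abundance
#' phenology -> comparison, writing every intermediate as flat CSV plus a
#' manifest (config hash, seed, row counts) to `out_dir`. Identical
#' configurations produce byte-identical outputs. A stage failure aborts
#' with the failing stage named; artifacts written before the failure are
#' retained for inspection.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory tables (world, halfmax,
#'   station_weekly, comparison, tests) and `paths` of the written files.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("phenomatch_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, stage = name, parent = e)))
    })
  }
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  sim <- config$simulate
  world <- stage("simulate", simulate_world(
    n_stations = sim$n_stations, n_species = sim$n_species,
    years = sim$years, n_cells = sim$n_cells,
    noise_sd_log = sim$noise_sd_log, year_effect_sd = sim$year_effect_sd,
    obs_noise_cv = sim$obs_noise_cv, order_mix = sim$order_mix,
    seed = config$seed, ebird_shift_days = sim$ebird_shift_days))
  paths <- list(
    stations = wcsv(world$stations, "stations.csv"),
    species = wcsv(world$species, "species.csv"),
    truth = wcsv(world$truth, "truth.csv"),
    radar_nights = wcsv(world$radar_nights, "radar_nights.csv"),
    ebird_weekly = wcsv(world$ebird_weekly, "ebird_weekly.csv"))

  ph <- config$phenology
  hm_radar <- stage("radar-phenology", radar_halfmax_table(
    world$radar_nights, basis_dim = ph$basis_dim, r2_min = ph$r2_min))

  station_weekly <- stage("ebird-aggregate", {
    sw <- suppressWarnings(aggregate_world_ebird(world,
                                                 radius_km = config$ebird$radius_km))
    if (nrow(sw) == 0L) {
      message("ebird-aggregate: all stations missing (no cells in buffer)")
    }
    sw
  })
  paths$station_weekly <- wcsv(
    station_weekly[, setdiff(names(station_weekly), "absent"), drop = FALSE],
    "station_weekly.csv")

  hm_ebird <- stage("ebird-phenology", ebird_halfmax_table(
    station_weekly, basis_dim = ph$basis_dim, r2_min = ph$r2_min))
  halfmax <- rbind(hm_radar, hm_ebird)
  paths$halfmax <- wcsv(halfmax, "halfmax.csv")

  result <- stage("compare", {
    if (nrow(hm_ebird) == 0L || nrow(hm_radar) == 0L) {
      stop(structure(class = c("phenomatch_empty_intersection", "error",
                               "condition"),
                     list(message = "no overlapping station estimates between platforms",
                          call = NULL)))
    }
    comparison <- do.call(rbind, lapply(c("spring", "autumn"), function(season)
      compare_platforms(halfmax, world$stations, world$species, season,
                        level = config$comparison$level)))
    dropped <- sum(!halfmax$retained)
    message(sprintf("compare: %d half-max estimate(s) not retained (%s)",
                    dropped, paste(names(table(halfmax$reason[!halfmax$retained])),
                                   collapse = ", ")))
    tests <- .tests_report(halfmax, world, station_weekly, config)
    list(comparison = comparison, tests = tests)
  })
  paths$comparison_report <- wcsv(result$comparison, "comparison_report.csv")
  paths$tests_report <- wcsv(result$tests, "tests_report.csv")

  manifest <- list(
    package = "phenomatch",
    version = as.character(utils::packageVersion("phenomatch")),
    seed = config$seed,
    config_hash = .config_hash(unclass(config)),
    rows = lapply(paths, function(p) length(readLines(p)) - 1L)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(out_dir, "manifest.json")
  invisible(list(world = world, halfmax = halfmax,
                 station_weekly = station_weekly,
                 comparison = result$comparison, tests = result$tests,
                 paths = paths))
}

# ANOVA / Tukey / paired-t / OLS rows for the tests report
.tests_report <- function(halfmax, world, station_weekly, config) {
  rows <- list()
  add <- function(season, test, statistic, df1, df2, p, extra = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      season = season, test = test, statistic = statistic,
      df1 = df1, df2 = df2, p = p, extra = extra, stringsAsFactors = FALSE)
  }
  rich <- list()
  for (season in c("spring", "autumn")) {
    rich[[season]] <- richness_summary(station_weekly, world$stations, season)
    rec <- suppressWarnings(build_station_records(halfmax, world$stations, season))
    rs <- rich[[season]]$per_station
    if (length(unique(rs$flyway)) >= 2L && all(table(rs$flyway) >= 2L) &&
        stats::var(rs$richness) > 0) {
      av <- one_way_anova(rs$richness, rs$flyway)
      add(season, "anova_richness_flyway", av$statistic, av$df[1], av$df[2], av$p)
      if (length(unique(rs$flyway)) >= 3L) {
        tk <- tukey_hsd(rs$richness, rs$flyway, alpha = config$comparison$alpha)
        for (i in seq_len(nrow(tk$pairwise))) {
          add(season, paste0("tukey_richness_", tk$pairwise$pair[i]),
              tk$pairwise$diff[i], NA, NA, tk$pairwise$p_adj[i])
        }
      }
    }
    if (nrow(rec) >= 2L && length(unique(rec$flyway)) >= 2L &&
        all(table(rec$flyway) >= 2L) && stats::var(rec$offset_days) > 0) {
      av <- one_way_anova(rec$offset_days, rec$flyway)
      add(season, "anova_offset_flyway", av$statistic, av$df[1], av$df[2], av$p)
    }
    if (nrow(rec) >= 3L && stats::var(rec$latitude) > 0) {
      ols <- offset_latitude_regression(rec)
      add(season, "ols_offset_latitude", ols$slope, 1, ols$n - 2, ols$p,
          extra = ols$r_squared)
    }
  }
  if (!is.null(rich$spring) && !is.null(rich$autumn)) {
    pt <- paired_t(rich$spring$per_station$richness,
                   rich$autumn$per_station$richness)
    add("both", "paired_t_richness_spring_vs_autumn", pt$statistic,
        pt$df, NA, pt$p, extra = pt$mean_difference)
  }
  if (length(rows) == 0L) {
    return(data.frame(season = character(0), test = character(0),
                      statistic = numeric(0), df1 = numeric(0),
                      df2 = numeric(0), p = numeric(0), extra = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
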