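# Cross-platform comparison: station-level offsets, Pearson correlations
# with Fisher-z intervals, flyway/order contrasts (ANOVA + Tukey HSD),
# paired tests and the offset-versus-latitude regression.

#' Assign a longitude to a migration flyway
#'
#' Western: west of 103 degrees W; central: between 103 and 90 degrees W
#' (closed interval); eastern: east of 90 degrees W.
#'
#' @param longitude Signed decimal degrees in [-180, 0).
#' @return Character vector: `"western"`, `"central"` or `"eastern"`.
#' @export
assign_flyway <- function(longitude) {
  if (any(!is.finite(longitude)) || any(longitude < -180 | longitude >= 0)) {
    stop("`longitude` must lie in [-180, 0)", call. = FALSE)
  }
  ifelse(longitude < -103, "western",
         ifelse(longitude <= -90, "central", "eastern"))
}

#' Build station-level comparison records
#'
#' Pairs the radar half-max with the mean of retained species half-max
#' dates at each station, for one season. The offset is radar minus mean
#' abundance-derived date, so negative offsets mean radar estimated earlier
#' phenology. Stations lacking either platform's estimate are dropped.
#'
#' @param halfmax Half-max table (as written by [run_all()]): platform,
#'   station_id, species_id, season, d_half, retained, ...
#' @param stations Station table (for latitude / flyway).
#' @param season `"spring"` or `"autumn"`.
#' @param species Optional species table; with `order`, restricts the
#'   abundance side to species of one taxonomic order.
#' @param order Optional order name (e.g. `"Passeriformes"`).
#' @return data.frame: station_id, season, flyway, latitude, longitude,
#'   radar_halfmax, ebird_mean_halfmax, n_species, offset_days.
#' @export
build_station_records <- function(halfmax, stations, season,
                                  species = NULL, order = NULL) {
  season <- match.arg(season, c("spring", "autumn"))
  hm <- halfmax[halfmax$season == season & halfmax$retained %in% TRUE, ,
                drop = FALSE]
  radar <- hm[hm$platform == "radar", , drop = FALSE]
  ebird <- hm[hm$platform == "ebird", , drop = FALSE]
  if (!is.null(order)) {
    if (is.null(species)) stop("`species` table needed to filter by order", call. = FALSE)
    keep <- species$species_id[species$order == order]
    ebird <- ebird[ebird$species_id %in% keep, , drop = FALSE]
  }
  empty <- data.frame(station_id = character(0), season = character(0),
                      flyway = character(0), latitude = numeric(0),
                      longitude = numeric(0), radar_halfmax = numeric(0),
                      ebird_mean_halfmax = numeric(0), n_species = integer(0),
                      offset_days = numeric(0), stringsAsFactors = FALSE)
  if (nrow(radar) == 0L || nrow(ebird) == 0L) {
    warning("no overlapping stations between platforms", call. = FALSE)
    return(empty)
  }
  eb_mean <- tapply(ebird$d_half, ebird$station_id, mean)
  eb_n <- tapply(ebird$d_half, ebird$station_id, length)
  shared <- intersect(radar$station_id, names(eb_mean))
  if (length(shared) == 0L) {
    warning("no overlapping stations between platforms", call. = FALSE)
    return(empty)
  }
  radar <- radar[match(shared, radar$station_id), , drop = FALSE]
  st <- stations[match(shared, stations$station_id), , drop = FALSE]
  out <- data.frame(
    station_id = shared, season = season, flyway = st$flyway,
    latitude = st$latitude, longitude = st$longitude,
    radar_halfmax = radar$d_half,
    ebird_mean_halfmax = as.numeric(eb_mean[shared]),
    n_species = as.integer(eb_n[shared]),
    stringsAsFactors = FALSE
  )
  out$offset_days <- out$radar_halfmax - out$ebird_mean_halfmax
  out
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation; the p-value comes from
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 df (two-sided) and the interval from
#' the Fisher z transform, `tanh(atanh(r) +/- z* / sqrt(n-3))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, nonzero variance.
#' @param level Confidence level (default 0.95).
#' @param group Label carried into the result.
#' @return Object of class `phenomatch_cor`: group, n, r, df, p, ci_low,
#'   ci_high.
#' @export
pearson_with_ci <- function(x, y, level = 0.95, group = "all") {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 4L) stop("need n >= 4 for a correlation interval", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop(structure(class = c("phenomatch_undefined_cor", "error", "condition"),
                   list(message = "correlation undefined: zero variance",
                        call = NULL)))
  }
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  r <- max(-1, min(1, r))
  df <- n - 2L
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  zstar <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * zstar / sqrt(n - 3))
  structure(list(group = group, n = n, r = r, df = df, p = p,
                 ci_low = ci[1], ci_high = ci[2], level = level),
            class = "phenomatch_cor")
}

#' @export
print.phenomatch_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation [%s]: r = %.2f, df = %d, p = %.3g, %d%% CI %.2f-%.2f\n",
              x$group, x$r, x$df, x$p, round(100 * x$level), x$ci_low, x$ci_high))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Wraps [stats::aov()]. When every observation is identical the F ratio is
#' reported as 0 with p = 1 rather than NaN.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @return Object of class `phenomatch_test` with test = "anova",
#'   statistic (F), df = c(between, within), p, and the aov fit.
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab[1, "Sum Sq"]; ssw <- tab[2, "Sum Sq"]
  f <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
  if ((ssb + ssw) <= 1e-12 * max(1, sum(values^2))) { f <- 0; p <- 1 }
  structure(list(test = "anova", statistic = f,
                 df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
                 p = p, fit = fit),
            class = "phenomatch_test")
}

#' Tukey honestly-significant-difference post-hoc test
#'
#' Wraps [stats::TukeyHSD()] on the one-way fit; unbalanced designs use the
#' Tukey-Kramer standard error. With only two groups the single pair is
#' reported with a warning.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Family-wise level for the intervals (default 0.05).
#' @return Object of class `phenomatch_test` with test = "tukey_hsd" and a
#'   `pairwise` data.frame (pair, diff, lwr, upr, p_adj).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 3L) {
    warning("fewer than 3 groups: Tukey HSD degenerates to a single pair",
            call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  structure(list(test = "tukey_hsd", pairwise = pw, alpha = alpha, fit = fit),
            class = "phenomatch_test")
}

#' Paired t test
#'
#' Standard paired t on the differences (df = n - 1). When all differences
#' are identical (zero variance) the statistic is reported as 0 with a
#' `zero_variance` flag instead of an error.
#'
#' @param x,y Paired numeric vectors of equal length, n >= 2.
#' @return Object of class `phenomatch_test` with test = "paired_t",
#'   statistic (t), df, p, mean_difference, zero_variance.
#' @export
paired_t <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(structure(list(test = "paired_t", statistic = 0,
                          df = n - 1L, p = 1, mean_difference = mean(d),
                          zero_variance = TRUE),
                     class = "phenomatch_test"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(test = "paired_t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_difference = unname(tt$estimate),
                 zero_variance = FALSE),
            class = "phenomatch_test")
}

#' Offset-versus-latitude regression
#'
#' Ordinary least squares of the station offset (radar minus abundance
#' half-max, days) on station latitude; the slope is in days per degree.
#'
#' @param records Station records from [build_station_records()] (needs
#'   columns offset_days and latitude), n >= 3.
#' @return Object of class `phenomatch_test` with test = "ols", slope,
#'   intercept, p (slope, two-sided), r_squared, n.
#' @export
offset_latitude_regression <- function(records) {
  if (nrow(records) < 3L) stop("need n >= 3 stations", call. = FALSE)
  if (stats::var(records$latitude) == 0) {
    stop(structure(class = c("phenomatch_undefined_slope", "error", "condition"),
                   list(message = "slope undefined: constant latitude",
                        call = NULL)))
  }
  fit <- stats::lm(offset_days ~ latitude, data = records)
  sm <- summary(fit)
  structure(list(test = "ols",
                 slope = unname(stats::coef(fit)["latitude"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 p = sm$coefficients["latitude", "Pr(>|t|)"],
                 r_squared = sm$r.squared, n = nrow(records), fit = fit),
            class = "phenomatch_test")
}

#' @export
print.phenomatch_test <- function(x, ...) {
  switch(x$test,
    anova = cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
                        x$df[1], x$df[2], x$statistic, x$p)),
    tukey_hsd = {
      cat("Tukey HSD pairwise differences:\n")
      print(x$pairwise, row.names = FALSE)
    },
    paired_t = cat(sprintf(
      "Paired t test: t(%d) = %.3f, p = %.3g, mean difference = %.3f%s\n",
      x$df, x$statistic, x$p, x$mean_difference,
      if (isTRUE(x$zero_variance)) " (zero-variance differences)" else "")),
    ols = cat(sprintf(
      "OLS offset ~ latitude: slope = %.3f d/deg, p = %.3g, R^2 = %.3f (n = %d)\n",
      x$slope, x$p, x$r_squared, x$n)),
    cat("phenomatch test:", x$test, "\n"))
  invisible(x)
}

#' Species-richness summary per station and flyway
#'
#' Counts, per station, the species whose buffer-averaged weekly abundance
#' is positive in at least one week of the seasonal retention window
#' (`rule = "nonzero"`, the default), or the species with a retained
#' half-max estimate (`rule = "retained"`, requires `halfmax`). Stations
#' with zero species are kept in the summaries.
#'
#' @param station_weekly Buffer-averaged series from [buffer_mean()].
#' @param stations Station table.
#' @param season `"spring"` or `"autumn"`.
#' @param rule Inclusion rule (see above).
#' @param halfmax Half-max table, needed when `rule = "retained"`.
#' @return List: per_station (station_id, flyway, richness), overall
#'   (mean, sd, n), by_flyway data.frame (flyway, mean, sd, n).
#' @export
richness_summary <- function(station_weekly, stations, season,
                             rule = c("nonzero", "retained"),
                             halfmax = NULL) {
  rule <- match.arg(rule)
  season <- match.arg(season, c("spring", "autumn"))
  counts <- stats::setNames(integer(nrow(stations)), stations$station_id)
  if (rule == "nonzero") {
    sw <- station_weekly[in_season_window(station_weekly$week_midpoint_ordinal,
                                          season) &
                           station_weekly$mean_abundance > 0, , drop = FALSE]
    if (nrow(sw) > 0L) {
      tab <- tapply(sw$species_id, sw$station_id,
                    function(s) length(unique(s)))
      counts[names(tab)] <- as.integer(tab)
    }
  } else {
    if (is.null(halfmax)) stop("`halfmax` needed for rule = 'retained'", call. = FALSE)
    hm <- halfmax[halfmax$platform == "ebird" & halfmax$season == season &
                    halfmax$retained %in% TRUE, , drop = FALSE]
    if (nrow(hm) > 0L) {
      tab <- tapply(hm$species_id, hm$station_id,
                    function(s) length(unique(s)))
      counts[names(tab)] <- as.integer(tab)
    }
  }
  per_station <- data.frame(station_id = stations$station_id,
                            flyway = stations$flyway,
                            richness = as.integer(counts),
                            stringsAsFactors = FALSE)
  by_flyway <- do.call(rbind, lapply(split(per_station, per_station$flyway),
    function(gr) data.frame(flyway = gr$flyway[1], mean = mean(gr$richness),
                            sd = stats::sd(gr$richness), n = nrow(gr),
                            stringsAsFactors = FALSE)))
  rownames(by_flyway) <- NULL
  list(per_station = per_station,
       overall = list(mean = mean(per_station$richness),
                      sd = stats::sd(per_station$richness),
                      n = nrow(per_station)),
       by_flyway = by_flyway)
}
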