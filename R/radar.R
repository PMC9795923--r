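# Radar-side processing: reflectivity factor -> reflectivity -> migration
# traffic rate -> nightly passage, then seasonal filtering.

#' Radar conversion constants
#'
#' Community-standard S-band (WSR-88D) values: wavelength 10.7 cm,
#' dielectric factor |Km|^2 = 0.93, and an assumed per-bird radar cross
#' section of 11 cm^2. Scan cadence 30 min, height bins 100 m deep.
#'
#' @param wavelength_cm Radar wavelength (cm).
#' @param km2 Dielectric factor |Km|^2 (dimensionless).
#' @param rcs_cm2 Assumed radar cross-section per bird (cm^2).
#' @param scan_interval_h Scan interval (hours).
#' @param bin_depth_km Height-bin depth (km).
#' @return A list of class `radar_constants`.
#' @export
radar_constants <- function(wavelength_cm = 10.7, km2 = 0.93, rcs_cm2 = 11,
                            scan_interval_h = 0.5, bin_depth_km = 0.1) {
  vals <- c(wavelength_cm, km2, rcs_cm2, scan_interval_h, bin_depth_km)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all radar constants must be strictly positive", call. = FALSE)
  }
  structure(list(wavelength_cm = wavelength_cm, km2 = km2, rcs_cm2 = rcs_cm2,
                 scan_interval_h = scan_interval_h, bin_depth_km = bin_depth_km),
            class = "radar_constants")
}

#' Convert reflectivity factor (dBZ) to reflectivity (eta)
#'
#' eta = 10^(dBZ/10) * 10^3 * pi^5 * |Km|^2 / lambda^4, in cm^2 km^-3.
#' Strictly increasing in dBZ; a 10 dBZ step multiplies eta by 10.
#'
#' @param dbz Reflectivity factor (dBZ), finite.
#' @param constants A [radar_constants()] object.
#' @return Reflectivity eta (cm^2 km^-3).
#' @export
dbz_to_eta <- function(dbz, constants = radar_constants()) {
  if (any(!is.finite(dbz))) stop("`dbz` must be finite", call. = FALSE)
  10^(dbz / 10) * 1e3 * pi^5 * constants$km2 / constants$wavelength_cm^4
}

#' Invert [dbz_to_eta()]
#'
#' @param eta Reflectivity (cm^2 km^-3), > 0.
#' @param constants A [radar_constants()] object.
#' @return Reflectivity factor (dBZ).
#' @export
eta_to_dbz <- function(eta, constants = radar_constants()) {
  if (any(!is.finite(eta)) || any(eta <= 0)) {
    stop("`eta` must be finite and > 0", call. = FALSE)
  }
  10 * log10(eta * constants$wavelength_cm^4 / (1e3 * pi^5 * constants$km2))
}

#' Migration traffic rate within one height bin
#'
#' rate = (eta / sigma_bird) * groundspeed * bin depth, in birds km^-1 h^-1.
#' eta / sigma_bird is bird density (birds km^-3); multiplying by
#' groundspeed (km h^-1) gives a flux which the 100-m bin depth converts to
#' a per-transect rate.
#'
#' @param eta Reflectivity (cm^2 km^-3), >= 0.
#' @param groundspeed Groundspeed (km h^-1), >= 0.
#' @param constants A [radar_constants()] object.
#' @return Migration traffic rate (birds km^-1 h^-1).
#' @export
rate_per_bin <- function(eta, groundspeed, constants = radar_constants()) {
  if (any(!is.finite(eta)) || any(eta < 0)) stop("`eta` must be >= 0", call. = FALSE)
  if (any(!is.finite(groundspeed)) || any(groundspeed < 0)) {
    stop("`groundspeed` must be >= 0", call. = FALSE)
  }
  (eta / constants$rcs_cm2) * groundspeed * constants$bin_depth_km
}

#' Integrate one night of scans to nightly passage
#'
#' Sums the per-bin migration traffic rate over all height bins and scans of
#' one station-night, weighting each scan by the (uniform) scan interval:
#' passage = sum(rate) * dt, in birds km^-1 per night. The night is labelled
#' with the ordinal date of the evening on which it began.
#'
#' @param scans A data.frame of scan-profile rows for a single station-night
#'   with columns station_id, timestamp, year, ordinal_date,
#'   height_bin_lower_m, groundspeed_kmh and at least one of dbz / eta.
#' @param constants A [radar_constants()] object.
#' @return One-row data.frame: station_id, year, ordinal_date, passage,
#'   n_scans.
#' @export
integrate_night <- function(scans, constants = radar_constants()) {
  if (is.null(scans) || nrow(scans) == 0L) {
    stop(structure(class = c("phenomatch_empty_night", "error", "condition"),
                   list(message = "no scans supplied for this night", call = NULL)))
  }
  if (length(unique(scans$station_id)) != 1L || length(unique(scans$ordinal_date)) != 1L) {
    stop("`scans` must cover exactly one station-night", call. = FALSE)
  }
  eta <- if ("eta" %in% names(scans) && !all(is.na(scans$eta))) {
    scans$eta
  } else if ("dbz" %in% names(scans)) {
    dbz_to_eta(scans$dbz, constants)
  } else {
    stop("scans must carry `dbz` or `eta`", call. = FALSE)
  }
  rates <- rate_per_bin(eta, scans$groundspeed_kmh, constants)
  data.frame(
    station_id = scans$station_id[1],
    year = scans$year[1],
    ordinal_date = scans$ordinal_date[1],
    passage = sum(rates) * constants$scan_interval_h,
    n_scans = length(unique(scans$timestamp)),
    stringsAsFactors = FALSE
  )
}

#' Process a scan-profile table into nightly passage
#'
#' Groups scans by (station, year, evening ordinal date), integrates each
#' night via [integrate_night()], and optionally restricts to a seasonal
#' window.
#'
#' @param scans Scan-profile data.frame (see [integrate_night()]).
#' @param constants A [radar_constants()] object.
#' @param season Optional `"spring"` or `"autumn"` filter.
#' @return Nightly passage data.frame.
#' @export
process_scans <- function(scans, constants = radar_constants(), season = NULL) {
  key <- interaction(scans$station_id, scans$year, scans$ordinal_date, drop = TRUE)
  nights <- do.call(rbind, lapply(split(scans, key), integrate_night,
                                  constants = constants))
  rownames(nights) <- NULL
  nights <- nights[order(nights$station_id, nights$year, nights$ordinal_date), ]
  if (!is.null(season)) nights <- filter_season(nights, season)
  rownames(nights) <- NULL
  nights
}

#' Restrict nightly passage to a seasonal window
#'
#' Spring: 1 March-15 June (ordinal 60-166); autumn: 1 August-15 November
#' (ordinal 213-319), both inclusive on the 365-day calendar.
#'
#' @param nights Nightly passage data.frame with an `ordinal_date` column.
#' @param season `"spring"` or `"autumn"`.
#' @return The filtered data.frame.
#' @export
filter_season <- function(nights, season) {
  nights[in_season_window(nights$ordinal_date, season), , drop = FALSE]
}
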