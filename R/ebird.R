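# Weekly relative-abundance aggregation: great-circle buffers around radar
# stations and unweighted cell means per species-week.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km on a sphere of radius 6371.0088 km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Cells within a buffer radius of a station
#'
#' @param station One-row station data.frame (latitude, longitude).
#' @param cells data.frame with cell_id, cell_latitude, cell_longitude
#'   (duplicated cell_ids are collapsed).
#' @param radius_km Buffer radius (km), > 0; default 37.5.
#' @return Character vector of cell_ids whose centroid lies within
#'   `radius_km` of the station (inclusive).
#' @export
cells_in_buffer <- function(station, cells, radius_km = 37.5) {
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("`radius_km` must be > 0", call. = FALSE)
  }
  if (nrow(cells) == 0L) return(character(0))
  cells <- cells[!duplicated(cells$cell_id), , drop = FALSE]
  d <- haversine_km(station$latitude, station$longitude,
                    cells$cell_latitude, cells$cell_longitude)
  cells$cell_id[d <= radius_km]
}

#' Buffer-average a weekly abundance surface at a station
#'
#' For each species, takes the unweighted arithmetic mean of abundance over
#' all cells within the buffer, per week midpoint. A species whose 52 weekly
#' means are all zero is flagged absent at the station. Species with zero
#' in-buffer cells are dropped with a warning.
#'
#' @param surface Weekly abundance data.frame: species_id, cell_id,
#'   cell_latitude, cell_longitude, week_midpoint_ordinal, abundance.
#' @param station One-row station data.frame.
#' @param radius_km Buffer radius (km); default 37.5.
#' @return data.frame: species_id, station_id, week_midpoint_ordinal,
#'   mean_abundance, n_cells, absent.
#' @export
buffer_mean <- function(surface, station, radius_km = 37.5) {
  empty <- data.frame(species_id = character(0), station_id = character(0),
                      week_midpoint_ordinal = numeric(0),
                      mean_abundance = numeric(0), n_cells = integer(0),
                      absent = logical(0), stringsAsFactors = FALSE)
  if (nrow(surface) == 0L) return(empty)
  out <- lapply(split(surface, surface$species_id), function(sl) {
    cells <- unique(sl[, c("cell_id", "cell_latitude", "cell_longitude")])
    keep <- cells_in_buffer(station, cells, radius_km)
    if (length(keep) == 0L) {
      warning(sprintf("species %s: no cells within %.3f km of station %s; marked missing",
                      sl$species_id[1], radius_km, station$station_id),
              call. = FALSE)
      return(NULL)
    }
    sl <- sl[sl$cell_id %in% keep, , drop = FALSE]
    m <- tapply(sl$abundance, sl$week_midpoint_ordinal, mean)
    weeks <- as.numeric(names(m))
    data.frame(species_id = sl$species_id[1], station_id = station$station_id,
               week_midpoint_ordinal = weeks, mean_abundance = as.numeric(m),
               n_cells = length(keep), absent = all(m == 0),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
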