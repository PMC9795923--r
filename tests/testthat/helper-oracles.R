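# Independent oracles and small fixture builders used across the suite.

# destination point at a bearing/distance on the sphere (direct geodesic on
# a sphere; independent of the package's haversine)
dest_point <- function(lat, lon, bearing_deg, dist_km, R = 6371.0088) {
  rad <- pi / 180
  phi1 <- lat * rad; lam1 <- lon * rad
  th <- bearing_deg * rad; delta <- dist_km / R
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(th))
  lam2 <- lam1 + atan2(sin(th) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  c(lat = phi2 / rad, lon = lam2 / rad)
}

gauss_pulse <- function(d, mu, sd, A = 1) A * exp(-(d - mu)^2 / (2 * sd^2))

# one-row station fixture
make_station <- function(id = "S001", lat = 37, lon = -95,
                         spring_peak = 120, autumn_peak = 270) {
  data.frame(station_id = id, latitude = lat, longitude = lon,
             flyway = assign_flyway(lon), spring_peak = spring_peak,
             autumn_peak = autumn_peak, stringsAsFactors = FALSE)
}

# one-row species fixture
make_species <- function(id = "SP001", order = "Passeriformes",
                         archetype = "passage", spring = 125, autumn = 265,
                         slope = 1.3, width = 13, detect = 1) {
  data.frame(species_id = id, order = order, archetype = archetype,
             base_spring_peak = spring, base_autumn_peak = autumn,
             latitude_slope = slope, peak_width = width,
             detectability = detect, stringsAsFactors = FALSE)
}

# integer-grid half-max crossing of a Gaussian pulse sampled on `grid`:
# threshold from the grid maximum, crossing by direct arithmetic
gauss_halfmax_oracle <- function(mu, sd, grid) {
  f <- gauss_pulse(grid, mu, sd)
  dmax <- grid[which.max(f)]
  half <- 0.5 * max(f)
  # f(d) >= half iff d >= mu - sd*sqrt(-2*log(half)) on the rising limb
  cross <- mu - sd * sqrt(-2 * log(half))
  candidates <- grid[grid >= cross & grid <= dmax]
  min(candidates)
}

# brute-force Pearson r from explicit sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# explicit sum-of-squares one-way ANOVA F
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); N <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Tukey-Kramer adjusted p for every pair, via the studentized-range quantile
tukey_oracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); N <- length(values)
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) / (N - k)
  nms <- names(g)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- mean(g[[j]]) - mean(g[[i]])
    se <- sqrt(mse / 2 * (1 / length(g[[i]]) + 1 / length(g[[j]])))
    out[[paste(nms[j], nms[i], sep = "-")]] <-
      c(diff = diff,
        p = stats::ptukey(abs(diff) / se, k, N - k, lower.tail = FALSE))
  }
  out
}
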