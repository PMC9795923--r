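# Synthetic migration world: determinism, structure, and closed-form truth.

test_that("station generation is deterministic, unique and spans the flyways", {
  a <- generate_stations(143, seed = 7)
  b <- generate_stations(143, seed = 7)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$station_id), 0L)
  expect_setequal(unique(a$flyway), c("western", "central", "eastern"))
  expect_gte(diff(range(a$latitude)), 15)
  expect_true(all(a$longitude >= -125 & a$longitude <= -67))
  c1 <- generate_stations(1, seed = 11)
  c2 <- generate_stations(1, seed = 11)
  expect_identical(c1, c2)
  expect_error(generate_stations(0), "count")
})

test_that("forced longitudes map onto the three flyways", {
  st <- generate_stations(3, seed = 1, longitudes = c(-105, -95, -80))
  expect_equal(st$flyway, c("western", "central", "eastern"))
})

test_that("species order allocation follows the proportions exactly", {
  sp <- generate_species(100, order_mix = c(Passeriformes = 0.57,
                                            Charadriiformes = 0.16,
                                            Anseriformes = 0.13,
                                            other = 0.14), seed = 2)
  expect_equal(as.vector(table(sp$order)[c("Passeriformes", "Charadriiformes",
                                           "Anseriformes", "other")]),
               c(57L, 16L, 13L, 14L))
  expect_equal(nrow(generate_species(0)), 0L)
  expect_equal(anyDuplicated(sp$species_id), 0L)
  expect_error(generate_species(10, order_mix = c(0.5, 0.4)), "sum")
})

test_that("waterfowl are configured earlier in spring than the songbird default", {
  sp <- generate_species(38, order_mix = c(Anseriformes = 1), seed = 5)
  defaults <- species_defaults()
  pass_spring <- defaults$base_spring_peak[defaults$order == "Passeriformes"]
  pass_autumn <- defaults$base_autumn_peak[defaults$order == "Passeriformes"]
  expect_true(all(sp$base_spring_peak < pass_spring))
  expect_true(all(sp$base_autumn_peak > pass_autumn))
})

test_that("true phenology is linear in latitude and clipped to the window", {
  sp <- make_species(slope = 1.5, width = 10, archetype = "passage")
  s1 <- make_station(lat = 30); s2 <- make_station(lat = 40)
  d1 <- true_phenology(s1, sp, "spring")
  d2 <- true_phenology(s2, sp, "spring")
  expect_equal(d2 - d1, 15)
  # zero slope: base peak minus the Gaussian half-rise lead
  sp0 <- make_species(slope = 0, width = 10)
  expect_equal(true_phenology(make_station(lat = 45), sp0, "spring"),
               125 - 10 * sqrt(2 * log(2)))
  # autumn: southern station 20 days later at slope magnitude 1
  spa <- make_species(slope = 1, width = 10)
  a_s <- true_phenology(make_station(lat = 25), spa, "autumn")
  a_n <- true_phenology(make_station(lat = 45), spa, "autumn")
  expect_equal(a_s - a_n, 20)
  # clipping
  sp_early <- make_species(spring = 40, slope = 0, width = 5)
  expect_equal(true_phenology(make_station(), sp_early, "spring"),
               season_window("spring")[1])
  expect_true(is.na(true_phenology(make_station(),
                                   make_species(archetype = "resident"),
                                   "spring")))
})

test_that("noiseless radar simulation is the exact pulse with argmax at the peak", {
  st <- make_station(spring_peak = 120)
  nights <- simulate_radar_nights(st, "spring", years = 2010,
                                  noise_sd_log = 0, year_effect_sd = 0,
                                  peak_sd_days = 15, amplitude = 200)
  w <- season_window("spring")
  expect_equal(nights$ordinal_date, w[1]:w[2])
  expect_equal(nights$passage,
               gauss_pulse(nights$ordinal_date, 120, 15, 200))
  expect_equal(nights$ordinal_date[which.max(nights$passage)], 120)
  expect_error(simulate_radar_nights(st, "spring", 2010, noise_sd_log = -1),
               "nonnegative")
})

test_that("radar simulation is seed-deterministic and nonnegative", {
  st <- make_station()
  a <- simulate_radar_nights(st, "autumn", 2010:2012, seed = 9)
  b <- simulate_radar_nights(st, "autumn", 2010:2012, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$passage >= 0))
  # one row per (year, night)
  expect_equal(nrow(a), 3 * diff(season_window("autumn")) + 3)
})

test_that("per-year argmax of a noisy pulse is unbiased around the true peak", {
  # Monte-Carlo check of the noise model: mean per-year argmax near day 120
  st <- make_station(spring_peak = 120)
  argmaxes <- unlist(lapply(1:50, function(seed) {
    nights <- simulate_radar_nights(st, "spring", years = 2002:2018,
                                    noise_sd_log = 0.3, year_effect_sd = 0.25,
                                    seed = seed, peak_sd_days = 15)
    vapply(split(nights, nights$year),
           function(yr) yr$ordinal_date[which.max(yr$passage)], 0)
  }))
  expect_lte(abs(mean(argmaxes) - 120), 2)
})

test_that("weekly abundance archetypes have their closed-form shapes", {
  st <- make_station(lat = 37)
  # resident, no ripple, no noise: 52 identical values
  res <- simulate_ebird_weekly(make_species(archetype = "resident"), st,
                               n_cells = 1, obs_noise_cv = 0, ripple = 0)
  expect_equal(nrow(res), 52L)
  expect_equal(length(unique(res$abundance)), 1L)
  # passage, no noise: max week contains the true peak date
  sp <- make_species(archetype = "passage", spring = 123, slope = 0)
  pas <- simulate_ebird_weekly(sp, st, n_cells = 1, obs_noise_cv = 0)
  wk <- pas$week_midpoint_ordinal[which.max(pas$abundance[pas$week_midpoint_ordinal < 180])]
  expect_lte(abs(wk - 123), 3.5)
  # breeder, no noise: value at the spring-midpoint week is half the plateau
  spb <- make_species(archetype = "breeder", spring = 116, autumn = 270,
                      slope = 0, detect = 2)
  br <- simulate_ebird_weekly(spb, st, n_cells = 1, obs_noise_cv = 0)
  at_mid <- br$abundance[br$week_midpoint_ordinal == 116]
  plateau <- max(br$abundance)
  expect_equal(at_mid, plateau / 2, tolerance = 1e-2)
  expect_error(simulate_ebird_weekly(make_species(archetype = "nope"), st),
               "archetype")
  expect_true(all(pas$abundance >= 0))
})

test_that("shifting abundance truths leaves radar output untouched", {
  w0 <- simulate_world(n_stations = 2, n_species = 2, years = 2010:2011,
                       n_cells = 2, seed = 4, ebird_shift_days = 0)
  w5 <- simulate_world(n_stations = 2, n_species = 2, years = 2010:2011,
                       n_cells = 2, seed = 4, ebird_shift_days = 5)
  expect_identical(w0$radar_nights, w5$radar_nights)
  t0 <- w0$truth[w0$truth$platform == "ebird" & !is.na(w0$truth$true_halfmax), ]
  t5 <- w5$truth[w5$truth$platform == "ebird" & !is.na(w5$truth$true_halfmax), ]
  interior <- t0$true_halfmax > season_window("spring")[1] + 5 &
    abs(t0$true_halfmax - season_window(t0$season[1])[2]) > 5
  expect_true(all(abs((t5$true_halfmax - t0$true_halfmax)[interior] - 5) < 1e-9))
})

test_that("the noiseless pulse half-max matches the Gaussian closed form", {
  # ground-truth identity enabling downstream oracles
  st <- make_station(spring_peak = 120)
  nights <- simulate_radar_nights(st, "spring", 2010, noise_sd_log = 0,
                                  year_effect_sd = 0, peak_sd_days = 15)
  cross <- 120 - 15 * sqrt(2 * log(2))
  half <- max(nights$passage) / 2
  above <- nights$ordinal_date[nights$passage >= half &
                                 nights$ordinal_date <= 120]
  expect_equal(min(above), ceiling(cross))
})
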