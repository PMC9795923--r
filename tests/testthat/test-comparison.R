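# Flyway assignment, station records, and the statistical toolkit against
# independent brute-force oracles.

test_that("flyway boundaries follow the 103/90 degree rule, closed interval central", {
  expect_equal(assign_flyway(-105), "western")
  expect_equal(assign_flyway(-95), "central")
  expect_equal(assign_flyway(-80), "eastern")
  expect_equal(assign_flyway(-103), "central")
  expect_equal(assign_flyway(-90), "central")
  expect_equal(assign_flyway(c(-120, -100, -70)),
               c("western", "central", "eastern"))
  expect_error(assign_flyway(10), "longitude")
  expect_error(assign_flyway(-181), "longitude")
})

make_halfmax <- function(radar, ebird_by_species) {
  # radar: named vector station -> d_half; ebird: list station -> named species vec
  rows <- lapply(names(radar), function(s) {
    data.frame(platform = "radar", station_id = s, species_id = "ALL",
               season = "spring", d_max = radar[[s]] + 15,
               d_half = radar[[s]], edge = "rising", r2_adjusted = 0.9,
               retained = TRUE, reason = "ok", stringsAsFactors = FALSE)
  })
  for (s in names(ebird_by_species)) {
    v <- ebird_by_species[[s]]
    for (sp in names(v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        platform = "ebird", station_id = s, species_id = sp,
        season = "spring", d_max = v[[sp]] + 15, d_half = v[[sp]],
        edge = "rising", r2_adjusted = 0.9, retained = TRUE, reason = "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("station records average species and sign the offset radar-minus-abundance", {
  st <- generate_stations(2, seed = 1, longitudes = c(-100, -85))
  hm <- make_halfmax(c(S001 = 108, S002 = 100),
                     list(S001 = c(A = 100, B = 110), S002 = c(A = 105)))
  rec <- build_station_records(hm, st, "spring")
  r1 <- rec[rec$station_id == "S001", ]
  expect_equal(r1$ebird_mean_halfmax, 105)
  expect_equal(r1$offset_days, 3)
  expect_equal(r1$n_species, 2L)
  r2 <- rec[rec$station_id == "S002", ]
  expect_equal(r2$offset_days, -5)   # radar earlier => negative
  # station with zero retained species is absent
  hm2 <- make_halfmax(c(S001 = 108, S002 = 100), list(S001 = c(A = 100)))
  rec2 <- build_station_records(hm2, st, "spring")
  expect_equal(rec2$station_id, "S001")
  # empty intersection warns and returns empty
  hm3 <- make_halfmax(c(S001 = 108), list())
  expect_warning(rec3 <- build_station_records(hm3, st, "spring"),
                 "overlapping")
  expect_equal(nrow(rec3), 0L)
})

test_that("shifting every abundance half-max by +k shifts every offset by -k", {
  st <- generate_stations(3, seed = 2)
  hm <- make_halfmax(c(S001 = 100, S002 = 110, S003 = 120),
                     list(S001 = c(A = 98, B = 104), S002 = c(A = 112),
                          S003 = c(A = 118, B = 121)))
  base <- build_station_records(hm, st, "spring")
  k <- 4
  hm_k <- hm
  hm_k$d_half[hm_k$platform == "ebird"] <- hm_k$d_half[hm_k$platform == "ebird"] + k
  shifted <- build_station_records(hm_k, st, "spring")
  expect_equal(shifted$offset_days, base$offset_days - k)
})

test_that("Pearson r, p and Fisher CI match brute-force computation", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  ct <- pearson_with_ci(x, y)
  r_o <- pearson_oracle(x, y)
  expect_equal(ct$r, r_o, tolerance = 1e-12)
  tval <- r_o * sqrt(3 / (1 - r_o^2))
  expect_equal(ct$p, 2 * pt(-abs(tval), 3), tolerance = 1e-12)
  expect_equal(ct$ci_low, tanh(atanh(r_o) - qnorm(0.975) / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(ct$ci_high, tanh(atanh(r_o) + qnorm(0.975) / sqrt(2)),
               tolerance = 1e-12)
  # cross-check against the reference implementation
  ref <- cor.test(x, y)
  expect_equal(ct$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-9)
  expect_equal(c(ct$ci_low, ct$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-6)
})

test_that("correlation limits and invariances hold", {
  x <- c(1, 2, 4, 7, 11)
  same <- pearson_with_ci(x, x)
  expect_equal(same$r, 1)
  expect_equal(same$ci_high, 1)
  neg <- pearson_with_ci(x, -x)
  expect_equal(neg$r, -1)
  set.seed(3)
  y <- x + rnorm(5)
  a <- pearson_with_ci(x, y)
  b <- pearson_with_ci(2 + 3 * x, y)      # positive affine transform
  expect_equal(a$r, b$r, tolerance = 1e-12)
  cneg <- pearson_with_ci(-x, y)          # antisymmetry under negation
  expect_equal(cneg$r, -a$r, tolerance = 1e-12)
  expect_error(pearson_with_ci(rep(1, 5), y),
               class = "phenomatch_undefined_cor")
  expect_error(pearson_with_ci(1:3, 1:3), "n >= 4")
})

test_that("one-way ANOVA matches the explicit sum-of-squares decomposition", {
  set.seed(11)
  values <- c(rnorm(5, 0), rnorm(8, 1), rnorm(12, 3))
  groups <- rep(c("a", "b", "c"), c(5, 8, 12))
  got <- one_way_anova(values, groups)
  want <- anova_oracle(values, groups)
  expect_equal(got$statistic, want$f, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)
  expect_equal(unname(got$df), c(2, 22))
  # no between-group variance: F = 0, p = 1
  flat <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1, tolerance = 1e-12)
  # all identical observations: F defined as 0
  ident <- one_way_anova(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  # two groups: F = t^2
  v2 <- c(rnorm(6), rnorm(6, 1)); g2 <- rep(c("a", "b"), each = 6)
  f2 <- one_way_anova(v2, g2)
  t2 <- t.test(v2 ~ g2, var.equal = TRUE)$statistic
  expect_equal(f2$statistic, unname(t2)^2, tolerance = 1e-8)
})

test_that("Tukey HSD matches the studentized-range oracle (Tukey-Kramer SE)", {
  set.seed(21)
  values <- c(rnorm(5, 0), rnorm(9, 0.5), rnorm(7, 3))
  groups <- rep(c("a", "b", "c"), c(5, 9, 7))
  got <- tukey_hsd(values, groups)
  want <- tukey_oracle(values, groups)
  for (pair in got$pairwise$pair) {
    expect_equal(got$pairwise$diff[got$pairwise$pair == pair],
                 unname(want[[pair]]["diff"]), tolerance = 1e-8)
    expect_equal(got$pairwise$p_adj[got$pairwise$pair == pair],
                 unname(want[[pair]]["p"]), tolerance = 1e-8)
  }
  # three identical groups: all adjusted p = 1
  same <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(abs(same$pairwise$p_adj - 1) < 1e-10))
  # antisymmetry under pair reversal (relevel the factor)
  rev_groups <- factor(groups, levels = c("c", "b", "a"))
  got_rev <- tukey_hsd(values, rev_groups)
  d_ab <- got$pairwise$diff[got$pairwise$pair == "b-a"]
  d_ba <- got_rev$pairwise$diff[got_rev$pairwise$pair == "a-b"]
  expect_equal(d_ab, -d_ba, tolerance = 1e-12)
  expect_warning(tukey_hsd(c(1, 2, 3, 4), c("a", "a", "b", "b")), "single pair")
})

test_that("Tukey adjusted p is at least the unadjusted pairwise t p", {
  set.seed(33)
  values <- c(rnorm(6, 0, 1), rnorm(6, 1, 1), rnorm(6, 2, 1))
  groups <- rep(c("a", "b", "c"), each = 6)
  tk <- tukey_hsd(values, groups)
  g <- split(values, groups)
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) /
    (length(values) - length(g))
  for (pair in tk$pairwise$pair) {
    gs <- strsplit(pair, "-")[[1]]
    se <- sqrt(mse * (1 / length(g[[gs[1]]]) + 1 / length(g[[gs[2]]])))
    tval <- (mean(g[[gs[1]]]) - mean(g[[gs[2]]])) / se
    p_unadj <- 2 * pt(-abs(tval), length(values) - length(g))
    expect_gte(tk$pairwise$p_adj[tk$pairwise$pair == pair] + 1e-12, p_unadj)
  }
})

test_that("paired t matches the hand computation and handles degeneracies", {
  x <- c(5, 7, 9); y <- c(4, 5, 6)   # differences 1, 2, 3
  got <- paired_t(x, y)
  expect_equal(got$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(got$df, 2)
  expect_equal(got$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-10)
  # swap negates t
  rev <- paired_t(y, x)
  expect_equal(rev$statistic, -got$statistic, tolerance = 1e-10)
  # identical vectors: zero-variance path
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_true(same$zero_variance)
})

test_that("offset-latitude regression recovers exact and noisy linear structure", {
  recs <- data.frame(offset_days = -0.5 * c(30, 35, 40, 45) + 2,
                     latitude = c(30, 35, 40, 45))
  got <- suppressWarnings(offset_latitude_regression(recs))
  expect_equal(got$slope, -0.5, tolerance = 1e-12)
  expect_equal(got$r_squared, 1, tolerance = 1e-12)
  # brute-force slope
  x <- recs$latitude; y <- recs$offset_days
  expect_equal(got$slope, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
               tolerance = 1e-12)
  # permutation invariance
  perm <- suppressWarnings(offset_latitude_regression(recs[c(3, 1, 4, 2), ]))
  expect_equal(perm$slope, got$slope, tolerance = 1e-12)
  expect_error(offset_latitude_regression(
    data.frame(offset_days = 1:3, latitude = rep(40, 3))),
    class = "phenomatch_undefined_slope")
  # Monte-Carlo: slope recovered within 0.1 across seeds
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    lat <- runif(143, 25, 48)
    df <- data.frame(latitude = lat, offset_days = -0.5 * lat + rnorm(143))
    offset_latitude_regression(df)$slope
  }, 0)
  expect_lte(max(abs(slopes + 0.5)), 0.1)
})

test_that("richness summaries count included species per station and flyway", {
  st <- generate_stations(2, seed = 1, longitudes = c(-100, -85))
  weeks <- 4 + 7 * (0:51)
  mk <- function(st_id, sp, vals) {
    data.frame(species_id = sp, station_id = st_id,
               week_midpoint_ordinal = weeks, mean_abundance = vals,
               n_cells = 1L, stringsAsFactors = FALSE)
  }
  in_spring <- as.numeric(in_season_window(weeks, "spring"))
  sw <- rbind(mk("S001", "A", in_spring), mk("S001", "B", in_spring),
              mk("S001", "C", in_spring),
              mk("S002", "A", in_spring), mk("S002", "B", 0 * weeks),
              mk("S002", "D", in_spring), mk("S002", "E", in_spring),
              mk("S002", "F", in_spring), mk("S002", "G", in_spring))
  rs <- richness_summary(sw, st, "spring")
  expect_equal(rs$per_station$richness, c(3L, 5L))
  expect_equal(rs$overall$mean, 4)
  expect_equal(rs$overall$sd, sqrt(2))
  # station with zero species kept in summaries
  st3 <- generate_stations(3, seed = 1, longitudes = c(-100, -85, -120))
  rs3 <- richness_summary(sw, st3, "spring")
  expect_equal(sort(rs3$per_station$richness), c(0L, 3L, 5L))
  expect_equal(rs3$overall$n, 3L)
})
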