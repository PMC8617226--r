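test_that("invalid scenarios are rejected with the offending field named", {
  expect_error(synthetic_scenario(n_stocks = 0), "n_stocks")
  expect_error(synthetic_scenario(n_countries = 0), "n_countries")
  expect_error(synthetic_scenario(year_range = c(2000, 2005)), "year_range")
  expect_error(synthetic_scenario(noise_sd = -1), "noise_sd")
  expect_error(synthetic_scenario(noise_sd = Inf), "noise_sd")
  expect_error(synthetic_scenario(archetype = "middling"), "archetype")
  expect_error(
    synthetic_scenario(n_countries = 3,
                       latent_resilience = c(C01 = 0.5, C02 = 0.5)),
    "latent_resilience"
  )
})

test_that("regeneration with the same seed is identical", {
  sc <- synthetic_scenario(seed = 1, n_countries = 3, n_stocks = 2,
                           noise_sd = 0.2)
  d1 <- generate_dataset(sc)
  d2 <- generate_dataset(sc)
  for (tb in c("stock_series", "reference_points", "species_traits",
               "catches", "country_records", "bounds")) {
    expect_identical(d1[[tb]], d2[[tb]])
  }
  d3 <- generate_dataset(synthetic_scenario(seed = 2, n_countries = 3,
                                            n_stocks = 2, noise_sd = 0.2))
  expect_false(identical(d1$stock_series$ssb, d3$stock_series$ssb))
})

test_that("generated series are complete, positive and cover the year range", {
  sc <- synthetic_scenario(seed = 5, n_countries = 4, noise_sd = 0.15)
  d <- generate_dataset(sc)
  yrs <- seq(sc$year_range[1], sc$year_range[2])
  for (sid in unique(d$stock_series$stock_id)) {
    s <- d$stock_series[d$stock_series$stock_id == sid, ]
    expect_identical(sort(s$year), yrs)
    expect_true(all(s$ssb > 0))
    expect_true(all(s$f >= 0))
    expect_true(all(s$recruitment >= 0))
  }
  r <- d$reference_points
  expect_true(all(r$ssb_lim > 0 & r$ssb_lim < r$b_msy))
  expect_true(all(r$f_msy > 0 & r$f_msy < r$f_lim))
})

test_that("best archetype stocks end below Fmsy and above Bmsy with no episode", {
  d <- generate_dataset(synthetic_scenario(seed = 1, n_countries = 3,
                                           archetype = "best"))
  for (sid in unique(d$stock_series$stock_id)) {
    s <- d$stock_series[d$stock_series$stock_id == sid, ]
    r <- d$reference_points[d$reference_points$stock_id == sid, ]
    n <- nrow(s)
    expect_lt(s$f[n] / r$f_msy, 1)
    expect_gt(s$ssb[n] / r$b_msy, 1)
    expect_equal(as.numeric(recovery_time(s, r$ssb_lim)), 0)
    # positive SSB trend
    expect_gt(as.numeric(relative_linear_trend(s$year, s$ssb)), 0)
  }
})

test_that("worst archetype stocks decline, are overfished and stay unrecovered", {
  d <- generate_dataset(synthetic_scenario(seed = 1, n_countries = 3,
                                           archetype = "worst"))
  for (sid in unique(d$stock_series$stock_id)) {
    s <- d$stock_series[d$stock_series$stock_id == sid, ]
    r <- d$reference_points[d$reference_points$stock_id == sid, ]
    n <- nrow(s)
    expect_gt(s$f[n] / r$f_msy, 1)
    expect_lt(s$ssb[n] / r$b_msy, 1)
    rec <- recovery_time(s, r$ssb_lim)
    expect_gt(as.numeric(rec), 0)
    expect_true(attr(rec, "censored"))
    expect_lt(as.numeric(relative_linear_trend(s$year, s$ssb)), 0)
  }
})

test_that("a noiseless planted line yields its closed-form relative trend", {
  sc <- synthetic_scenario(seed = 9, n_countries = 2, n_stocks = 2,
                           latent_resilience = c(C01 = 1, C02 = 1),
                           noise_sd = 0)
  d <- generate_dataset(sc)
  s <- d$stock_series[d$stock_series$stock_id == "S01", ]
  # u = 1: pure line with relative slope 1.2 / (span - 1)
  expect_equal(as.numeric(relative_linear_trend(s$year, s$ssb)),
               1.2 / (nrow(s) - 1), tolerance = 1e-12)
})

test_that("noiseless country fields are monotone in the latent score", {
  lat <- setNames(seq(0, 1, length.out = 6), sprintf("C%02d", 1:6))
  sc <- synthetic_scenario(seed = 2, n_countries = 6, n_stocks = 3,
                           latent_resilience = lat, noise_sd = 0)
  d <- generate_dataset(sc)
  rec <- d$country_records[match(names(lat), d$country_records$country), ]
  pos <- c("gear_count", "ices_areas_recent", "ices_areas_delta",
           "research_investment", "management_investment",
           "n_organizations", "swap_earnings", "compliance")
  for (f in pos) expect_true(all(diff(rec[[f]]) >= 0), label = f)
  expect_true(all(diff(rec$above_tac) <= 0))
  # planted dependencies decrease with the latent score too
  dep <- vapply(names(lat), function(cc) {
    sh <- catch_shares(d$catches, cc, "sp1")
    sum(sh$share^2)
  }, numeric(1))
  expect_true(all(diff(dep) <= 1e-12))
})

test_that("archetype records occupy the extremes of every field's admissible range", {
  best <- generate_dataset(synthetic_scenario(seed = 1, n_countries = 3,
                                              archetype = "best"))
  worst <- generate_dataset(synthetic_scenario(seed = 1, n_countries = 3,
                                               archetype = "worst"))
  b <- best$bounds
  for (f in c("gear_count", "n_organizations", "compliance", "swap_earnings",
              "research_investment", "ices_areas_delta")) {
    expect_equal(unique(best$country_records[[f]]),
                 b$upper[b$indicator_id == f], label = f)
    expect_equal(unique(worst$country_records[[f]]),
                 b$lower[b$indicator_id == f], label = f)
  }
  # negative-direction field: best sits at the admissible minimum
  expect_equal(unique(best$country_records$above_tac),
               b$lower[b$indicator_id == "above_tac"])
  expect_equal(unique(worst$country_records$above_tac),
               b$upper[b$indicator_id == "above_tac"])
})

test_that("planted catch tables hit the dependency targets exactly", {
  sc <- synthetic_scenario(seed = 4, n_countries = 5, n_stocks = 4,
                           noise_sd = 0)
  d <- generate_dataset(sc)
  u <- sc$latent_resilience
  for (cc in names(u)) {
    sh <- catch_shares(d$catches, cc, "sp1")
    expect_equal(sum(sh$share), 1, tolerance = 1e-12)
    herf_target <- 1 + (1 / sc$n_stocks - 1) * u[[cc]]
    expect_equal(sum(sh$share^2), herf_target, tolerance = 1e-10)
    dep_tot <- catch_dependency(d$catches, cc, sh$stock_id[1], "total")
    # total-catch dependency of the whole species
    sp_dep <- sum(vapply(sh$stock_id, function(st) {
      as.numeric(catch_dependency(d$catches, cc, st, "total"))
    }, numeric(1)))
    expect_equal(sp_dep, 0.95 + (0.05 - 0.95) * u[[cc]], tolerance = 1e-10)
  }
})
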