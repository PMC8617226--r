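# Synthetic study-system generator.
#
# Every raw field is a monotone transform of a planted latent resilience
# score in [0, 1]: u = 1 is the most favorable admissible value of every
# field, u = 0 the least. The deterministic u = 0 and u = 1 constructions
# double as the boundary archetypes AND as the normalization-bounds table
# (the realized indicator values at the two extremes), so archetype
# datasets score exactly 0 or 1 through the whole pipeline. All
# distributional choices here are artifact choices: the study's raw-data
# distributions are not described anywhere, so the generator aims only at
# the features the downstream statistics consume (trends, excursions,
# endpoints, monotone country fields), not at biological realism.

lerp <- function(lo, hi, u) lo + (hi - lo) * u

# field ranges: the admissible scale of each directly-measured raw field
.field_ranges <- list(
  area_2006 = c(5e4, 2e6), area_2100 = c(1e4, 1.5e6),
  t50 = c(4, 16), t_range = c(2, 14),
  gear_count = c(1, 12), ices_areas_recent = c(1, 15),
  ices_areas_delta = c(-3, 8),
  research_investment = log(c(1e5, 1e8)), management_investment = log(c(5e4, 5e7)),
  n_organizations = c(0, 30), swap_earnings = log(c(1e4, 5e7)),
  above_tac = c(0.5, 0), compliance = c(0, 1),
  stockdep_total = c(0.95, 0.05)
)
.log_fields <- c("research_investment", "management_investment", "swap_earnings")
.count_fields <- c("gear_count", "ices_areas_recent", "ices_areas_delta",
                   "n_organizations")

#' Define a synthetic study scenario
#'
#' A scenario fixes the sampling frame (stocks, countries, assessment
#' years), the planted latent resilience score of every country, the
#' noise level, and an optional boundary archetype. The latent score is
#' the generator's ground truth: every downstream raw field is a monotone
#' transform of it, so the pipeline's recovered index can be validated
#' against it.
#'
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the scenario including this seed.
#' @param n_countries Number of fishing countries.
#' @param n_stocks Number of assessed stocks of the focal species;
#'   defaults to `max(2, n_countries)` (a single-stock scenario leaves
#'   the within-species dependency indicator degenerate).
#' @param year_range Inclusive first/last assessment year; must span at
#'   least 10 years.
#' @param latent_resilience Named numeric vector in \[0, 1\], one entry
#'   per country; default is evenly spaced over \[0.05, 0.95\].
#' @param noise_sd Nonnegative noise scale, applied both as the sd of the
#'   perturbation of the latent score behind each country field and as
#'   the stationary sd of the log-scale AR(1) noise on the stock series.
#' @param archetype `"none"`, `"best"` or `"worst"`. Archetypes pin every
#'   country's latent score to 1 or 0 and generate noise-free, so every
#'   field sits at its most/least favorable admissible value.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, n_countries = 10L,
                               n_stocks = max(2L, n_countries),
                               year_range = c(1950L, 2010L),
                               latent_resilience = NULL,
                               noise_sd = 0.1,
                               archetype = c("none", "best", "worst")) {
  archetype <- archetype[1]
  if (!archetype %in% c("none", "best", "worst")) {
    stop("unknown archetype label: ", archetype, call. = FALSE)
  }
  if (!is.numeric(n_stocks) || n_stocks < 1) {
    stop("n_stocks must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_countries) || n_countries < 1) {
    stop("n_countries must be a positive integer", call. = FALSE)
  }
  if (length(year_range) != 2 || diff(year_range) < 9) {
    stop("year_range must span at least 10 years", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be finite and nonnegative", call. = FALSE)
  }
  countries <- sprintf("C%02d", seq_len(n_countries))
  if (is.null(latent_resilience)) {
    latent_resilience <- stats::setNames(
      if (n_countries == 1) 0.5 else seq(0.05, 0.95, length.out = n_countries),
      countries
    )
  }
  if (!setequal(names(latent_resilience), countries)) {
    stop("latent_resilience keys must exactly cover the generated countries",
         call. = FALSE)
  }
  if (archetype != "none") {
    latent_resilience[] <- if (archetype == "best") 1 else 0
    noise_sd <- 0
  }
  structure(
    list(seed = as.integer(seed), n_countries = as.integer(n_countries),
         n_stocks = as.integer(n_stocks),
         year_range = as.integer(year_range),
         latent_resilience = latent_resilience[countries],
         noise_sd = noise_sd, archetype = archetype,
         species = "sp1",
         countries = countries,
         stocks = sprintf("S%02d", seq_len(n_stocks))),
    class = "synthetic_scenario"
  )
}

# deterministic series core for one stock at latent u (no noise):
# SSB is a line of relative trend (2u-1)*r_max with a planted
# multiplicative dip (depth 0.2) whose length shrinks with u; F is a line
# through a final value 0.5*(1-u); R is a line like SSB. Reference points
# are fixed multiples of the SSB scale.
.stock_core <- function(u, years) {
  n <- length(years)
  tbar <- mean(years)
  half <- (n - 1) / 2
  r_max <- 0.6 / half               # keeps the line within [0.4, 1.6] x scale
  m <- 1000
  ssb <- m * (1 + (2 * u - 1) * r_max * (years - tbar))
  f_fin <- 0.5 * (1 - u)
  b_f <- (1 - 2 * u) * 0.45 / (n - 1)
  f <- f_fin + b_f * (years - years[n])
  rec <- 1e6 * (1 + (2 * u - 1) * r_max * (years - tbar))
  l_max <- min(20L, n - 10L)
  dip_len <- round(l_max * max(0, 1 - u / 0.75))
  dip <- rep(FALSE, n)
  if (dip_len > 0) {
    if (u < 0.25) {
      dip[(n - dip_len + 1):n] <- TRUE          # unrecovered, censored at end
    } else {
      dip[(n - 4 - dip_len):(n - 5)] <- TRUE    # completed, recovers 5y before end
    }
    ssb[dip] <- ssb[dip] * 0.2
  }
  list(
    ssb = ssb, f = f, recruitment = rec,
    refs = tibble::tibble(ssb_lim = 0.3 * m, f_lim = 0.375,
                          b_msy = 0.9 * m, f_msy = 0.25)
  )
}

.ar1 <- function(n, sd, phi = 0.5) {
  if (sd == 0) return(rep(0, n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# stock latent scores: each country has a primary stock (round-robin);
# a stock's latent is the mean latent of the countries it is primary for
.stock_latents <- function(scenario) {
  primary <- ((seq_len(scenario$n_countries) - 1) %% scenario$n_stocks) + 1
  vapply(seq_len(scenario$n_stocks), function(k) {
    who <- scenario$countries[primary == k]
    if (length(who) == 0) mean(scenario$latent_resilience)
    else mean(scenario$latent_resilience[who])
  }, numeric(1))
}

#' Generate synthetic stock-assessment series and reference points
#'
#' Produces one complete annual SSB/F/recruitment series per stock over
#' the scenario's year range, plus limit and MSY reference points and
#' species traits. Stocks tied to high-latent countries get a rising SSB
#' line, declining fishing mortality ending below Fmsy, and no
#' below-limit episode; low-latent stocks the reverse, including a
#' planted below-limit dip (unrecovered for the lowest scores). Noise is
#' multiplicative log-scale AR(1) (autocorrelation 0.5) on all three
#' series.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with tibbles `stock_series`, `reference_points`,
#'   `species_traits`.
#' @export
generate_stock_series <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  years <- seq(scenario$year_range[1], scenario$year_range[2])
  us <- .stock_latents(scenario)
  lat <- seq(36, 70, length.out = scenario$n_stocks)  # Iberia to Barents
  series <- purrr::map_dfr(seq_len(scenario$n_stocks), function(k) {
    core <- .stock_core(us[k], years)
    tibble::tibble(
      stock_id = scenario$stocks[k], species = scenario$species,
      year = years,
      ssb = core$ssb * exp(.ar1(length(years), scenario$noise_sd)),
      f = core$f * exp(.ar1(length(years), scenario$noise_sd)),
      recruitment = core$recruitment * exp(.ar1(length(years), scenario$noise_sd)),
      latitude = lat[k]
    )
  })
  refs <- purrr::map_dfr(seq_len(scenario$n_stocks), function(k) {
    dplyr::mutate(.stock_core(us[k], years)$refs,
                  stock_id = scenario$stocks[k], .before = 1)
  })
  u_sp <- if (scenario$archetype == "best") 1
          else if (scenario$archetype == "worst") 0
          else mean(scenario$latent_resilience)
  traits <- tibble::tibble(
    species = scenario$species,
    area_2006 = lerp(.field_ranges$area_2006[1], .field_ranges$area_2006[2], u_sp),
    area_2100 = lerp(.field_ranges$area_2100[1], .field_ranges$area_2100[2], u_sp),
    t50 = lerp(.field_ranges$t50[1], .field_ranges$t50[2], u_sp),
    t_range = lerp(.field_ranges$t_range[1], .field_ranges$t_range[2], u_sp)
  )
  list(stock_series = series, reference_points = refs, species_traits = traits)
}

# solve the primary-stock share p giving a target within-species catch
# concentration (Herfindahl) H with the remainder spread evenly
.share_from_herfindahl <- function(h, k) {
  if (k == 1) return(1)
  a <- 1 + 1 / (k - 1)
  b <- -2 / (k - 1)
  cc <- 1 / (k - 1) - h
  (-b + sqrt(pmax(b^2 - 4 * a * cc, 0))) / (2 * a)
}

#' Generate synthetic country records and the catch table
#'
#' Every directly-measured country field is a monotone noisy transform of
#' the country's latent resilience: positive-direction fields increase
#' with it, negative-direction fields (TAC overshoot, and through the
#' catch table both dependency indicators) decrease. Monetary fields are
#' log-scaled; count fields are integer-rounded after the transform.
#' Catches are constructed so that the pipeline's dependency indicators
#' hit planted values exactly: the focal species' share of the country's
#' total catch encodes the total-catch dependency, and the concentration
#' of the species catch across stocks (most on the country's primary
#' stock) encodes the within-species dependency.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with tibbles `country_records` and `catches`.
#' @export
generate_country_records <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 1L)
  years <- seq(scenario$year_range[1], scenario$year_range[2])
  k <- scenario$n_stocks
  noisy_u <- function(u) {
    pmin(pmax(u + stats::rnorm(length(u), 0, scenario$noise_sd), 0), 1)
  }
  lat <- scenario$latent_resilience
  fields <- c("gear_count", "ices_areas_recent", "ices_areas_delta",
              "research_investment", "management_investment",
              "n_organizations", "swap_earnings", "above_tac", "compliance")
  records <- tibble::tibble(country = scenario$countries,
                            species = scenario$species)
  for (f in fields) {
    rg <- .field_ranges[[f]]
    v <- lerp(rg[1], rg[2], noisy_u(lat))
    if (f %in% .log_fields) v <- exp(v)
    if (f %in% .count_fields) v <- round(v)
    records[[f]] <- v
  }

  total_per_year <- 1000
  dep_total <- lerp(.field_ranges$stockdep_total[1],
                    .field_ranges$stockdep_total[2], noisy_u(lat))
  herf <- lerp(1, 1 / k, noisy_u(lat))
  primary <- ((seq_len(scenario$n_countries) - 1) %% k) + 1
  catches <- purrr::map_dfr(seq_len(scenario$n_countries), function(i) {
    p <- .share_from_herfindahl(herf[i], k)
    shares <- rep((1 - p) / max(k - 1, 1), k)
    shares[primary[i]] <- p
    focal <- dep_total[i] * total_per_year
    dplyr::bind_rows(
      tidyr::expand_grid(stock_id = scenario$stocks, year = years) |>
        dplyr::mutate(country = scenario$countries[i],
                      species = scenario$species,
                      catch = focal * shares[match(.data$stock_id, scenario$stocks)]),
      tibble::tibble(country = scenario$countries[i], stock_id = "other",
                     species = "other", year = years,
                     catch = (1 - dep_total[i]) * total_per_year)
    )
  }) |>
    dplyr::select("country", "stock_id", "species", "year", "catch")
  list(country_records = records, catches = catches)
}

# realized indicator values of the deterministic u = 0 / u = 1
# constructions: the normalization-bounds table the generator emits
.synthetic_bounds <- function(scenario, config = resilience_config()) {
  years <- seq(scenario$year_range[1], scenario$year_range[2])
  historic <- config$historic_period %||% range(years)
  recent <- config$recent_period %||% c(max(years) - 30L, max(years))
  eco_at <- function(u) {
    core <- .stock_core(u, years)
    n <- length(years)
    c(
      ssb_trend_historic = relative_linear_trend(years, core$ssb, historic),
      ssb_trend_recent = relative_linear_trend(years, core$ssb, recent),
      f_trend = relative_linear_trend(years, core$f, historic),
      r_trend = relative_linear_trend(years, core$recruitment, historic),
      overmsy = as.numeric(overmsy_index(core$ssb[n], core$f[n], core$refs)),
      kobe_status = kobe_status(core$ssb[n], core$f[n], core$refs),
      recovery_time = as.numeric(recovery_time(
        list(years = years, ssb = core$ssb), core$refs$ssb_lim
      ))
    )
  }
  lo <- eco_at(0)
  hi <- eco_at(1)
  eco_ids <- names(lo)
  simple <- setdiff(names(.field_ranges), "stockdep_total")
  simple_b <- purrr::map_dfr(simple, function(f) {
    rg <- .field_ranges[[f]]
    if (f %in% .log_fields) rg <- exp(rg)
    tibble::tibble(indicator_id = f, lower = min(rg), upper = max(rg))
  })
  dplyr::bind_rows(
    tibble::tibble(indicator_id = eco_ids,
                   lower = unname(pmin(lo, hi)), upper = unname(pmax(lo, hi))),
    simple_b,
    tibble::tibble(indicator_id = "stockdep_total",
                   lower = .field_ranges$stockdep_total[2],
                   upper = .field_ranges$stockdep_total[1]),
    tibble::tibble(indicator_id = "stockdep_species",
                   lower = 1 / scenario$n_stocks, upper = 1)
  )
}

#' Generate a complete synthetic dataset
#'
#' Bundles [generate_stock_series()] and [generate_country_records()]
#' with the normalization-bounds table (the realized indicator values of
#' the deterministic boundary constructions, playing the role of a fixed
#' normalization-values table) and an echo of the scenario truth.
#' Regeneration from the same scenario is bit-identical.
#'
#' @param scenario A [synthetic_scenario()].
#' @param config A [resilience_config()]; only the trend periods affect
#'   the emitted bounds.
#' @return A list with `stock_series`, `reference_points`,
#'   `species_traits`, `catches`, `country_records`, `bounds`, `truth`.
#' @examples
#' d <- generate_dataset(synthetic_scenario(seed = 1, n_countries = 4))
#' dplyr::glimpse(d$country_records)
#' @export
generate_dataset <- function(scenario, config = resilience_config()) {
  eco <- generate_stock_series(scenario)
  soc <- generate_country_records(scenario)
  c(eco, soc,
    list(bounds = .synthetic_bounds(scenario, config), truth = scenario))
}
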