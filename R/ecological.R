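#' Relative linear trend of an assessment series
#'
#' Ordinary least-squares slope of `values` on `years`, restricted to
#' `period`, divided by the mean of the in-period values. The division
#' makes trends comparable across stocks of very different absolute
#' biomass, mortality or recruitment; the result is a dimensionless
#' per-year rate (0.01 = the series grows by about 1% of its period mean
#' per year).
#'
#' @param years Integer vector of assessment years (strictly increasing).
#' @param values Numeric vector, same length as `years`.
#' @param period Inclusive year pair `c(first, last)`; `NULL` uses all years.
#' @param log Fit the regression on `log(values)` (requires positive
#'   values); the slope is then divided by the mean log value.
#' @return A single number, or `NA` with attribute `reason` when fewer
#'   than 3 observations fall in the period (`"too_few_points"`) or the
#'   in-period mean is zero (`"zero_mean"`).
#' @examples
#' relative_linear_trend(2000:2003, c(1, 2, 3, 4))  # slope 1 / mean 2.5 = 0.4
#' @export
relative_linear_trend <- function(years, values, period = NULL, log = FALSE) {
  stopifnot(length(years) == length(values))
  if (is.null(period)) period <- range(years)
  keep <- years >= period[1] & years <= period[2] & is.finite(values)
  x <- years[keep]
  y <- values[keep]
  if (length(x) < 3) {
    return(structure(NA_real_, reason = "too_few_points"))
  }
  if (log) {
    if (any(y <= 0)) return(structure(NA_real_, reason = "nonpositive_for_log"))
    y <- base::log(y)
  }
  m <- mean(y)
  if (m == 0) {
    return(structure(NA_real_, reason = "zero_mean"))
  }
  # closed-form OLS slope; avoids an lm() fit per indicator row
  xc <- x - mean(x)
  slope <- sum(xc * (y - m)) / sum(xc^2)
  slope / m
}

#' Overexploitation index from MSY reference points
#'
#' Ratio of relative fishing pressure to relative biomass,
#' `(F/Fmsy) / (SSB/Bmsy)`, evaluated at the final assessment year.
#' Values above 1 signal overexploitation pressure: fishing mortality high
#' relative to its MSY level while biomass is low relative to its MSY
#' level. The indicator enters the hierarchy with negative direction, so
#' larger values reduce resilience. The orientation is configurable only
#' by editing the hierarchy direction, not here.
#'
#' @param ssb_final Final-year spawning stock biomass (tonnes), > 0.
#' @param f_final Final-year fishing mortality, >= 0.
#' @param ref A one-row reference-point record with `f_msy` and `b_msy`.
#' @return A single number; `NA` with `reason = "degenerate biomass"` when
#'   `ssb_final` is zero.
#' @export
overmsy_index <- function(ssb_final, f_final, ref) {
  stopifnot(ref$f_msy > 0, ref$b_msy > 0, f_final >= 0)
  if (!is.finite(ssb_final) || ssb_final <= 0) {
    return(structure(NA_real_, reason = "degenerate biomass"))
  }
  (f_final / ref$f_msy) / (ssb_final / ref$b_msy)
}

#' Kobe-quadrant stock status
#'
#' Ordinal status score from the position of the stock in the
#' fishing-mortality vs biomass plane relative to the limit reference
#' points, as in a Kobe plot: the green quadrant (F at or below Flim and
#' SSB at or above SSBlim) scores 1; overfishing alone scores 2/3; low
#' biomass alone scores 1/3; both violated scores 0. The 4-level scoring
#' of the quadrants is this package's choice of ordinal mapping.
#'
#' @param ssb_final Final-year spawning stock biomass (tonnes).
#' @param f_final Final-year fishing mortality.
#' @param ref A one-row reference-point record with `f_lim` and `ssb_lim`.
#' @return One of 0, 1/3, 2/3, 1.
#' @export
kobe_status <- function(ssb_final, f_final, ref) {
  stopifnot(ref$f_lim > 0, ref$ssb_lim > 0)
  f_ok <- f_final <= ref$f_lim
  b_ok <- ssb_final >= ref$ssb_lim
  if (f_ok && b_ok) 1 else if (!f_ok && b_ok) 2 / 3 else if (f_ok && !b_ok) 1 / 3 else 0
}

#' Recovery time from below-limit biomass excursions
#'
#' Scans the SSB series for maximal runs of consecutive years below
#' `ssb_lim`. A completed run lasts from the first below-limit year to the
#' first year back at or above the limit; a run still open at the end of
#' the series counts its observed years and is flagged censored. Returns
#' the maximum duration over all runs (the worst episode), 0 when the
#' stock never drops below the limit.
#'
#' @param series A one-stock tibble with columns `year` and `ssb`, or a
#'   list with `years`/`ssb` vectors.
#' @param ssb_lim Limit reference biomass (tonnes), > 0.
#' @return Integer years, with attributes `censored` (logical: is the
#'   maximal run open at the series end) and `episodes` (a tibble of all
#'   runs with `start`, `duration`, `censored`).
#' @examples
#' s <- tibble::tibble(year = 2000:2010, ssb = c(5, 5, 5, 1, 1, 1, 1, 5, 5, 5, 5))
#' recovery_time(s, ssb_lim = 3)  # below 2003-2006, back 2007 -> 4 years
#' @export
recovery_time <- function(series, ssb_lim) {
  stopifnot(ssb_lim > 0)
  if (is.data.frame(series)) {
    years <- series$year
    ssb <- series$ssb
  } else {
    years <- series$years
    ssb <- series$ssb
  }
  below <- ssb < ssb_lim
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ep <- tibble::tibble(start = integer(), duration = integer(), censored = logical())
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    first_below <- years[starts[i]]
    open <- ends[i] == length(years)
    dur <- if (open) {
      years[length(years)] - first_below + 1L
    } else {
      # first year back at/above the limit minus first year below it
      years[ends[i] + 1L] - first_below
    }
    ep <- dplyr::bind_rows(ep, tibble::tibble(
      start = as.integer(first_below), duration = as.integer(dur), censored = open
    ))
  }
  if (nrow(ep) == 0) {
    return(structure(0L, censored = FALSE, episodes = ep))
  }
  worst <- which.max(ep$duration)
  structure(ep$duration[worst], censored = ep$censored[worst], episodes = ep)
}

#' Compile the ecological indicator table
#'
#' Computes every stock-level ecological indicator from the assessment
#' series, reference points and species traits, and returns them in the
#' long indicator format used by the index engine. Stocks without
#' reference points lose their overexploitation and recovery rows (status
#' `"missing"`); stocks whose species lacks traits lose the area and
#' temperature rows. Trend indicators that cannot be estimated are kept
#' as missing rows with a reason, never imputed as zero (zero is a
#' meaningful trend).
#'
#' @param stocks Stock-series tibble: `stock_id`, `species`, `year`,
#'   `ssb`, `f`, `recruitment`, `latitude`.
#' @param refs Reference-point tibble: `stock_id`, `ssb_lim`, `f_lim`,
#'   `b_msy`, `f_msy`.
#' @param traits Species-trait tibble: `species`, `area_2006`,
#'   `area_2100`, `t50`, `t_range`.
#' @param config A [resilience_config()]; controls the trend periods and
#'   whether trends are fitted on log series.
#' @return A tibble with columns `entity`, `entity_level`, `species`,
#'   `indicator_id`, `factor_id`, `dimension`, `direction`, `value`,
#'   `status`.
#' @export
compile_ecological <- function(stocks, refs, traits, config = resilience_config()) {
  hier <- indicator_hierarchy()
  rows <- purrr::map_dfr(split(stocks, stocks$stock_id), function(s) {
    s <- dplyr::arrange(s, .data$year)
    sp <- s$species[1]
    historic <- config$historic_period %||% range(s$year)
    recent <- config$recent_period %||% c(max(s$year) - 30L, max(s$year))
    tr <- traits[traits$species == sp, ]
    rf <- refs[refs$stock_id == s$stock_id[1], ]
    last <- nrow(s)

    vals <- list(
      ssb_trend_historic = relative_linear_trend(s$year, s$ssb, historic, log = config$log_trends),
      ssb_trend_recent   = relative_linear_trend(s$year, s$ssb, recent, log = config$log_trends),
      f_trend            = relative_linear_trend(s$year, s$f, historic, log = config$log_trends),
      r_trend            = relative_linear_trend(s$year, s$recruitment, historic, log = config$log_trends)
    )
    vals$area_2006 <- if (nrow(tr) == 1) tr$area_2006 else NA_real_
    vals$area_2100 <- if (nrow(tr) == 1) tr$area_2100 else NA_real_
    vals$t50 <- if (nrow(tr) == 1) tr$t50 else NA_real_
    vals$t_range <- if (nrow(tr) == 1) tr$t_range else NA_real_
    if (nrow(rf) == 1) {
      vals$overmsy <- overmsy_index(s$ssb[last], s$f[last], rf)
      vals$kobe_status <- kobe_status(s$ssb[last], s$f[last], rf)
      vals$recovery_time <- as.numeric(recovery_time(s, rf$ssb_lim))
    } else {
      vals$overmsy <- structure(NA_real_, reason = "no reference points")
      vals$kobe_status <- structure(NA_real_, reason = "no reference points")
      vals$recovery_time <- structure(NA_real_, reason = "no reference points")
    }

    tibble::tibble(
      entity = s$stock_id[1],
      entity_level = "stock",
      species = sp,
      indicator_id = names(vals),
      value = purrr::map_dbl(vals, as.numeric),
      status = purrr::map_chr(vals, function(v) {
        if (is.na(v)) attr(v, "reason") %||% "missing" else "ok"
      })
    )
  })
  rows |>
    dplyr::inner_join(
      hier[hier$dimension == "ecological",
           c("indicator_id", "factor_id", "dimension", "direction")],
      by = "indicator_id"
    ) |>
    dplyr::select("entity", "entity_level", "species", "indicator_id",
                  "factor_id", "dimension", "direction", "value", "status") |>
    dplyr::arrange(.data$entity,
                   match(.data$indicator_id, hier$indicator_id))
}
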