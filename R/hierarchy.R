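#' The frozen indicator hierarchy
#'
#' Returns the indicator -> factor -> dimension hierarchy that defines the
#' resilience index, with the direction in which each indicator influences
#' resilience (`"+"` raises it, `"-"` lowers it) and the entity level at
#' which it is measured (`"stock"` for ecological indicators, `"country"`
#' for socioeconomic and institutional ones).
#'
#' The ecological dimension holds five factors: distribution area (current
#' and end-of-century potential area), abundance (relative linear trends of
#' spawning stock biomass, fishing mortality and recruitment), temperature
#' (median preferred temperature and preferred-temperature range),
#' overexploitation (an MSY-ratio index and the Kobe-quadrant status), and
#' recovery (years to recover from below-limit biomass excursions). The
#' socioeconomic dimension holds gear diversity, fleet mobility, catch
#' dependency and adaptive management; the institutional dimension holds
#' co-management, property rights, quotas and compliance strength.
#'
#' Row order is the canonical ordering used for deterministic tie-breaking
#' in [correlation_prune()].
#'
#' @return A tibble with columns `indicator_id`, `factor_id`, `factor_name`,
#'   `dimension`, `direction`, `entity_level`.
#' @examples
#' indicator_hierarchy()
#' @export
indicator_hierarchy <- function() {
  tibble::tribble(
    ~indicator_id,        ~factor_id, ~factor_name,          ~dimension,      ~direction, ~entity_level,
    "area_2006",          "E1",       "area",                "ecological",    "+",        "stock",
    "area_2100",          "E1",       "area",                "ecological",    "+",        "stock",
    "ssb_trend_historic", "E2",       "abundance",           "ecological",    "+",        "stock",
    "ssb_trend_recent",   "E2",       "abundance",           "ecological",    "+",        "stock",
    "f_trend",            "E2",       "abundance",           "ecological",    "-",        "stock",
    "r_trend",            "E2",       "abundance",           "ecological",    "+",        "stock",
    "t50",                "E3",       "temperature",         "ecological",    "+",        "stock",
    "t_range",            "E3",       "temperature",         "ecological",    "+",        "stock",
    "overmsy",            "E4",       "overexploitation",    "ecological",    "-",        "stock",
    "kobe_status",        "E4",       "overexploitation",    "ecological",    "+",        "stock",
    "recovery_time",      "E5",       "recovery",            "ecological",    "-",        "stock",
    "gear_count",         "S1",       "gear_diversity",      "socioeconomic", "+",        "country",
    "ices_areas_recent",  "S2",       "fleet_mobility",      "socioeconomic", "+",        "country",
    "ices_areas_delta",   "S2",       "fleet_mobility",      "socioeconomic", "+",        "country",
    "stockdep_species",   "S3",       "catch_dependency",    "socioeconomic", "-",        "country",
    "stockdep_total",     "S3",       "catch_dependency",    "socioeconomic", "-",        "country",
    "research_investment","S4",       "adaptive_management", "socioeconomic", "+",        "country",
    "management_investment","S4",     "adaptive_management", "socioeconomic", "+",        "country",
    "n_organizations",    "I1",       "co_management",       "institutional", "+",        "country",
    "swap_earnings",      "I2",       "property_rights",     "institutional", "+",        "country",
    "above_tac",          "I3",       "quotas",              "institutional", "-",        "country",
    "compliance",         "I4",       "strength",            "institutional", "+",        "country"
  )
}

#' Default analysis configuration
#'
#' Assembles the tunable knobs of the pipeline with their defaults:
#' the correlation-pruning threshold, the trend periods, the dependency
#' reference window, the stock-to-country ecological rollup mode, and
#' optional fixed normalization bounds.
#'
#' @param correlation_threshold Absolute Pearson correlation above which one
#'   of a pair of same-dimension indicators is dropped. Default 0.75.
#' @param historic_period Inclusive year pair for the historic trend window;
#'   `NULL` means the full extent of each series.
#' @param recent_period Inclusive year pair for the recent trend window;
#'   `NULL` means the last 31 years of each series (a three-decade window).
#' @param dependency_years Number of trailing years of the catch table over
#'   which catch-dependency shares are summed. Default 5.
#' @param rollup Stock-to-country ecological aggregation: `"catch_share"`
#'   (weights stocks by the country's catch shares) or `"mean"`.
#' @param bounds Optional tibble of fixed normalization bounds with columns
#'   `indicator_id`, `lower`, `upper`; `NULL` uses observed min/max.
#' @param log_trends Fit trend regressions on log-transformed series
#'   instead of raw values. Default `FALSE`.
#' @param require_all_dimensions If `TRUE` (default) the overall index is
#'   missing when any dimension is missing; if `FALSE` it is the mean of
#'   the available dimensions.
#' @return A list of class `fishres_config`.
#' @export
resilience_config <- function(correlation_threshold = 0.75,
                              historic_period = NULL,
                              recent_period = NULL,
                              dependency_years = 5,
                              rollup = c("catch_share", "mean"),
                              bounds = NULL,
                              log_trends = FALSE,
                              require_all_dimensions = TRUE) {
  stopifnot(
    is.numeric(correlation_threshold), length(correlation_threshold) == 1,
    correlation_threshold > 0, correlation_threshold <= 1,
    is.numeric(dependency_years), dependency_years >= 1
  )
  rollup <- match.arg(rollup)
  if (!is.null(bounds)) {
    stopifnot(all(c("indicator_id", "lower", "upper") %in% names(bounds)))
  }
  structure(
    list(
      correlation_threshold = correlation_threshold,
      historic_period = historic_period,
      recent_period = recent_period,
      dependency_years = dependency_years,
      rollup = rollup,
      bounds = bounds,
      log_trends = log_trends,
      require_all_dimensions = require_all_dimensions
    ),
    class = "fishres_config"
  )
}
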