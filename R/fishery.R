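#' Catch dependency of a country on a stock
#'
#' Proportion of a country's catch taken from one stock, summed over the
#' reference years. At `level = "species"` the denominator is the
#' country's total catch of that stock's species; at `level = "total"` it
#' is the country's total catch across all species. Dependency carries
#' negative direction in the hierarchy: the more a country's catch is
#' concentrated on a single stock, the less room it has to respond when
#' that stock shifts or declines.
#'
#' @param catches Catch tibble: `country`, `stock_id`, `species`, `year`,
#'   `catch` (tonnes).
#' @param country,stock_id The country and stock of interest.
#' @param level `"species"` or `"total"` denominator.
#' @param years Optional integer vector of reference years; `NULL` uses
#'   the last `ref_window` years present in the table.
#' @param ref_window Number of trailing years when `years` is `NULL`.
#' @return A number in \[0, 1\]; `NA` with `reason = "zero denominator"`
#'   when the country has no catch in the window.
#' @export
catch_dependency <- function(catches, country, stock_id,
                             level = c("species", "total"),
                             years = NULL, ref_window = 5) {
  level <- match.arg(level)
  if (is.null(years)) {
    yr <- sort(unique(catches$year))
    years <- utils::tail(yr, ref_window)
  }
  cc <- catches[catches$country == country & catches$year %in% years, ]
  sp <- cc$species[match(stock_id, cc$stock_id)]
  num <- sum(cc$catch[cc$stock_id == stock_id])
  den <- if (level == "species") {
    sum(cc$catch[cc$species %in% sp])
  } else {
    sum(cc$catch)
  }
  if (!isTRUE(den > 0)) {
    return(structure(NA_real_, reason = "zero denominator"))
  }
  num / den
}

#' Catch-share weights of a country over the stocks of a species
#'
#' Nonnegative weights proportional to the country's catch of each stock
#' of the species over the reference years, summing to 1. Used to roll
#' stock-level ecological scores up to the countries that fish them.
#'
#' @inheritParams catch_dependency
#' @param species Species identifier.
#' @return A tibble with columns `stock_id`, `share`; zero rows when the
#'   country has no catch of the species in the window.
#' @export
catch_shares <- function(catches, country, species, years = NULL, ref_window = 5) {
  if (is.null(years)) {
    yr <- sort(unique(catches$year))
    years <- utils::tail(yr, ref_window)
  }
  cc <- catches[catches$country == country & catches$species == species &
                  catches$year %in% years, ]
  tot <- sum(cc$catch)
  if (!isTRUE(tot > 0)) {
    return(tibble::tibble(stock_id = character(), share = numeric()))
  }
  cc |>
    dplyr::summarise(share = sum(.data$catch) / tot, .by = "stock_id") |>
    dplyr::arrange(.data$stock_id)
}

#' Compile the socioeconomic and institutional indicator table
#'
#' Turns per country-species records and the catch table into long-format
#' indicator rows. Most socioeconomic and institutional indicators are
#' direct measurements (gear counts, investments, organization counts,
#' quota-swap earnings, TAC overshoot, compliance) copied through with
#' their hierarchy direction; the catch-dependency rows are computed from
#' the catch table. The species-level dependency of a country-species
#' entity is the catch-share-weighted mean of its per-stock dependencies
#' (the Herfindahl concentration of the country's within-species catch);
#' the total-level dependency is the species' share of the country's
#' total catch.
#'
#' @param records Country-record tibble: `country`, `species`,
#'   `gear_count`, `ices_areas_recent`, `ices_areas_delta`,
#'   `research_investment`, `management_investment`, `n_organizations`,
#'   `swap_earnings`, `above_tac`, `compliance`.
#' @param catches Catch tibble as in [catch_dependency()].
#' @param config A [resilience_config()]; `dependency_years` sets the
#'   reference window.
#' @return A long indicator tibble with the same columns as
#'   [compile_ecological()].
#' @export
compile_fishery <- function(records, catches, config = resilience_config()) {
  hier <- indicator_hierarchy()
  pass_through <- c("gear_count", "ices_areas_recent", "ices_areas_delta",
                    "research_investment", "management_investment",
                    "n_organizations", "swap_earnings", "above_tac", "compliance")
  rows <- purrr::pmap_dfr(
    records[, c("country", "species")],
    function(country, species) {
      rec <- records[records$country == country & records$species == species, ]
      vals <- as.list(rec[1, pass_through])
      shares <- catch_shares(catches, country, species,
                             ref_window = config$dependency_years)
      if (nrow(shares) > 0) {
        dep_sp <- purrr::map_dbl(shares$stock_id, function(st) {
          as.numeric(catch_dependency(catches, country, st, "species",
                                      ref_window = config$dependency_years))
        })
        vals$stockdep_species <- sum(shares$share * dep_sp)
        vals$stockdep_total <- sum(purrr::map_dbl(shares$stock_id, function(st) {
          as.numeric(catch_dependency(catches, country, st, "total",
                                      ref_window = config$dependency_years))
        }))
      } else {
        vals$stockdep_species <- structure(NA_real_, reason = "zero denominator")
        vals$stockdep_total <- structure(NA_real_, reason = "zero denominator")
      }
      tibble::tibble(
        entity = paste(country, species, sep = ":"),
        entity_level = "country",
        species = species,
        indicator_id = names(vals),
        value = purrr::map_dbl(vals, as.numeric),
        status = purrr::map_chr(vals, function(v) {
          if (is.na(v)) attr(v, "reason") %||% "missing" else "ok"
        })
      )
    }
  )
  rows |>
    dplyr::inner_join(
      hier[hier$entity_level == "country",
           c("indicator_id", "factor_id", "dimension", "direction")],
      by = "indicator_id"
    ) |>
    dplyr::select("entity", "entity_level", "species", "indicator_id",
                  "factor_id", "dimension", "direction", "value", "status") |>
    dplyr::arrange(.data$entity,
                   match(.data$indicator_id, hier$indicator_id))
}
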