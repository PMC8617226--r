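# CSV schemas, validation and the pipeline driver. All tabular I/O is
# UTF-8 CSV with "." decimal; missing values are empty cells, never
# sentinel numbers.

.schemas <- list(
  stock_series = c("stock_id", "species", "year", "ssb", "f",
                   "recruitment", "latitude"),
  reference_points = c("stock_id", "ssb_lim", "f_lim", "b_msy", "f_msy"),
  species_traits = c("species", "area_2006", "area_2100", "t50", "t_range"),
  catches = c("country", "stock_id", "species", "year", "catch"),
  country_records = c("country", "species", "gear_count",
                      "ices_areas_recent", "ices_areas_delta",
                      "research_investment", "management_investment",
                      "n_organizations", "swap_earnings", "above_tac",
                      "compliance")
)
.id_cols <- c("stock_id", "species", "country")

.read_one <- function(path, table) {
  required <- .schemas[[table]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required header(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warning(sprintf("%s: unknown column(s) ignored: %s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(required, .id_cols)
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- suppressWarnings(is.na(as.numeric(v)) & !is.na(v) & v != "")
      if (any(bad)) {
        stop(sprintf("%s: non-numeric value in numeric column '%s' at row %d",
                     path, col, which(bad)[1]), call. = FALSE)
      }
      df[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  tibble::as_tibble(df[, required])
}

#' Read and validate the five input tables
#'
#' Loads the stock-series, reference-point, species-trait, catch and
#' country-record CSVs, checks headers and numeric columns with located
#' error messages, and enforces the structural invariants: stock series
#' must have strictly increasing gap-free years with at least 10
#' observations, catch rows must be unique per (country, stock, year),
#' and compliance must lie in \[0, 1\].
#'
#' @param paths Named list or vector with elements `stock_series`,
#'   `reference_points`, `species_traits`, `catches`, `country_records`
#'   (file paths), optionally `bounds` (a normalization-bounds CSV with
#'   columns `indicator_id`, `lower`, `upper`).
#' @return A validated dataset list in the shape [compute_resilience()]
#'   expects.
#' @export
read_tables <- function(paths) {
  needed <- names(.schemas)
  if (!all(needed %in% names(paths))) {
    stop("paths must name: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  ds <- lapply(stats::setNames(needed, needed), function(tb) {
    .read_one(paths[[tb]], tb)
  })
  # per-stock series invariants
  for (sid in unique(ds$stock_series$stock_id)) {
    yrs <- sort(ds$stock_series$year[ds$stock_series$stock_id == sid])
    if (length(yrs) < 10) {
      stop(sprintf("stock %s: fewer than 10 annual observations", sid),
           call. = FALSE)
    }
    if (any(diff(yrs) != 1)) {
      stop(sprintf("stock %s: years must be strictly increasing with no gaps (gap after %d)",
                   sid, yrs[which(diff(yrs) != 1)[1]]), call. = FALSE)
    }
  }
  dup <- duplicated(ds$catches[, c("country", "stock_id", "year")])
  if (any(dup)) {
    stop("catches: duplicate (country, stock_id, year) at row ",
         which(dup)[1], call. = FALSE)
  }
  if (any(ds$country_records$compliance < 0 | ds$country_records$compliance > 1,
          na.rm = TRUE)) {
    stop("country_records: compliance must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(paths$bounds)) {
    b <- readr::read_csv(paths$bounds, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("indicator_id", "lower", "upper") %in% names(b)))
    ds$bounds <- tibble::as_tibble(b)
  }
  ds
}

#' Write a dataset to a directory of CSVs
#'
#' Writes the five input tables (plus the bounds table and, for
#' synthetic datasets, the scenario truth as JSON) in the schemas
#' [read_tables()] reads back.
#'
#' @param dataset A dataset list (e.g. from [generate_dataset()]).
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in names(.schemas)) {
    readr::write_csv(dataset[[tb]], file.path(dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  if (!is.null(dataset$bounds)) {
    readr::write_csv(dataset$bounds, file.path(dir, "bounds.csv"),
                     progress = FALSE)
  }
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    jsonlite::write_json(
      list(seed = truth$seed, n_countries = truth$n_countries,
           n_stocks = truth$n_stocks, year_range = truth$year_range,
           latent_resilience = as.list(truth$latent_resilience),
           noise_sd = truth$noise_sd, archetype = truth$archetype),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Run the whole pipeline
#'
#' Drives every stage end to end: optionally generates a synthetic
#' dataset (or reads one from disk), computes the resilience scores,
#' runs the factor-importance and latitude analyses, and writes per-tier
#' score CSVs, the indicator table, the drop log and a JSON run manifest
#' (config, seed, input summary) sufficient to reproduce the outputs.
#'
#' @param out_dir Output directory.
#' @param scenario Optional [synthetic_scenario()]; generated data are
#'   used when supplied.
#' @param paths Optional input paths for [read_tables()] (ignored when
#'   `scenario` is given).
#' @param config A [resilience_config()].
#' @param seed Seed for the attribution stage.
#' @return Invisibly, a list with `result` (`resilience_scores`),
#'   `importance`, `latitude`, `manifest`.
#' @export
run_pipeline <- function(out_dir, scenario = NULL, paths = NULL,
                         config = resilience_config(), seed = 1) {
  stopifnot(!is.null(scenario) || !is.null(paths))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- if (!is.null(scenario)) {
    generate_dataset(scenario, config)
  } else {
    read_tables(paths)
  }
  res <- compute_resilience(dataset, config)

  scores <- res$scores
  readr::write_csv(scores, file.path(out_dir, "scores.csv"), progress = FALSE)
  readr::write_csv(res$indicators, file.path(out_dir, "indicators.csv"),
                   progress = FALSE)
  readr::write_csv(res$pruned, file.path(out_dir, "drop_log.csv"),
                   progress = FALSE)
  readr::write_csv(res$bounds, file.path(out_dir, "bounds_used.csv"),
                   progress = FALSE)

  fac <- scores[scores$level == "factor" & scores$entity_level == "country", ]
  ov <- scores[scores$level == "overall", ]
  wide <- tidyr::pivot_wider(fac[, c("entity", "node_id", "score")],
                             names_from = "node_id", values_from = "score")
  imp <- NULL
  if (nrow(wide) >= 10) {
    idx <- ov$score[match(wide$entity, ov$entity)]
    imp <- factor_importance(wide[, -1], idx, seed = seed)
    readr::write_csv(imp$importance, file.path(out_dir, "importance.csv"),
                     progress = FALSE)
  }
  latfx <- NULL
  eco <- scores[scores$level == "dimension" & scores$entity_level == "stock" &
                  scores$node_id == "ecological", ]
  stock_lat <- dataset$stock_series |>
    dplyr::distinct(.data$stock_id, .data$latitude)
  lats <- stock_lat$latitude[match(eco$entity, stock_lat$stock_id)]
  if (nrow(eco) >= 10 && length(unique(lats)) >= 2) {
    latfx <- latitude_effect(eco$score, lats)
    readr::write_csv(latfx$curve, file.path(out_dir, "latitude_curve.csv"),
                     progress = FALSE)
  }

  manifest <- list(
    config = unclass(config)[c("correlation_threshold", "dependency_years",
                               "rollup", "log_trends",
                               "require_all_dimensions")],
    seed = seed,
    scenario = if (!is.null(scenario)) {
      list(seed = scenario$seed, n_countries = scenario$n_countries,
           n_stocks = scenario$n_stocks, noise_sd = scenario$noise_sd,
           archetype = scenario$archetype)
    },
    inputs = if (!is.null(paths)) lapply(paths, normalizePath),
    n_entities = list(stocks = length(unique(dataset$stock_series$stock_id)),
                      countries = nrow(dataset$country_records)),
    dropped = res$pruned$indicator_id
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(result = res, importance = imp, latitude = latfx,
                 manifest = manifest))
}
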