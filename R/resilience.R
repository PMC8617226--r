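#' Compute the social-ecological resilience index
#'
#' End-to-end index construction: compiles the ecological (per stock) and
#' socioeconomic/institutional (per country-species) indicator tables,
#' prunes redundant indicators within each dimension by the correlation
#' threshold, min-max normalizes with direction reversal, aggregates
#' stepwise into factor, dimension and overall scores, and rolls
#' stock-level ecological scores up to countries by catch share.
#'
#' Normalization bounds come from, in order of precedence:
#' `config$bounds`, a `bounds` element of `dataset` (as emitted by
#' [generate_dataset()], mirroring a fixed normalization-values table),
#' or the observed min/max across entities of the same level and species.
#'
#' @param dataset A list with elements `stock_series`,
#'   `reference_points`, `species_traits`, `catches`, `country_records`
#'   (tibbles in the schemas of [read_tables()]) and optionally `bounds`.
#' @param config A [resilience_config()].
#' @return An object of class `resilience_scores`: a list with
#'   \describe{
#'     \item{scores}{node tibble from [aggregate_scores()] for all
#'       entities, including the country-level ecological rollup and
#'       overall index}
#'     \item{indicators}{the long indicator table with raw values,
#'       normalized scores and a `retained` flag}
#'     \item{pruned}{drop log per dimension}
#'     \item{bounds}{normalization bounds actually used per indicator}
#'     \item{config}{the configuration}
#'   }
#' @export
compute_resilience <- function(dataset, config = resilience_config()) {
  hier <- indicator_hierarchy()
  eco <- compile_ecological(dataset$stock_series, dataset$reference_points,
                            dataset$species_traits, config)
  soc <- compile_fishery(dataset$country_records, dataset$catches, config)
  ind <- dplyr::bind_rows(eco, soc)

  # --- prune within each dimension on raw values -------------------------
  drop_log <- tibble::tibble(dimension = character(), indicator_id = character(),
                             partner = character(), correlation = numeric())
  retained <- character()
  for (dm in unique(hier$dimension)) {
    sub <- ind[ind$dimension == dm, ]
    wide <- tidyr::pivot_wider(sub[, c("entity", "indicator_id", "value")],
                               names_from = "indicator_id", values_from = "value")
    cols <- intersect(hier$indicator_id[hier$dimension == dm], names(wide))
    mat <- as.matrix(wide[, cols, drop = FALSE])
    if (nrow(mat) >= 3 && length(cols) >= 2) {
      pr <- correlation_prune(mat, config$correlation_threshold)
      retained <- c(retained, pr$retained)
      if (nrow(pr$dropped) > 0) {
        drop_log <- dplyr::bind_rows(drop_log,
                                     dplyr::mutate(pr$dropped, dimension = dm,
                                                   .before = 1))
      }
    } else {
      retained <- c(retained, cols)  # too few entities to estimate correlations
    }
  }
  ind$retained <- ind$indicator_id %in% retained

  # --- normalize ---------------------------------------------------------
  fixed <- config$bounds %||% dataset$bounds
  kept <- ind[ind$retained, ]
  norm_groups <- split(
    kept,
    interaction(kept$indicator_id, kept$entity_level, kept$species, drop = TRUE)
  )
  bounds_used <- tibble::tibble(indicator_id = character(), species = character(),
                                lower = numeric(), upper = numeric(),
                                source = character())
  scored_list <- lapply(norm_groups, function(g) {
    id <- g$indicator_id[1]
    b <- NULL
    src <- "observed"
    if (!is.null(fixed) && id %in% fixed$indicator_id) {
      row <- fixed[fixed$indicator_id == id, ][1, ]
      b <- c(row$lower, row$upper)
      src <- "fixed"
    }
    g$score <- normalize_indicator(g$value, g$direction[1], bounds = b)
    fin <- is.finite(g$value)
    attr(g, "bounds_row") <- tibble::tibble(
      indicator_id = id, species = g$species[1],
      lower = if (!is.null(b)) b[1] else if (any(fin)) min(g$value[fin]) else NA_real_,
      upper = if (!is.null(b)) b[2] else if (any(fin)) max(g$value[fin]) else NA_real_,
      source = src
    )
    g
  })
  bounds_used <- purrr::map_dfr(scored_list, attr, "bounds_row")
  scored <- dplyr::bind_rows(scored_list)

  # --- aggregate ---------------------------------------------------------
  stock_nodes <- aggregate_scores(
    scored[scored$entity_level == "stock", ],
    hierarchy = hier, require_all_dimensions = FALSE
  ) |>
    dplyr::filter(.data$level != "overall")

  country_scored <- scored[scored$entity_level == "country", ]
  country_nodes <- aggregate_scores(country_scored, hierarchy = hier,
                                    require_all_dimensions = FALSE) |>
    dplyr::filter(.data$level != "overall")

  stock_eco <- stock_nodes |>
    dplyr::filter(.data$level == "dimension", .data$node_id == "ecological") |>
    dplyr::select("entity", "score")

  rollup <- country_scored |>
    dplyr::distinct(.data$entity, .data$species) |>
    dplyr::mutate(country = sub(":[^:]*$", "", .data$entity)) |>
    purrr::pmap_dfr(function(entity, species, country) {
      shares <- catch_shares(dataset$catches, country, species,
                             ref_window = config$dependency_years)
      tibble::tibble(
        entity = entity, entity_level = "country", level = "dimension",
        node_id = "ecological", dimension = "ecological",
        score = country_ecological_rollup(stock_eco, shares,
                                          mode = config$rollup),
        n_children = nrow(shares), completeness = NA_real_
      )
    })

  country_dims <- dplyr::bind_rows(
    country_nodes[country_nodes$level == "dimension", ], rollup
  )
  overall <- country_dims |>
    dplyr::summarise(
      level = "overall", node_id = "overall", dimension = NA_character_,
      score = if (config$require_all_dimensions && anyNA(.data$score)) NA_real_
              else if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
      n_children = dplyr::n(),
      completeness = mean(!is.na(.data$score)),
      .by = c("entity", "entity_level")
    )

  scores <- dplyr::bind_rows(
    stock_nodes,
    country_nodes[country_nodes$level != "dimension", ],
    country_dims,
    overall
  )
  names(scores$score) <- NULL

  structure(
    list(scores = scores, indicators = scored, pruned = drop_log,
         bounds = bounds_used, config = config),
    class = "resilience_scores"
  )
}

#' @export
print.resilience_scores <- function(x, ...) {
  ov <- x$scores[x$scores$level == "overall", ]
  cat("<resilience_scores>\n")
  cat("  stocks:   ", sum(x$scores$level == "dimension" &
                            x$scores$entity_level == "stock"), "\n")
  cat("  countries:", nrow(ov), "\n")
  cat("  pruned indicators:", nrow(x$pruned), "\n")
  if (nrow(ov) > 0) {
    cat("  overall index: ",
        sprintf("median %.3f, range [%.3f, %.3f]",
                stats::median(ov$score, na.rm = TRUE),
                min(ov$score, na.rm = TRUE), max(ov$score, na.rm = TRUE)), "\n")
  }
  invisible(x)
}

#' Tidy a resilience result
#'
#' @param x A `resilience_scores` object.
#' @param level Optional filter: one of `"indicator"`, `"factor"`,
#'   `"dimension"`, `"overall"`.
#' @param ... Unused.
#' @return The node score tibble (one row per entity x node).
#' @method tidy resilience_scores
#' @export
tidy.resilience_scores <- function(x, level = NULL, ...) {
  out <- x$scores
  if (!is.null(level)) out <- out[out$level %in% level, ]
  out
}

#' One-row summary of a resilience result
#'
#' @param x A `resilience_scores` object.
#' @param ... Unused.
#' @return A one-row tibble: entity counts, number of pruned indicators,
#'   and the median overall, ecological, socioeconomic and institutional
#'   scores across country entities.
#' @method glance resilience_scores
#' @export
glance.resilience_scores <- function(x, ...) {
  ov <- x$scores[x$scores$level == "overall", ]
  dm <- x$scores[x$scores$level == "dimension" &
                   x$scores$entity_level == "country", ]
  med <- function(node) stats::median(dm$score[dm$node_id == node], na.rm = TRUE)
  tibble::tibble(
    n_stocks = length(unique(x$scores$entity[x$scores$entity_level == "stock"])),
    n_countries = nrow(ov),
    n_pruned = nrow(x$pruned),
    median_overall = stats::median(ov$score, na.rm = TRUE),
    median_ecological = med("ecological"),
    median_socioeconomic = med("socioeconomic"),
    median_institutional = med("institutional")
  )
}
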