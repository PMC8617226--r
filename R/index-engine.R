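#' Min-max normalize an indicator across entities
#'
#' Rescales raw indicator values to \[0, 1\] with
#' `(x - min) / (max - min)`, reversed (`1 - ...`) for indicators that
#' negatively affect resilience, so that after normalization higher is
#' always better. Bounds default to the observed min/max across entities;
#' explicit bounds reproduce a fixed normalization scale, in which case
#' values outside the bounds are clipped to \[0, 1\]. Missing values stay
#' missing.
#'
#' @param values Numeric vector of raw values, one per entity.
#' @param direction `"+"` or `"-"`.
#' @param bounds Optional `c(lower, upper)` pair overriding observed
#'   min/max.
#' @return Numeric vector of scores in \[0, 1\] (NA preserved). When all
#'   finite values are identical and no bounds are given the indicator is
#'   degenerate: every score is 0.5 and a warning is raised.
#' @examples
#' normalize_indicator(c(1, 3, 5), "+")            # 0, 0.5, 1
#' normalize_indicator(c(1, 3, 5), "-")            # 1, 0.5, 0
#' normalize_indicator(3, "+", bounds = c(1, 5))   # 0.5
#' @export
normalize_indicator <- function(values, direction = c("+", "-"), bounds = NULL) {
  direction <- match.arg(direction)
  finite <- is.finite(values)
  if (is.null(bounds)) {
    if (sum(finite) < 2 || diff(range(values[finite])) == 0) {
      warning("degenerate indicator: all values identical, scoring 0.5",
              call. = FALSE)
      out <- ifelse(finite, 0.5, NA_real_)
      return(out)
    }
    lo <- min(values[finite])
    hi <- max(values[finite])
    clip <- FALSE
  } else {
    stopifnot(length(bounds) == 2, bounds[2] >= bounds[1])
    lo <- bounds[1]
    hi <- bounds[2]
    clip <- TRUE
    if (hi == lo) {
      warning("degenerate bounds: scoring 0.5", call. = FALSE)
      return(ifelse(finite, 0.5, NA_real_))
    }
  }
  score <- (values - lo) / (hi - lo)
  if (clip) score <- pmin(pmax(score, 0), 1)
  if (direction == "-") score <- 1 - score
  ifelse(finite, score, NA_real_)
}

#' Drop redundant indicators within a dimension
#'
#' Computes pairwise-complete Pearson correlations between the raw
#' indicator columns of one dimension and greedily drops indicators until
#' no retained pair is correlated above the threshold, to avoid double
#' counting in the aggregation. At each step the candidate set is the
#' indicators involved in at least one above-threshold pair; the one with
#' the highest mean absolute correlation to the other retained indicators
#' is dropped, ties broken by dropping the later column (canonical
#' hierarchy order). Zero-variance columns cannot enter a correlation and
#' are retained with a warning.
#'
#' @param mat Numeric matrix or data frame, entities x indicators, with
#'   indicator ids as column names, in canonical order.
#' @param threshold Absolute correlation above which a pair is redundant;
#'   in (0, 1]. Default 0.75.
#' @return A list with `retained` (character vector of kept indicator
#'   ids, original order) and `dropped` (tibble `indicator_id`,
#'   `partner`, `correlation` in drop order).
#' @export
correlation_prune <- function(mat, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1)
  mat <- as.matrix(mat)
  ids <- colnames(mat)
  stopifnot(!is.null(ids))
  variances <- apply(mat, 2, stats::var, na.rm = TRUE)
  constant <- !is.na(variances) & variances == 0
  if (any(constant)) {
    warning("zero-variance indicator(s) excluded from correlation: ",
            paste(ids[constant], collapse = ", "), call. = FALSE)
  }
  active <- ids[!constant]
  drop_log <- tibble::tibble(indicator_id = character(), partner = character(),
                             correlation = numeric())
  if (length(active) >= 2) {
    repeat {
      cm <- suppressWarnings(
        stats::cor(mat[, active, drop = FALSE], use = "pairwise.complete.obs")
      )
      diag(cm) <- 0
      cm[is.na(cm)] <- 0
      if (max(abs(cm)) <= threshold) break
      viol <- which(abs(cm) > threshold, arr.ind = TRUE)
      candidates <- unique(active[viol[, 1]])
      mean_abs <- vapply(candidates, function(id) {
        mean(abs(cm[id, setdiff(active, id)]))
      }, numeric(1))
      # ties broken toward the later canonical column
      best <- max(mean_abs)
      tied <- candidates[mean_abs >= best - 1e-12]
      drop_id <- tied[which.max(match(tied, ids))]
      partners <- active[abs(cm[drop_id, ]) > threshold]
      partner <- partners[which.max(abs(cm[drop_id, partners]))]
      drop_log <- dplyr::bind_rows(drop_log, tibble::tibble(
        indicator_id = drop_id, partner = partner,
        correlation = cm[drop_id, partner]
      ))
      active <- setdiff(active, drop_id)
      if (length(active) < 2) break
    }
  }
  retained <- ids[ids %in% c(active, ids[constant])]
  list(retained = retained, dropped = drop_log)
}

#' Aggregate normalized indicators into factor, dimension and overall scores
#'
#' Stepwise unweighted (or weighted) averaging: indicator scores are
#' averaged into factor scores, factors into dimension scores, and
#' dimensions into the overall index. At every tier the mean is taken
#' over the non-missing children; a node whose children are all missing
#' is missing. No imputation occurs anywhere; a completeness fraction is
#' recorded per node instead.
#'
#' @param scored Long tibble with columns `entity`, `entity_level`,
#'   `indicator_id`, `factor_id`, `dimension`, `score` (normalized,
#'   missing allowed). Every indicator must appear in the hierarchy.
#' @param hierarchy The hierarchy tibble; defaults to
#'   [indicator_hierarchy()].
#' @param weights Optional named list with elements `indicator`, `factor`,
#'   `dimension`, each a named numeric vector of nonnegative weights
#'   (renormalized over the non-missing children of each node); `NULL`
#'   means equal weights everywhere.
#' @param require_all_dimensions If `TRUE`, the overall index is missing
#'   when any dimension is missing.
#' @return A tibble of nodes: `entity`, `entity_level`, `level`
#'   (`"indicator"`, `"factor"`, `"dimension"`, `"overall"`), `node_id`,
#'   `dimension`, `score`, `n_children`, `completeness`.
#' @export
aggregate_scores <- function(scored, hierarchy = indicator_hierarchy(),
                             weights = NULL, require_all_dimensions = TRUE) {
  unknown <- setdiff(unique(scored$indicator_id), hierarchy$indicator_id)
  if (length(unknown) > 0) {
    stop("indicator(s) not in hierarchy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  wmean <- function(x, ids, w) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    if (is.null(w)) return(mean(x[ok]))
    wi <- w[ids]
    wi[is.na(wi)] <- 1
    wi <- wi[ok]
    if (sum(wi) == 0) return(mean(x[ok]))
    sum(x[ok] * wi) / sum(wi)
  }

  ind <- scored |>
    dplyr::transmute(.data$entity, .data$entity_level, level = "indicator",
                     node_id = .data$indicator_id, .data$dimension,
                     score = .data$score, n_children = 1L,
                     completeness = as.numeric(!is.na(.data$score)))

  fac <- scored |>
    dplyr::summarise(
      level = "factor",
      score = wmean(.data$score, .data$indicator_id, weights$indicator),
      n_children = dplyr::n(),
      completeness = mean(!is.na(.data$score)),
      .by = c("entity", "entity_level", "dimension", "factor_id")
    ) |>
    dplyr::rename(node_id = "factor_id")

  dim <- fac |>
    dplyr::summarise(
      level = "dimension",
      score = wmean(.data$score, .data$node_id, weights$factor),
      n_children = dplyr::n(),
      completeness = mean(!is.na(.data$score)),
      .by = c("entity", "entity_level", "dimension")
    ) |>
    dplyr::mutate(node_id = .data$dimension)

  overall <- dim |>
    dplyr::summarise(
      level = "overall",
      score = if (require_all_dimensions && anyNA(.data$score)) NA_real_
              else wmean(.data$score, .data$node_id, weights$dimension),
      n_children = dplyr::n(),
      completeness = mean(!is.na(.data$score)),
      .by = c("entity", "entity_level")
    ) |>
    dplyr::mutate(node_id = "overall", dimension = NA_character_)

  dplyr::bind_rows(ind, fac, dim, overall) |>
    dplyr::select("entity", "entity_level", "level", "node_id", "dimension",
                  "score", "n_children", "completeness")
}

#' Roll stock-level ecological scores up to a country
#'
#' Catch-share-weighted (or simple) mean of the ecological dimension
#' scores of the stocks a country fishes. The study's stock-level
#' ecological assessment and country-level social assessment meet here:
#' a country dependent on less resilient stocks inherits their low
#' ecological score.
#'
#' @param stock_scores Tibble with columns `entity` (stock id) and
#'   `score` (ecological dimension score per stock).
#' @param shares Tibble from [catch_shares()]: `stock_id`, `share`.
#' @param mode `"catch_share"` or `"mean"`.
#' @return A single score in \[0, 1\], or `NA` when no scored stock has
#'   positive share.
#' @export
country_ecological_rollup <- function(stock_scores, shares,
                                      mode = c("catch_share", "mean")) {
  mode <- match.arg(mode)
  joined <- dplyr::inner_join(shares, stock_scores,
                              by = c(stock_id = "entity"))
  joined <- joined[!is.na(joined$score) & joined$share > 0, ]
  if (nrow(joined) == 0) return(NA_real_)
  if (mode == "mean") {
    mean(joined$score)
  } else {
    sum(joined$share * joined$score) / sum(joined$share)
  }
}
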