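#' Permutation importance of resilience factors
#'
#' Fits a regression random forest of the overall resilience index on the
#' factor scores and reports permutation-based variable importance (mean
#' decrease in accuracy): the increase in out-of-bag mean squared error
#' when a factor's values are shuffled, expressed as a percentage of the
#' response variance so that values are comparable across runs. An
#' uninformative factor scores near 0; a factor that alone determines the
#' index scores far above 100. Identifies which factors drive the index —
#' in the study system, the overexploitation status of the fished stocks
#' tends to dominate.
#'
#' @param factor_scores A data frame or tibble, entities x factors
#'   (numeric columns, one per factor).
#' @param index Numeric response vector, the overall index per entity.
#' @param n_trees Number of trees. Default 500.
#' @param seed Integer seed; results are deterministic given it.
#' @param mtry Features tried per split; default `ceiling(p / 3)`
#'   (regression convention).
#' @return An object of class `factor_importance`: list with
#'   `importance` (tibble `factor`, `importance_pct`, `rank`), `oob_mse`,
#'   `n_trees`, `seed`, and the fitted `forest`.
#' @export
factor_importance <- function(factor_scores, index, n_trees = 500, seed = 1,
                              mtry = NULL) {
  factor_scores <- as.data.frame(factor_scores)
  stopifnot(nrow(factor_scores) == length(index))
  if (nrow(factor_scores) < 10) {
    stop("need at least 10 entities for a stable importance estimate",
         call. = FALSE)
  }
  all_missing <- vapply(factor_scores, function(x) all(is.na(x)), logical(1))
  if (any(all_missing)) {
    stop("factor column(s) entirely missing: ",
         paste(names(factor_scores)[all_missing], collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(factor_scores) & !is.na(index)
  factor_scores <- factor_scores[keep, , drop = FALSE]
  index <- index[keep]
  if (is.null(mtry)) mtry <- ceiling(ncol(factor_scores) / 3)
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = factor_scores, y = index, ntree = n_trees, mtry = mtry,
    importance = TRUE
  )
  # raw (unscaled) permutation increase in OOB MSE, as % of var(index);
  # the scaled variant is a t-statistic and not a percentage
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)
  tb <- tibble::tibble(
    factor = rownames(imp),
    importance_pct = 100 * as.numeric(imp[, 1]) / stats::var(index),
    rank = rank(-as.numeric(imp[, 1]), ties.method = "first")
  ) |>
    dplyr::arrange(.data$rank)
  structure(
    list(importance = tb, oob_mse = rf$mse[n_trees], n_trees = n_trees,
         seed = seed, forest = rf),
    class = "factor_importance"
  )
}

#' @export
print.factor_importance <- function(x, ...) {
  cat("<factor_importance> ", x$n_trees, " trees, OOB MSE ",
      signif(x$oob_mse, 4), "\n", sep = "")
  print(x$importance)
  invisible(x)
}

#' @method tidy factor_importance
#' @export
tidy.factor_importance <- function(x, ...) x$importance

#' @method glance factor_importance
#' @export
glance.factor_importance <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, oob_mse = x$oob_mse, seed = x$seed,
                 top_factor = x$importance$factor[1])
}

#' Latitude effect on resilience scores
#'
#' Smooth regression of bounded resilience scores on latitude under a
#' quasibinomial family with logit link, testing whether resilience has a
#' latitudinal gradient (e.g., as stocks shift poleward). Returns the
#' smooth-term summary and the fitted curve on a latitude grid.
#'
#' @param scores Numeric vector in \[0, 1\], one per entity.
#' @param latitudes Numeric vector of latitudes (degrees), same length.
#' @param basis_dim Basis dimension of the smooth (capped at the number
#'   of distinct latitudes minus one). Default 10 (the mgcv default).
#' @param grid_n Number of grid points for the fitted curve.
#' @return An object of class `latitude_effect`: list with `edf`
#'   (effective degrees of freedom of the smooth), `p_value` (approximate
#'   significance), `curve` (tibble `latitude`, `fitted`), `family`,
#'   `model`.
#' @export
latitude_effect <- function(scores, latitudes, basis_dim = 10, grid_n = 100) {
  stopifnot(length(scores) == length(latitudes))
  keep <- is.finite(scores) & is.finite(latitudes)
  scores <- scores[keep]
  latitudes <- latitudes[keep]
  if (length(scores) < 10) {
    stop("need at least 10 entities to estimate a latitude smooth",
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  n_lat <- length(unique(latitudes))
  if (n_lat < 2) {
    stop("constant latitude: no smooth estimable", call. = FALSE)
  }
  k <- min(basis_dim, n_lat - 1)
  df <- data.frame(score = scores, lat = latitudes)
  grid <- data.frame(lat = seq(min(latitudes), max(latitudes),
                               length.out = grid_n))
  if (stats::var(scores) < .Machine$double.eps) {
    # constant response: the smooth is unidentifiable and its penalized
    # limit is the intercept-only fit -- a flat curve with edf 1
    fit <- stats::glm(score ~ 1, data = df,
                      family = stats::quasibinomial(link = "logit"))
    edf <- 1
    p_value <- NA_real_
  } else {
    fit <- mgcv::gam(score ~ s(lat, k = k), data = df,
                     family = stats::quasibinomial(link = "logit"))
    sm <- summary(fit)
    edf <- unname(sm$edf[1])
    p_value <- unname(sm$s.pv[1])
  }
  curve <- tibble::tibble(
    latitude = grid$lat,
    fitted = as.numeric(stats::predict(fit, grid, type = "response"))
  )
  structure(
    list(edf = edf, p_value = p_value,
         curve = curve, family = "quasibinomial(logit)", model = fit),
    class = "latitude_effect"
  )
}

#' @export
print.latitude_effect <- function(x, ...) {
  cat("<latitude_effect> smooth edf ", signif(x$edf, 3),
      ", approx p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy latitude_effect
#' @export
tidy.latitude_effect <- function(x, ...) {
  tibble::tibble(term = "s(latitude)", edf = x$edf, p_value = x$p_value)
}

#' @method glance latitude_effect
#' @export
glance.latitude_effect <- function(x, ...) {
  tibble::tibble(edf = x$edf, p_value = x$p_value, family = x$family,
                 curve_min = min(x$curve$fitted), curve_max = max(x$curve$fitted))
}
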