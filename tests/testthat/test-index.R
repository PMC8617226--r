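test_that("normalize_indicator rescales with direction reversal", {
  expect_equal(normalize_indicator(c(1, 3, 5), "+"), c(0, 0.5, 1))
  expect_equal(normalize_indicator(c(1, 3, 5), "-"), c(1, 0.5, 0))
  expect_equal(normalize_indicator(3, "+", bounds = c(1, 5)), 0.5)
  # explicit bounds clip out-of-range values
  expect_equal(normalize_indicator(c(-2, 7), "+", bounds = c(0, 5)), c(0, 1))
  # missing stays missing
  expect_equal(normalize_indicator(c(1, NA, 5), "+"), c(0, NA, 1))
})

test_that("a degenerate indicator warns and scores 0.5 everywhere", {
  expect_warning(s <- normalize_indicator(c(2, 2, 2), "+"), "degenerate")
  expect_equal(s, c(0.5, 0.5, 0.5))
})

test_that("correlation_prune leaves uncorrelated sets alone and drops duplicates once", {
  set.seed(8)
  m <- make_exact_cor_data(12, diag(3) |>
                             `dimnames<-`(list(NULL, c("a", "b", "c"))))
  pr <- correlation_prune(m, 0.75)
  expect_identical(pr$retained, c("a", "b", "c"))
  expect_equal(nrow(pr$dropped), 0)
  # duplicated column: exactly one of the pair goes
  m2 <- cbind(m, a2 = m[, "a"])
  pr2 <- correlation_prune(m2, 0.75)
  expect_equal(nrow(pr2$dropped), 1)
  expect_setequal(c(pr2$retained, pr2$dropped$indicator_id),
                  c("a", "b", "c", "a2"))
  expect_equal(abs(pr2$dropped$correlation), 1, tolerance = 1e-9)
})

test_that("the greedy drop sequence follows the highest-mean-correlation rule", {
  # planted triple: r12 = 0.9, r13 = 0.8; r23 = 0.5 (the smallest round
  # value admissible for a valid correlation matrix given the other two)
  R <- matrix(c(1, 0.9, 0.8,
                0.9, 1, 0.5,
                0.8, 0.5, 1), 3, 3,
              dimnames = list(NULL, c("i1", "i2", "i3")))
  m <- make_exact_cor_data(10, R, seed = 3)
  expect_equal(unname(cor(m)), unname(R), tolerance = 1e-10)
  pr <- correlation_prune(m, 0.75)
  # i1 has the highest mean |r| (0.85 vs 0.70 and 0.65): dropped first,
  # after which the surviving pair (r = 0.5) is below threshold
  expect_identical(pr$dropped$indicator_id, "i1")
  expect_identical(pr$retained, c("i2", "i3"))
  # threshold 1.0 drops nothing
  expect_equal(nrow(correlation_prune(m, 1.0)$dropped), 0)
})

test_that("pruning an already-pruned set is a no-op", {
  set.seed(12)
  for (i in 1:10) {
    R <- stats::cov2cor(crossprod(matrix(rnorm(25), 5, 5)) + diag(5))
    colnames(R) <- rownames(R) <- sprintf("v%d", 1:5)
    m <- make_exact_cor_data(15, R, seed = i)
    pr <- correlation_prune(m, 0.75)
    again <- correlation_prune(m[, pr$retained, drop = FALSE], 0.75)
    expect_equal(nrow(again$dropped), 0)
    expect_identical(again$retained, pr$retained)
  }
})

test_that("zero-variance columns are excluded from correlation but retained", {
  m <- cbind(make_exact_cor_data(10, diag(2) |>
                                   `dimnames<-`(list(NULL, c("a", "b")))),
             flat = rep(3, 10))
  expect_warning(pr <- correlation_prune(m, 0.75), "zero-variance")
  expect_true("flat" %in% pr$retained)
})

small_hier <- tibble::tibble(
  indicator_id = c("i1", "i2", "i3", "i4"),
  factor_id = c("F1", "F1", "F2", "F3"),
  dimension = c("d1", "d1", "d1", "d2"),
  direction = "+", entity_level = "country"
)

test_that("aggregate_scores is a stepwise mean over non-missing children", {
  scored <- tibble::tibble(
    entity = "e", entity_level = "country",
    indicator_id = c("i1", "i2", "i3", "i4"),
    factor_id = c("F1", "F1", "F2", "F3"),
    dimension = c("d1", "d1", "d1", "d2"),
    score = c(0.2, 0.8, 0.9, 0.4)
  )
  out <- aggregate_scores(scored, small_hier)
  get <- function(lvl, id) out$score[out$level == lvl & out$node_id == id]
  expect_equal(get("factor", "F1"), 0.5)
  expect_equal(get("factor", "F2"), 0.9)
  # dimension is the mean of factor scores (0.5, 0.9) -> 0.7
  expect_equal(get("dimension", "d1"), 0.7)
  expect_equal(get("overall", "overall"), mean(c(0.7, 0.4)))
  # constant scores propagate unchanged
  scored$score <- 0.7
  out2 <- aggregate_scores(scored, small_hier)
  expect_true(all(out2$score == 0.7))
})

test_that("explicit equal weights reproduce the unweighted result", {
  scored <- tibble::tibble(
    entity = rep(c("e1", "e2"), each = 4), entity_level = "country",
    indicator_id = rep(c("i1", "i2", "i3", "i4"), 2),
    factor_id = rep(c("F1", "F1", "F2", "F3"), 2),
    dimension = rep(c("d1", "d1", "d1", "d2"), 2),
    score = runif(8)
  )
  w <- list(indicator = setNames(rep(1, 4), c("i1", "i2", "i3", "i4")),
            factor = setNames(rep(1, 3), c("F1", "F2", "F3")),
            dimension = setNames(rep(1, 2), c("d1", "d2")))
  expect_equal(aggregate_scores(scored, small_hier, weights = w)$score,
               aggregate_scores(scored, small_hier)$score)
})

test_that("missing children are averaged over, never imputed", {
  scored <- tibble::tibble(
    entity = "e", entity_level = "country",
    indicator_id = c("i1", "i2", "i3", "i4"),
    factor_id = c("F1", "F1", "F2", "F3"),
    dimension = c("d1", "d1", "d1", "d2"),
    score = c(0.2, NA, NA, 0.4)
  )
  out <- aggregate_scores(scored, small_hier, require_all_dimensions = FALSE)
  get <- function(lvl, id) out$score[out$level == lvl & out$node_id == id]
  expect_equal(get("factor", "F1"), 0.2)   # mean of its one available child
  expect_true(is.na(get("factor", "F2")))  # all children missing
  expect_equal(get("dimension", "d1"), 0.2)
  expect_equal(get("overall", "overall"), mean(c(0.2, 0.4)))
  strict <- aggregate_scores(
    dplyr::mutate(scored, score = c(0.2, NA, NA, NA)), small_hier,
    require_all_dimensions = TRUE
  )
  expect_true(is.na(strict$score[strict$level == "overall"]))
})

test_that("an indicator missing from the hierarchy is a hard error", {
  scored <- tibble::tibble(entity = "e", entity_level = "country",
                           indicator_id = "mystery", factor_id = "F9",
                           dimension = "d1", score = 0.5)
  expect_error(aggregate_scores(scored, small_hier), "mystery")
})

test_that("country_ecological_rollup weights stock scores by catch share", {
  stock_scores <- tibble::tibble(entity = c("s1", "s2"), score = c(0.5, 1.0))
  sh <- tibble::tibble(stock_id = c("s1", "s2"), share = c(0.6, 0.4))
  expect_equal(country_ecological_rollup(stock_scores, sh), 0.7)
  one <- tibble::tibble(stock_id = "s1", share = 1)
  expect_equal(country_ecological_rollup(stock_scores, one), 0.5)
  eq <- tibble::tibble(stock_id = c("s1", "s2"), share = c(0.5, 0.5))
  expect_equal(country_ecological_rollup(stock_scores, eq),
               country_ecological_rollup(stock_scores, eq, mode = "mean"))
  none <- tibble::tibble(stock_id = "s9", share = 1)
  expect_true(is.na(country_ecological_rollup(stock_scores, none)))
})

test_that("every emitted score is bounded and order-invariant", {
  sc <- synthetic_scenario(seed = 13, n_countries = 6, n_stocks = 4,
                           noise_sd = 0.3)
  d <- generate_dataset(sc)
  r <- compute_resilience(d)
  expect_true(all(r$scores$score >= 0 & r$scores$score <= 1, na.rm = TRUE))
  # permuting input rows changes nothing but order
  d2 <- d
  set.seed(1)
  d2$country_records <- d2$country_records[sample(nrow(d2$country_records)), ]
  d2$stock_series <- d2$stock_series[order(d2$stock_series$year), ]
  r2 <- compute_resilience(d2)
  a <- dplyr::arrange(r$scores, entity, level, node_id)
  b <- dplyr::arrange(r2$scores, entity, level, node_id)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("the shipped hierarchy file matches the canonical in-code table", {
  path <- system.file("extdata", "hierarchy.csv", package = "fishres")
  shipped <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(shipped), as.data.frame(indicator_hierarchy()))
})
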