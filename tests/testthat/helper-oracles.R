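# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

# enumerate below-limit runs by walking the series year by year
oracle_recovery <- function(years, ssb, lim) {
  best <- 0L
  i <- 1L
  n <- length(years)
  while (i <= n) {
    if (ssb[i] < lim) {
      first <- i
      while (i <= n && ssb[i] < lim) i <- i + 1L
      dur <- if (i > n) years[n] - years[first] + 1L else years[i] - years[first]
      if (dur > best) best <- dur
    } else {
      i <- i + 1L
    }
  }
  best
}

# OLS slope via lm(), independent of the closed-form implementation
oracle_relative_trend <- function(years, values, period) {
  keep <- years >= period[1] & years <= period[2]
  fit <- lm(values[keep] ~ years[keep])
  unname(coef(fit)[2]) / mean(values[keep])
}

# mean-of-means index on a raw long table, written as plain loops:
# min-max per indicator (direction-reversed), then indicator -> factor ->
# dimension -> overall means over non-missing children
oracle_index <- function(raw, hierarchy) {
  ents <- unique(raw$entity)
  norm <- raw
  for (id in unique(raw$indicator_id)) {
    sel <- raw$indicator_id == id
    v <- raw$value[sel]
    dir <- hierarchy$direction[hierarchy$indicator_id == id]
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    s <- (v - lo) / (hi - lo)
    if (dir == "-") s <- 1 - s
    norm$score[sel] <- s
  }
  out <- list()
  for (e in ents) {
    sub <- norm[norm$entity == e, ]
    dims <- list()
    for (dm in unique(hierarchy$dimension)) {
      facs <- c()
      for (fc in unique(hierarchy$factor_id[hierarchy$dimension == dm])) {
        ids <- hierarchy$indicator_id[hierarchy$factor_id == fc]
        v <- sub$score[sub$indicator_id %in% ids]
        v <- v[!is.na(v)]
        if (length(v) > 0) facs[fc] <- mean(v)
      }
      if (length(facs) > 0) dims[[dm]] <- mean(facs)
      for (fc in names(facs)) {
        out[[paste(e, "factor", fc, sep = ".")]] <- unname(facs[[fc]])
      }
    }
    out[[paste0(e, ".dims")]] <- unlist(dims)
    out[[paste0(e, ".overall")]] <- mean(unlist(dims))
  }
  out
}

# data matrix with an EXACTLY prescribed sample correlation matrix:
# center + orthonormalize a random basis, then color by chol(R)
make_exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  # columns of Q span the centered columns of X, so they are themselves
  # centered as well as orthonormal
  Q <- qr.Q(qr(X))
  Y <- Q %*% chol(R)
  colnames(Y) <- colnames(R)
  Y
}

# a random small hierarchy + raw table for oracle-equivalence checks
random_small_instance <- function(seed) {
  set.seed(seed)
  n_ent <- sample(3:5, 1)
  n_ind <- sample(3:6, 1)
  ind <- sprintf("x%d", seq_len(n_ind))
  fac <- sprintf("F%d", sample(1:3, n_ind, replace = TRUE))
  dms <- c("ecological", "socioeconomic")
  dim_of_fac <- setNames(sample(dms, length(unique(fac)), replace = TRUE),
                         unique(fac))
  hier <- tibble::tibble(
    indicator_id = ind, factor_id = fac, dimension = dim_of_fac[fac],
    direction = sample(c("+", "-"), n_ind, replace = TRUE),
    entity_level = "country"
  )
  raw <- tidyr::expand_grid(entity = sprintf("e%d", seq_len(n_ent)),
                            indicator_id = ind) |>
    dplyr::left_join(hier, by = "indicator_id") |>
    dplyr::mutate(value = stats::runif(dplyr::n()), score = NA_real_)
  list(hierarchy = hier, raw = raw)
}
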