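# Independent brute-force oracles used to cross-check the vectorized
# implementations. All are deliberately written as plain loops / hand formulas.

# midranks without stats::rank: average position of tied values
oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho: Pearson product-moment formula applied to midranks
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# cellwise mean with nodata propagation
oracle_consensus <- function(a, b) {
  out <- a
  for (i in seq_along(a)) {
    out[i] <- if (is.na(a[i]) || is.na(b[i])) NA else (a[i] + b[i]) / 2
  }
  out
}

# two-value CV after the documented positivity shift
oracle_pairwise_cv <- function(a, b) {
  shift <- -min(c(a, b), na.rm = TRUE) + 1e-6
  out <- a
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) { out[i] <- NA; next }
    av <- a[i] + shift; bv <- b[i] + shift
    out[i] <- 100 * (abs(av - bv) / 2) / ((av + bv) / 2)
  }
  out
}

# type-7 quantile by hand: h = (n-1)p + 1 on the sorted values
oracle_quantile7 <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_percentile_mask <- function(spread, q) {
  thr <- oracle_quantile7(spread, q / 100)
  out <- matrix(FALSE, nrow(spread), ncol(spread))
  for (i in seq_along(spread)) {
    out[i] <- !is.na(spread[i]) && spread[i] <= thr
  }
  out
}

oracle_combine <- function(mask_list) {
  out <- mask_list[[1]]
  for (m in mask_list[-1]) for (i in seq_along(out)) out[i] <- out[i] && m[i]
  out
}

oracle_hotspot <- function(values, keep, q) {
  thr <- oracle_quantile7(values[keep], q / 100)
  out <- matrix(FALSE, nrow(values), ncol(values))
  for (i in seq_along(values)) {
    out[i] <- keep[i] && !is.na(values[i]) && values[i] > thr
  }
  out
}

oracle_union <- function(a, b) {
  out <- a
  for (i in seq_along(a)) out[i] <- a[i] || b[i]
  out
}

oracle_overlap_pct <- function(fungal, plant) {
  f <- 0; ov <- 0
  for (i in seq_along(fungal)) {
    if (fungal[i]) {
      f <- f + 1
      if (plant[i]) ov <- ov + 1
    }
  }
  100 * ov / f
}

# Pearson chi-squared on a 2x2 table by the textbook formula
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# least squares by normal equations, no lm()
oracle_lm_coef <- function(X, y) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)
}
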