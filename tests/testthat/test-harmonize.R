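test_that("log1p standardization matches the closed form on three points", {
  lay <- richness_layer(matrix(c(0, exp(1) - 1, exp(2) - 1), 1, 3), "raw")
  out <- log1p_standardize(lay)
  # log1p gives {0, 1, 2}; centring and scaling by the sample SD gives {-1, 0, 1}
  expect_equal(as.numeric(out$values), c(-1, 0, 1), tolerance = 1e-12)
  expect_identical(out$transform, "standardized")
})

test_that("log1p standardization enforces the transform state machine", {
  std <- log1p_standardize(richness_layer(matrix(1:20, 4, 5), "raw"))
  expect_error(log1p_standardize(std), "already standardized")
  logged <- richness_layer(matrix(log1p(1:20), 4, 5), "log1p")
  out <- log1p_standardize(logged)
  expect_equal(mean(out$values), 0, tolerance = 1e-12)
  expect_equal(sd(out$values), 1, tolerance = 1e-12)
  expect_error(log1p_standardize(richness_layer(matrix(0, 2, 2), "raw")),
               "zero-variance")
  expect_error(log1p_standardize(richness_layer(matrix(NA_real_, 2, 2), "raw")),
               "all-nodata")
})

test_that("standardization post-condition holds on a fixture layer", {
  lay <- make_fixture("tiny-4x5")$taxa$plant$studies[[1]]
  out <- log1p_standardize(lay)
  v <- out$values
  # recompute moments independently
  expect_equal(sum(v) / length(v), 0, tolerance = 1e-10)
  expect_equal(sqrt(sum((v - mean(v))^2) / (length(v) - 1)), 1, tolerance = 1e-10)
})

test_that("consensus mean is the cellwise average with nodata propagation", {
  p <- fixture_std_pair()
  cons <- consensus_mean(p$a, p$b)
  expect_equal(cons$values, oracle_consensus(p$a$values, p$b$values))
  expect_identical(cons$provenance, "consensus")
  # idempotence
  same <- consensus_mean(p$a, p$a)
  expect_equal(same$values, p$a$values)
  # simple arithmetic
  a <- richness_layer(matrix(1, 1, 2), "standardized")
  b <- richness_layer(matrix(-1, 1, 2), "standardized")
  expect_equal(as.numeric(consensus_mean(a, b)$values), c(0, 0))
  # state mismatch
  expect_error(consensus_mean(a, richness_layer(matrix(1, 1, 2), "raw")),
               "standardized")
})

test_that("pairwise CV matches the brute-force oracle and is symmetric", {
  p <- fixture_std_pair()
  cv_ab <- pairwise_cv(p$a, p$b)
  cv_ba <- pairwise_cv(p$b, p$a)
  expect_equal(cv_ab$values, oracle_pairwise_cv(p$a$values, p$b$values),
               tolerance = 1e-12)
  expect_equal(cv_ab$values, cv_ba$values, tolerance = 1e-12)
  expect_true(is.finite(attr(cv_ab, "shift")))
  # identical inputs give CV zero everywhere
  cv0 <- pairwise_cv(p$a, p$a)
  expect_true(all(cv0$values[!is.na(cv0$values)] == 0))
})

test_that("pairwise CV reproduces the two-value hand computation", {
  # shifted values 2 and 4: CV = (|2-4|/2)/3 = 1/3
  a0 <- matrix(c(2, 1e-6), 1, 2); b0 <- matrix(c(4, 4), 1, 2)
  # craft standardized-state layers whose post-shift values are 2 and 4 at cell 1:
  # min across both is 0 at cell 2 of a, so shift = 1e-6; feed values directly.
  a <- structure(list(values = a0 - 1e-6, transform = "standardized",
                      provenance = "a"), class = "richness_layer")
  b <- structure(list(values = b0 - 1e-6, transform = "standardized",
                      provenance = "b"), class = "richness_layer")
  cv <- pairwise_cv(a, b)
  expect_equal(cv$values[1, 1] / 100, 1 / 3, tolerance = 1e-9)
})

test_that("percentile mask retains <= threshold and matches the sort oracle", {
  set.seed(42)
  spread <- matrix(sample(seq(0.01, 1, length.out = 100)), 10, 10)
  u <- uncertainty_layer(spread, "cv_percent")
  m <- percentile_mask(u, 95)
  expect_identical(sum(m$values), 95L)          # distinct values: exactly 95 kept
  expect_equal(m$values, oracle_percentile_mask(spread, 95))
  # tie policy: all values equal means everything is retained
  m_tie <- percentile_mask(uncertainty_layer(matrix(0.3, 5, 5), "sd"), 95)
  expect_true(all(m_tie$values))
  expect_error(percentile_mask(uncertainty_layer(matrix(NA_real_, 2, 2), "sd")),
               "empty")
})

test_that("mask combination is a cellwise AND and monotone", {
  set.seed(9)
  ms <- lapply(1:3, function(i) cell_mask(matrix(runif(100) < 0.9, 10, 10),
                                          paste0("m", i)))
  comb <- combine_masks(ms)
  expect_equal(comb$values, oracle_combine(lapply(ms, `[[`, "values")))
  expect_identical(combine_masks(ms[1])$values, ms[[1]]$values)  # identity
  # adding a mask never increases retention
  expect_lte(sum(combine_masks(ms)$values), sum(combine_masks(ms[1:2])$values))
  expect_identical(length(comb$provenance), 3L)
})

test_that("retained fraction is exact on fixtures and bounded on random masks", {
  m_full <- cell_mask(matrix(TRUE, 4, 5))
  expect_equal(retained_fraction(m_full)$percent, 100)
  m19 <- matrix(TRUE, 4, 5); m19[2, 3] <- FALSE
  expect_equal(retained_fraction(cell_mask(m19))$percent, 95)
  # two random 95%-retention masks keep at least 90% combined
  set.seed(3)
  big <- lapply(1:2, function(i) {
    v <- matrix(TRUE, 100, 100); v[sample(10000, 500)] <- FALSE
    cell_mask(v)
  })
  expect_gte(retained_fraction(combine_masks(big))$percent, 90)
})

test_that("per-zone retention is reported and masking is monotone per zone", {
  w <- small_world()
  comp <- build_comparison(w, "am")
  rf_all <- retained_fraction(comp$mask, w$zones)
  rf_sub <- retained_fraction(combine_masks(comp$masks[1:2]), w$zones)
  eco_all <- rf_all[rf_all$scale == "ecoregion", ]
  eco_sub <- rf_sub[rf_sub$scale == "ecoregion", ]
  m <- merge(eco_all, eco_sub, by = "zone_id")
  expect_true(all(m$percent.x <= m$percent.y + 1e-12))
  expect_true(rf_all$percent[rf_all$scale == "global"] >= 50)
})
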