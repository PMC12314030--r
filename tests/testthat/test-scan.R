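test_that("sampling honours quotas, the minimum-cell rule and the seed", {
  w <- small_world()
  comp <- build_comparison(w, "am")
  sm <- sample_cells(comp, "ecoregion", quota = 300, min_cells = 100, seed = 4)
  for (df in sm$samples) {
    expect_lte(nrow(df), 300)
    expect_false(any(duplicated(df$cell)))
    expect_true(all(comp$mask$values[df$cell]))
    expect_true(all(df$ecoregion_id == attr(df, "zone_id")))
  }
  # quota larger than available uses every masked cell
  big <- sample_cells(comp, "ecoregion", quota = 10000, min_cells = 100, seed = 4)
  zid <- names(big$samples)[1]
  avail <- sum(comp$mask$values & w$zones$values == as.integer(zid))
  expect_identical(nrow(big$samples[[zid]]), avail)
  # a min_cells rule larger than any zone excludes (and reports) all zones
  excl <- sample_cells(comp, "ecoregion", quota = 300, min_cells = 10000, seed = 4)
  expect_identical(length(excl$samples), 0L)
  expect_identical(nrow(excl$excluded), nrow(w$zones$lookup))
  # determinism
  sm2 <- sample_cells(comp, "ecoregion", quota = 300, min_cells = 100, seed = 4)
  expect_identical(sm$samples, sm2$samples)
  sm3 <- sample_cells(comp, "ecoregion", quota = 300, min_cells = 100, seed = 5)
  expect_false(identical(sm$samples[[1]]$cell, sm3$samples[[1]]$cell))
})

test_that("Spearman correlation matches hand computations and flags degeneracy", {
  # rank-formula hand computation: d^2 = (1,1,1,1,0) -> 1 - 6*4/120 = 0.8
  df <- data.frame(plant = 1:5, fungal = c(2, 1, 4, 3, 5))
  expect_equal(spearman_correlation(df)$rho, 0.8)
  # monotone transforms
  df2 <- data.frame(plant = c(1, 2, 3, 4, 5), fungal = c(1, 4, 9, 16, 25))
  expect_equal(spearman_correlation(df2)$rho, 1.0)
  df3 <- data.frame(plant = 1:5, fungal = -(1:5))
  expect_equal(spearman_correlation(df3)$rho, -1.0)
  expect_error(spearman_correlation(data.frame(plant = rep(1, 5), fungal = 1:5)),
               "constant")
  expect_error(spearman_correlation(data.frame(plant = 1:2, fungal = 2:1)),
               "at least 3")
})

test_that("Spearman is invariant to strictly increasing transforms (with ties)", {
  set.seed(8)
  for (i in 1:5) {
    x <- sample(1:20, 50, replace = TRUE)   # ties on purpose
    y <- sample(1:20, 50, replace = TRUE)
    base <- spearman_correlation(data.frame(plant = x, fungal = y))$rho
    tr <- spearman_correlation(data.frame(plant = exp(x / 3), fungal = y^3))$rho
    expect_equal(base, tr, tolerance = 1e-12)
    expect_equal(base, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("scan records match direct per-zone computation on a two-zone fixture", {
  oz <- make_fixture("two-zone-opposite-signs")
  sc <- scan_all_scales(oz, quotas = list(global = 100, biome = 100, ecoregion = 100),
                        min_cells = 10, seed = 2, taxa = "am")
  eco <- sc$correlations[sc$correlations$scale == "ecoregion", ]
  comp <- sc$comparisons$am
  for (i in seq_len(nrow(eco))) {
    sel <- comp$zones$values == eco$zone_id[i] & comp$mask$values
    direct <- oracle_spearman(comp$plant$values[sel], comp$fungal$values[sel])
    expect_equal(eco$rho[i], direct, tolerance = 1e-12)
  }
  expect_true(all(eco$rho[eco$zone_id == 1] > 0.8))
  expect_true(all(eco$rho[eco$zone_id == 2] < -0.8))
})

test_that("mixing zones of opposite correlation sign attenuates the global estimate", {
  w <- make_world(world_config(nrow = 60, ncol = 240, n_biomes = 1,
                               eco_per_biome = 4, rho_am = c(0.6, -0.6, 0.6, -0.6),
                               autocorr_length = 1, noise_cv = 0, noise_sd_log = 0,
                               covariate_effect = 0, seed = 6))
  sc <- scan_all_scales(w, quotas = list(global = 5000, biome = 5000,
                                         ecoregion = 1000),
                        min_cells = 100, seed = 3, taxa = "am")
  glob <- abs(sc$correlations$rho[sc$correlations$scale == "global"])
  zonal <- abs(sc$correlations$rho[sc$correlations$scale == "ecoregion"])
  expect_lt(glob, mean(zonal))
  expect_lt(glob, max(zonal))
})

test_that("biome t-tests reject a shifted mean and error on degenerate input", {
  recs <- data.frame(taxon_pair = "plant-am", scale = "ecoregion",
                     zone_id = 1:30, biome_id = 1L,
                     rho = local({ set.seed(11); rnorm(30, 0.3, 0.1) }),
                     n = 500)
  out <- biome_sign_test(recs)
  expect_lt(out$p, 0.05)
  expect_gt(out$mean_rho, 0.2)
  # degenerate cases error when a single group is tested
  recs$rho <- 0.5
  expect_error(biome_sign_test(recs), "zero variance")
  expect_error(biome_sign_test(recs[1, ]), "fewer than 2")
  # symmetric-around-zero values give a large p
  recs2 <- recs
  recs2$rho <- rep(c(-0.2, 0.2), 15)
  expect_gt(biome_sign_test(recs2)$p, 0.9)
})

test_that("smooth fits capture linear, null and hump-shaped relationships", {
  set.seed(14)
  x <- runif(1000, 0, 10)
  lin <- data.frame(plant = x, fungal = 2 + 3 * x)
  expect_gte(fit_richness_smooth(lin, k = 3)$deviance_explained, 99.9)
  null <- data.frame(plant = x, fungal = rnorm(1000))
  d0 <- fit_richness_smooth(null, k = 3)$deviance_explained
  expect_lt(d0, 5)
  expect_gte(d0, 0)
  hump <- data.frame(plant = x, fungal = -(x - 5)^2 + rnorm(1000, 0, 0.5))
  smooth_de <- fit_richness_smooth(hump, k = 3)$deviance_explained
  line_r2 <- 100 * summary(lm(fungal ~ plant, hump))$r.squared
  expect_gt(smooth_de, line_r2)
  expect_error(fit_richness_smooth(lin[1:20, ], k = 3), "10\\*k")
})

test_that("smooth deviance explained tracks linear R^2 when the truth is linear", {
  set.seed(15)
  x <- runif(800)
  df <- data.frame(plant = x, fungal = 1 + 2 * x + rnorm(800, 0, 0.5))
  de <- fit_richness_smooth(df, k = 3)$deviance_explained
  r2 <- 100 * summary(lm(fungal ~ plant, df))$r.squared
  expect_lt(abs(de - r2), 1)
})

test_that("metric comparison is 1 for noiseless monotone relations and needs 3 zones", {
  set.seed(16)
  x <- runif(500, 0.1, 1)
  zones <- lapply(1:6, function(i) {
    strength <- i / 6
    df <- data.frame(plant = x, fungal = strength * x + (1 - strength) * runif(500))
    attr(df, "zone_id") <- i
    df
  })
  corr <- do.call(rbind, lapply(zones, function(df)
    cbind(zone_id = attr(df, "zone_id"), spearman_correlation(df))))
  fits <- do.call(rbind, lapply(zones, fit_richness_smooth))
  cm <- compare_metrics(corr, fits)
  expect_gt(cm$rho, 0.8)
  expect_error(compare_metrics(corr[1:2, ], fits), "3 matched zones")
  # shuffled pairing destroys the relation
  corr_sh <- corr
  corr_sh$rho <- corr$rho[c(4, 6, 5, 2, 1, 3)]
  expect_lt(abs(compare_metrics(corr_sh, fits)$rho), 0.9)
})
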