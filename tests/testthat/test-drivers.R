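test_that("partial deviance follows the nested-deviance arithmetic", {
  expect_equal(partial_deviance_explained(40, 60, 100), 20)
  expect_equal(partial_deviance_explained(60, 60, 100), 0)
  expect_error(partial_deviance_explained(1, 2, 0), "zero")
  expect_warning(out <- partial_deviance_explained(60, 50, 100), "clipping")
  expect_equal(out, 0)
})

test_that("deviance partition matches independent refits and is affine-invariant", {
  set.seed(20)
  n <- 1500
  df <- data.frame(plant = runif(n), temperature = runif(n),
                   precipitation = runif(n), ph = runif(n), soc = runif(n),
                   nitrogen = runif(n), phosphorus = runif(n),
                   elevation = runif(n))
  df$fungal <- 2 * df$plant + df$temperature + rnorm(n, 0, 0.3)
  part <- deviance_partition(df, k = 3)
  # independent refits straight through mgcv with hand-built formulas
  full <- mgcv::gam(fungal ~ s(plant, k = 3, bs = "tp") + s(temperature, k = 3, bs = "tp") +
                      s(precipitation, k = 3, bs = "tp") + s(ph, k = 3, bs = "tp") +
                      s(soc, k = 3, bs = "tp") + s(nitrogen, k = 3, bs = "tp") +
                      s(phosphorus, k = 3, bs = "tp") + s(elevation, k = 3, bs = "tp"),
                    data = df, method = "REML")
  red <- mgcv::gam(fungal ~ s(temperature, k = 3, bs = "tp") +
                     s(precipitation, k = 3, bs = "tp") + s(ph, k = 3, bs = "tp") +
                     s(soc, k = 3, bs = "tp") + s(nitrogen, k = 3, bs = "tp") +
                     s(phosphorus, k = 3, bs = "tp") + s(elevation, k = 3, bs = "tp"),
                   data = df, method = "REML")
  oracle <- 100 * (deviance(red) - deviance(full)) / full$null.deviance
  expect_equal(part$partial_pct, oracle, tolerance = 1e-8)
  expect_true(part$dev_null >= part$dev_reduced && part$dev_reduced >= part$dev_full)
  # affine rescaling of covariates leaves the partition unchanged
  df2 <- df
  df2$temperature <- 100 + 25 * df2$temperature
  df2$ph <- -3 * df2$ph
  expect_equal(deviance_partition(df2, k = 3)$partial_pct, part$partial_pct,
               tolerance = 1e-6)
})

test_that("global driver model reports collinearity and refits deterministically", {
  set.seed(21)
  n <- 400
  df <- data.frame(plant = runif(n), temperature = runif(n))
  df$precipitation <- df$temperature          # duplicate covariate
  df$fungal <- rnorm(n)
  expect_error(fit_global_driver_model(df, c("temperature", "precipitation")),
               "collinear")
  df$precipitation <- runif(n)
  f1 <- fit_global_driver_model(df, c("temperature", "precipitation"))
  f2 <- fit_global_driver_model(df, c("temperature", "precipitation"))
  expect_identical(f1$deviance, f2$deviance)
  expect_error(fit_global_driver_model(df[1:20, ], c("temperature", "precipitation")),
               "10 observations per smooth term")
})

test_that("zone sign models recover constructed signs and match a least-squares oracle", {
  oz <- make_fixture("two-zone-opposite-signs")
  comp <- build_comparison(oz, "am")
  sm <- sample_cells(comp, "ecoregion", quota = 100, min_cells = 10, seed = 1)
  sp <- fit_zone_sign_models(sm$samples[["2"]], "temperature", "am_host_pct",
                             min_cells = 10)
  expect_true(sign(sp$plant_est) != sign(sp$fungal_est))
  # oracle: normal-equations solve on the same [0,1]-scaled design
  df <- sm$samples[["2"]]
  sc01 <- function(x) (x - min(x)) / (max(x) - min(x))
  X <- cbind(env = sc01(df$temperature), other = sc01(df$fungal),
             host = sc01(df$am_host_pct))
  beta <- oracle_lm_coef(X, sc01(df$plant))
  expect_equal(sp$plant_est, unname(beta["env", 1]), tolerance = 1e-9)
  # preconditions
  expect_error(fit_zone_sign_models(df[1:20, ], "temperature", "am_host_pct"),
               "min_cells")
  df$temperature <- rep(1:5, length.out = nrow(df))
  expect_error(fit_zone_sign_models(df, "temperature", "am_host_pct",
                                    min_cells = 10), "10 unique values")
})

test_that("sign-concordance chi-squared matches the hand formula", {
  # counts: same-sign x (rho+, rho-) = (30, 10); opposite x (rho+, rho-) = (8, 25)
  pairs <- data.frame(
    zone_id = 1:73,
    plant_est = c(rep(1, 30), rep(1, 10), rep(1, 8), rep(1, 25)),
    fungal_est = c(rep(1, 30), rep(1, 10), rep(-1, 8), rep(-1, 25)),
    plant_p = 0.01, fungal_p = 0.01,
    rho = c(rep(0.5, 30), rep(-0.5, 10), rep(0.5, 8), rep(-0.5, 25)))
  res <- sign_concordance_test(pairs)
  expect_equal(unclass(res$table)[1:4],
               c(30L, 8L, 10L, 25L), ignore_attr = TRUE)
  expect_equal(res$statistic, oracle_chisq(matrix(c(30, 8, 10, 25), 2, 2)),
               tolerance = 1e-9)
  expect_identical(res$n_used, 73L)
})

test_that("sign-concordance limiting cases behave as expected", {
  mk <- function(n_agree_pos, n_dis_neg, n_agree_neg = 0, n_dis_pos = 0) {
    n <- n_agree_pos + n_dis_neg + n_agree_neg + n_dis_pos
    data.frame(zone_id = seq_len(n),
               plant_est = 1,
               fungal_est = c(rep(1, n_agree_pos), rep(-1, n_dis_neg),
                              rep(1, n_agree_neg), rep(-1, n_dis_pos)),
               plant_p = 0.001, fungal_p = 0.001,
               rho = c(rep(1, n_agree_pos), rep(-1, n_dis_neg),
                       rep(-1, n_agree_neg), rep(1, n_dis_pos)))
  }
  # perfectly concordant: p shrinks with n
  p20 <- sign_concordance_test(mk(20, 20))$p
  p60 <- sign_concordance_test(mk(60, 60))$p
  expect_lt(p60, p20)
  expect_lt(p60, 1e-10)
  # uniform table: statistic 0, p = 1
  unif <- sign_concordance_test(mk(10, 10, 10, 10))
  expect_equal(unif$statistic, 0)
  expect_equal(unif$p, 1)
  # the p filter removes rows but never flips recorded signs
  pairs <- mk(5, 5)
  pairs$plant_p[1:3] <- 0.5
  res <- sign_concordance_test(pairs)
  expect_identical(res$n_excluded, 3L)
  expect_identical(sum(res$table), 7L)
  # everything filtered out
  pairs$plant_p <- 0.5
  expect_error(sign_concordance_test(pairs), "empty table")
})

test_that("collinearity sensitivity drops flagged zones and tracks the fraction", {
  pairs <- data.frame(zone_id = 1:40, plant_est = 1,
                      fungal_est = rep(c(1, -1), each = 20),
                      plant_p = 0.001, fungal_p = 0.001,
                      rho = rep(c(1, -1), each = 20))
  zc <- data.frame(zone_id = 1:40, max_abs_cor = c(rep(0.95, 4), rep(0.5, 36)))
  out <- collinearity_sensitivity(pairs, zc, cutoffs = c(0.85, 0.80))
  expect_equal(out[["0.85"]]$dropped_fraction, 0.1)
  expect_identical(out[["0.85"]]$n_zones, 36L)
  # no zone above the cutoff reproduces the baseline exactly
  zc0 <- data.frame(zone_id = 1:40, max_abs_cor = 0.2)
  base <- sign_concordance_test(pairs)
  same <- collinearity_sensitivity(pairs, zc0, cutoffs = 0.85)[["0.85"]]
  expect_equal(same$result$statistic, base$statistic)
  expect_equal(same$dropped_fraction, 0)
  # all zones dropped
  zc1 <- data.frame(zone_id = 1:40, max_abs_cor = 0.99)
  expect_error(collinearity_sensitivity(pairs, zc1, cutoffs = 0.85))
})

test_that("normality screen calibrates near 5% on normal data and flags skew", {
  set.seed(31)
  zones_norm <- lapply(1:60, function(i) {
    df <- data.frame(plant = rnorm(500), fungal = rnorm(500))
    attr(df, "zone_id") <- i
    df
  })
  out <- normality_screen(zones_norm)
  rate <- mean(out$flagged)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
  zones_exp <- lapply(1:20, function(i) {
    df <- data.frame(plant = rexp(500), fungal = rexp(500))
    attr(df, "zone_id") <- i
    df
  })
  expect_true(all(normality_screen(zones_exp)$flagged))
  const <- list(structure(data.frame(plant = rep(1, 50), fungal = rnorm(50)),
                          zone_id = 1L))
  res <- normality_screen(const)
  expect_match(res$note[res$response == "plant"], "not testable")
})

test_that("correlation-driver model recovers a stability-driven signal", {
  # rho targets constructed monotone in climate stability; the fitted partial
  # effect of stability must be increasing and carry most of the rho variance
  w <- make_world(world_config(nrow = 120, ncol = 180, n_biomes = 6,
                               eco_per_biome = 10, rho_am = "climate_stability",
                               noise_cv = 0.05, noise_sd_log = 0.05,
                               covariate_effect = 0, seed = 9))
  sc <- scan_all_scales(w, quotas = list(global = 2000, biome = 2000,
                                         ecoregion = 300),
                        min_cells = 50, seed = 2, taxa = "am")
  zt <- zone_driver_table(sc, "am")
  fit <- fit_correlation_driver_model(zt, k = 4, min_zones = 50)
  expect_gt(fit$deviance_explained, 50)
  ps <- fit$partials[fit$partials$term == "climate_stability", ]
  ps <- ps[order(ps$x), ]
  expect_gt(cor(ps$x, ps$effect, method = "spearman"), 0.9)
  # a null covariate's partial effect stays flat relative to the signal's
  ph <- fit$partials[fit$partials$term == "human_dev", ]
  expect_lt(diff(range(ph$effect)), diff(range(ps$effect)) / 2)
  # preconditions
  expect_error(fit_correlation_driver_model(zt[1:10, ], min_zones = 50),
               "insufficient zones")
  zt$temperature <- zt$ph
  expect_error(fit_correlation_driver_model(zt, min_zones = 50), "collinearity")
})
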