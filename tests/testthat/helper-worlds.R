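# Shared small worlds for tests (built once per test run)

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_world(world_config(nrow = 80, ncol = 80, n_biomes = 4,
                                        eco_per_biome = 3, seed = 7))
    }
    cache
  }
})

# noise-free single-biome world with one ecoregion per rho target and
# independent cells (no spatial smoothing, no covariate effects)
recovery_world <- function(targets, zone_side = 40, seed = 21,
                           integer_richness = TRUE) {
  make_world(world_config(
    nrow = zone_side, ncol = zone_side * length(targets),
    n_biomes = 1, eco_per_biome = length(targets),
    rho_am = targets, rho_ecm = targets,
    autocorr_length = 1, noise_cv = 0, noise_sd_log = 0,
    covariate_effect = 0, integer_richness = integer_richness, seed = seed))
}

# standardized layer pair with some nodata, for oracle comparisons
fixture_std_pair <- function(seed = 5, nr = 10, nc = 10, na_frac = 0.1) {
  set.seed(seed)
  mk <- function(p) {
    v <- matrix(exp(rnorm(nr * nc, 4, 0.5)), nr, nc)
    v[sample(nr * nc, round(na_frac * nr * nc))] <- NA
    log1p_standardize(richness_layer(v, "raw", p))
  }
  list(a = mk("study-a"), b = mk("study-b"))
}
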