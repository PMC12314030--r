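#' Configuration for the synthetic world generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' spatially autocorrelated richness surfaces for vascular plants and two
#' mycorrhizal guilds (AM, ECM), a known per-ecoregion Spearman correlation
#' between plant and fungal richness (Gaussian-copula construction), two noisy
#' "study" replicates per taxon with honest heteroscedastic uncertainty
#' surfaces in the dialects used by published products, rectangular
#' biome/ecoregion tiles, and environmental covariates that drive richness
#' with per-ecoregion signs.
#'
#' Zones are laid out as `n_biomes` horizontal bands of rows, each split into
#' `eco_per_biome` vertical tiles; ecoregion `e` of biome `b` gets id
#' `(b-1)*eco_per_biome + e`.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param n_biomes number of biomes (horizontal bands).
#' @param eco_per_biome ecoregions per biome (vertical tiles within a band).
#' @param rho_am,rho_ecm per-ecoregion target Spearman correlation between
#'   plant and fungal richness; a scalar is recycled, a vector must have one
#'   value per ecoregion, or the name of a covariate (e.g.
#'   `"climate_stability"`) to derive targets as `0.8 *` the zone-mean of that
#'   covariate scaled to \[0, 1\]. Defaults span the negative-to-positive
#'   range observed across real ecoregions.
#' @param autocorr_length spatial autocorrelation length in cells (Gaussian
#'   smoothing kernel SD); 1 gives effectively independent cells.
#' @param noise_cv per-study observation noise for raw-scale study layers, as
#'   a fraction of true richness (heteroscedastic: scaled per cell by a smooth
#'   field in \[0.5, 1.5\] of this value).
#' @param noise_sd_log per-study noise SD for the pre-logged study layers.
#' @param covariate_effect strength of the additive covariate effect injected
#'   on the latent (Gaussian) scale before the richness link; 0 disables it.
#' @param injected_covariates covariates receiving injected effects.
#' @param fungal_sign_mode `"match_rho"` makes each fungal guild respond to
#'   injected covariates with the sign of its zone's `rho` target (plants
#'   always respond positively), so correlation sign and response
#'   sign-agreement coincide by construction; `"positive"` makes all responses
#'   positive.
#' @param integer_richness round true richness to integer counts `>= 1`
#'   (the realistic default); `FALSE` keeps the continuous link value, which
#'   makes monotone constructions exactly tie-free.
#' @param seed integer seed fixing all generated layers.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(nrow = 240, ncol = 240, n_biomes = 6, eco_per_biome = 10,
                         rho_am = NULL, rho_ecm = NULL,
                         autocorr_length = 3, noise_cv = 0.15, noise_sd_log = 0.15,
                         covariate_effect = 0.4,
                         injected_covariates = c("temperature", "precipitation", "ph"),
                         fungal_sign_mode = c("match_rho", "positive"),
                         integer_richness = TRUE, seed = 1L) {
  fungal_sign_mode <- match.arg(fungal_sign_mode)
  if (nrow <= 0 || ncol <= 0) stop("grid dimensions must be positive")
  if (n_biomes < 1 || eco_per_biome < 1) stop("need at least one zone")
  if (nrow < n_biomes || ncol < eco_per_biome) stop("ecoregion smaller than 1 cell")
  n_eco <- n_biomes * eco_per_biome
  expand_rho <- function(rho, default) {
    if (is.null(rho)) rho <- default
    if (is.character(rho)) return(rho)
    if (length(rho) == 1) rho <- rep(rho, n_eco)
    if (length(rho) != n_eco) stop("rho must be scalar or one value per ecoregion")
    if (any(!is.finite(rho)) || any(abs(rho) > 1)) stop("rho targets must be finite in [-1, 1]")
    rho
  }
  rho_am <- expand_rho(rho_am, seq(-0.76, 0.89, length.out = n_eco))
  rho_ecm <- expand_rho(rho_ecm, seq(-0.3, 0.84, length.out = n_eco))
  if (noise_cv < 0 || noise_sd_log < 0) stop("noise SD must be >= 0")
  if (autocorr_length < 1) stop("autocorrelation length must be >= 1 cell")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 n_biomes = as.integer(n_biomes),
                 eco_per_biome = as.integer(eco_per_biome),
                 rho_am = rho_am, rho_ecm = rho_ecm,
                 autocorr_length = autocorr_length,
                 noise_cv = noise_cv, noise_sd_log = noise_sd_log,
                 covariate_effect = covariate_effect,
                 injected_covariates = injected_covariates,
                 fungal_sign_mode = fungal_sign_mode,
                 integer_richness = integer_richness,
                 seed = as.integer(seed)),
            class = "world_config")
}

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Spatially autocorrelated standard-Gaussian field: white noise convolved with
# a separable Gaussian kernel (circular edges), then re-standardized.
gaussian_field <- function(nr, nc, len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (len > 1) {
    half <- ceiling(3 * len)
    k <- stats::dnorm(seq(-half, half), sd = len)
    k <- k / sum(k)
    z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
  }
  (z - mean(z)) / stats::sd(z)
}

make_zone_grid <- function(cfg) {
  row_band <- pmin(ceiling(seq_len(cfg$nrow) / (cfg$nrow / cfg$n_biomes)), cfg$n_biomes)
  col_tile <- pmin(ceiling(seq_len(cfg$ncol) / (cfg$ncol / cfg$eco_per_biome)), cfg$eco_per_biome)
  eco <- outer(row_band, col_tile, function(b, e) (b - 1L) * cfg$eco_per_biome + e)
  lookup <- data.frame(ecoregion_id = seq_len(cfg$n_biomes * cfg$eco_per_biome))
  lookup$biome_id <- (lookup$ecoregion_id - 1L) %/% cfg$eco_per_biome + 1L
  zone_map(eco, lookup)
}

#' Generate a synthetic world with known ground truth
#'
#' Builds the full input bundle the pipeline consumes: true richness layers
#' per taxon, two noisy study layers with matching uncertainty layers per
#' taxon, a zone map, and eleven covariate layers. The plant-fungal Spearman
#' correlation within each ecoregion converges to the configured `rho` target
#' (Gaussian copula: the fungal latent field mixes the plant latent with an
#' independent field at Pearson weight `2*sin(pi*rho/6)`, the bivariate-normal
#' inversion of the Spearman grade correlation, before the monotone
#' exp-and-round richness link).
#'
#' Study-layer dialects mirror the heterogeneity of published products: plant
#' study layers are raw-scale with IQR-ratio-% and CV-% uncertainty; each
#' fungal guild has one raw-scale CV-% study and one pre-log-transformed study
#' whose uncertainty is an SD on the log scale.
#'
#' @param config a [world_config()].
#' @return A `world_bundle` list: `config`, `zones`, `truth` (per-taxon true
#'   richness matrices plus realized `rho` targets), `taxa` (per taxon:
#'   `studies` as [richness_layer()]s, `uncertainty` as
#'   [uncertainty_layer()]s, `sd_true` noise-SD matrices), `covariates`
#'   (named list of matrices) and `sign_tables`.
#' @export
make_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  with_seed(cfg$seed, {
    nr <- cfg$nrow; nc <- cfg$ncol
    zones <- make_zone_grid(cfg)
    eco <- zones$values
    n_eco <- nrow(zones$lookup)

    covar_specs <- list(
      temperature = c(-10, 30), precipitation = c(100, 3000), ph = c(4, 8.5),
      soc = c(2, 150), nitrogen = c(0.2, 10), phosphorus = c(1, 50),
      elevation = c(0, 4000), am_host_pct = c(0, 100), ecm_host_pct = c(0, 100),
      climate_stability = c(0, 1), human_dev = c(0, 100))
    covar_z <- lapply(covar_specs, function(rng) gaussian_field(nr, nc, cfg$autocorr_length))
    covariates <- mapply(function(z, rng) rng[1] + (rng[2] - rng[1]) * stats::pnorm(z),
                         covar_z, covar_specs, SIMPLIFY = FALSE)

    rho_targets <- function(rho) {
      if (is.character(rho)) {
        if (!rho %in% names(covariates)) stop("unknown covariate for rho derivation: ", rho)
        zm <- tapply(covariates[[rho]], eco, mean)[as.character(seq_len(n_eco))]
        zm01 <- (zm - min(zm)) / max(max(zm) - min(zm), .Machine$double.eps)
        as.numeric(0.8 * zm01)
      } else rho
    }
    rho <- list(am = rho_targets(cfg$rho_am), ecm = rho_targets(cfg$rho_ecm))

    sign_table <- function(rho_e) {
      s <- matrix(1, n_eco, length(cfg$injected_covariates),
                  dimnames = list(NULL, cfg$injected_covariates))
      if (cfg$fungal_sign_mode == "match_rho") s <- s * ifelse(rho_e >= 0, 1, -1)
      s
    }
    signs <- list(plant = matrix(1, n_eco, length(cfg$injected_covariates),
                                 dimnames = list(NULL, cfg$injected_covariates)),
                  am = sign_table(rho$am), ecm = sign_table(rho$ecm))

    inject <- function(sgn_tab) {
      eff <- matrix(0, nr, nc)
      if (cfg$covariate_effect > 0) {
        for (v in cfg$injected_covariates) {
          eff <- eff + cfg$covariate_effect * covar_z[[v]] *
            matrix(sgn_tab[eco, v], nr, nc)
        }
      }
      eff
    }

    A <- gaussian_field(nr, nc, cfg$autocorr_length)        # shared plant latent
    B <- list(am = gaussian_field(nr, nc, cfg$autocorr_length),
              ecm = gaussian_field(nr, nc, cfg$autocorr_length))

    link <- function(latent, mu, sigma) {
      v <- exp(mu + sigma * latent)
      if (cfg$integer_richness) pmax(round(v), 1) else v
    }
    link_pars <- list(plant = c(5.5, 0.6), am = c(4.5, 0.5), ecm = c(4.0, 0.5))

    latent <- list(plant = A + inject(signs$plant))
    for (tx in c("am", "ecm")) {
      r <- 2 * sin(pi * rho[[tx]] / 6)        # Pearson weight hitting the Spearman target
      rcell <- matrix(r[eco], nr, nc)
      latent[[tx]] <- rcell * A + sqrt(1 - rcell^2) * B[[tx]] + inject(signs[[tx]])
    }
    truth <- lapply(names(latent), function(tx)
      link(latent[[tx]], link_pars[[tx]][1], link_pars[[tx]][2]))
    names(truth) <- names(latent)

    het <- stats::pnorm(gaussian_field(nr, nc, cfg$autocorr_length)) + 0.5  # in (0.5, 1.5)

    raw_study <- function(true, dialect, provenance) {
      sd_true <- cfg$noise_cv * het * true
      obs <- true + stats::rnorm(nr * nc) * sd_true
      if (cfg$integer_richness) obs <- pmax(round(obs), 1) else obs <- pmax(obs, 1e-6)
      spread <- switch(dialect,
                       cv_percent = 100 * sd_true / obs,
                       iqr_ratio_percent = 100 * sd_true / (1.35 * obs))
      list(layer = richness_layer(obs, "raw", provenance),
           u = uncertainty_layer(spread, dialect, provenance), sd_true = sd_true)
    }
    logged_study <- function(true, provenance) {
      sd_log <- cfg$noise_sd_log * het
      obs <- log1p(true) + stats::rnorm(nr * nc) * sd_log
      list(layer = richness_layer(obs, "log1p", provenance),
           u = uncertainty_layer(sd_log, "sd", provenance), sd_true = sd_log)
    }

    studies <- list(
      plant = list(raw_study(truth$plant, "iqr_ratio_percent", "plant-study-1"),
                   raw_study(truth$plant, "cv_percent", "plant-study-2")),
      am = list(raw_study(truth$am, "cv_percent", "am-study-1"),
                logged_study(truth$am, "am-study-2")),
      ecm = list(raw_study(truth$ecm, "cv_percent", "ecm-study-1"),
                 logged_study(truth$ecm, "ecm-study-2")))
    taxa <- lapply(studies, function(ss) list(
      studies = lapply(ss, `[[`, "layer"),
      uncertainty = lapply(ss, `[[`, "u"),
      sd_true = lapply(ss, `[[`, "sd_true")))

    structure(list(config = cfg, zones = zones,
                   truth = c(truth, list(rho = rho)),
                   taxa = taxa, covariates = covariates, sign_tables = signs),
              class = "world_bundle")
  })
}

#' @export
print.world_bundle <- function(x, ...) {
  cat(sprintf("<world_bundle> %d x %d cells, %d ecoregions in %d biomes, seed %d\n",
              x$config$nrow, x$config$ncol, nrow(x$zones$lookup),
              x$config$n_biomes, x$config$seed))
  cat(sprintf("  taxa: %s; covariates: %d; noise_cv = %g\n",
              paste(names(x$taxa), collapse = ", "), length(x$covariates),
              x$config$noise_cv))
  invisible(x)
}

#' Hand-enumerable test fixtures
#'
#' Small deterministic worlds (at most 100 cells) whose downstream outputs are
#' documented constants:
#' * `"tiny-4x5"` — 20 cells, one zone, plant richness exactly 1..20 and
#'   fungal richness a fixed monotone-discordant permutation; uncertainty
#'   spreads are the distinct values 1..20 (study 1) and 20..1 (study 2).
#' * `"two-zone-opposite-signs"` — 10x10 grid, two ecoregions; in zone 1 plant
#'   and fungal richness both increase with temperature, in zone 2 plant
#'   increases while fungal decreases.
#' * `"hotspot-known-overlap"` — 10x10 grid with distinct richness 1..100 per
#'   taxon arranged so the plant and fungal top-5% hotspot sets (q = 95) share
#'   exactly 2 of 5 cells.
#'
#' @param name fixture id.
#' @return A `world_bundle` (studies are noise-free copies of the truth, so
#'   masks retain everything).
#' @export
make_fixture <- function(name = c("tiny-4x5", "two-zone-opposite-signs",
                                  "hotspot-known-overlap")) {
  name <- match.arg(name)
  bundle_from <- function(plant, fungal, zones, covariates,
                          u_plant = NULL, u_fungal = NULL) {
    mk_taxon <- function(m, u, tag) {
      u1 <- if (is.null(u)) matrix(0, nrow(m), ncol(m)) else u[[1]]
      u2 <- if (is.null(u)) matrix(0, nrow(m), ncol(m)) else u[[2]]
      list(studies = list(richness_layer(m, "raw", paste0(tag, "-study-1")),
                          richness_layer(m, "raw", paste0(tag, "-study-2"))),
           uncertainty = list(uncertainty_layer(u1, "cv_percent", paste0(tag, "-study-1")),
                              uncertainty_layer(u2, "cv_percent", paste0(tag, "-study-2"))),
           sd_true = list(matrix(0, nrow(m), ncol(m)), matrix(0, nrow(m), ncol(m))))
    }
    structure(list(config = NULL, zones = zones,
                   truth = list(plant = plant, am = fungal, ecm = fungal, rho = NULL),
                   taxa = list(plant = mk_taxon(plant, u_plant, "plant"),
                               am = mk_taxon(fungal, u_fungal, "am"),
                               ecm = mk_taxon(fungal, u_fungal, "ecm")),
                   covariates = covariates, sign_tables = NULL),
              class = "world_bundle")
  }

  if (name == "tiny-4x5") {
    plant <- matrix(1:20, 4, 5)
    fungal <- matrix(c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L, 10L, 9L, 12L, 11L,
                       14L, 13L, 16L, 15L, 18L, 17L, 20L, 19L), 4, 5)
    zones <- zone_map(matrix(1L, 4, 5), data.frame(ecoregion_id = 1L, biome_id = 1L))
    covs <- list(temperature = matrix(seq(0, 19), 4, 5))
    return(bundle_from(plant, fungal, zones, covs,
                       u_plant = list(matrix(1:20, 4, 5), matrix(20:1, 4, 5)),
                       u_fungal = list(matrix(1:20, 4, 5), matrix(20:1, 4, 5))))
  }

  if (name == "two-zone-opposite-signs") {
    nr <- 10; nc <- 10
    eco <- matrix(rep(c(1L, 2L), each = nr * nc / 2), nr, nc)  # left/right halves
    zones <- zone_map(eco, data.frame(ecoregion_id = 1:2, biome_id = c(1L, 1L)))
    temp <- outer(seq_len(nr) * 0.13, seq_len(nc), `+`)        # 100 unique values
    host <- outer(seq_len(nr), seq_len(nc) * 0.07, `+`)        # independent gradient
    idx <- seq_len(nr * nc)
    wiggle_p <- matrix(sin(idx), nr, nc) * 3                   # taxon-specific
    wiggle_f <- matrix(cos(1.7 * idx), nr, nc) * 3             # deterministic "noise"
    plant <- 50 + 5 * temp + 0.3 * host + wiggle_p
    fungal <- 60 + 4 * temp * (eco == 1L) - 4 * temp * (eco == 2L) +
      0.2 * host + wiggle_f
    covs <- list(temperature = temp, am_host_pct = host, ecm_host_pct = host)
    return(bundle_from(plant, fungal, zones, covs))
  }

  # hotspot-known-overlap: distinct values 1..100; with q = 95 the threshold is
  # 95.05 (type-7), so hotspot cells are those valued 96..100. Plant hotspots
  # sit at cells 1..5, fungal hotspots at cells 4..8: overlap is exactly {4, 5}.
  plant <- matrix(100:1, 10, 10)            # cell 1 has 100, ..., cell 5 has 96
  fungal_vals <- integer(100)
  fungal_vals[4:8] <- 100:96                # fungal top-5 at cells 4..8
  fungal_vals[-(4:8)] <- 95:1
  fungal <- matrix(fungal_vals, 10, 10)
  zones <- zone_map(matrix(1L, 10, 10), data.frame(ecoregion_id = 1L, biome_id = 1L))
  covs <- list(temperature = matrix(seq_len(100) / 10, 10, 10))
  bundle_from(plant, fungal, zones, covs)
}

#' Synthetic world with a known hotspot-overlap fraction
#'
#' Constructs tie-free plant and fungal richness surfaces whose top-(100-q)%
#' hotspot cell sets overlap in a chosen fraction of cells, for validating the
#' hotspot-overlap accounting at scale.
#'
#' @param nrow,ncol grid dimensions.
#' @param overlap_frac target fraction of the fungal hotspot set shared with
#'   the plant hotspot set.
#' @param q hotspot percentile.
#' @param seed RNG seed (placement of hotspot cells).
#' @return A list with raw [richness_layer()]s `plant` and `fungal`, an
#'   all-true [cell_mask()] `mask`, the realized `expected_overlap_percent`,
#'   and `q`.
#' @export
make_overlap_world <- function(nrow = 300, ncol = 300, overlap_frac = 0.4,
                               q = 95, seed = 1L) {
  stopifnot(overlap_frac >= 0, overlap_frac <= 1)
  with_seed(seed, {
    n <- nrow * ncol
    thr <- stats::quantile(seq_len(n), q / 100, type = 7, names = FALSE)
    k <- sum(seq_len(n) > thr)               # hotspot cells under strict > rule
    cells <- sample.int(n)                   # random placement
    plant_hot <- cells[seq_len(k)]
    n_shared <- round(overlap_frac * k)
    fungal_hot <- c(plant_hot[seq_len(n_shared)],
                    cells[(k + 1):(2 * k - n_shared)])
    assign_vals <- function(hot) {
      v <- numeric(n)
      v[hot] <- sample(seq(n - k + 1, n))
      v[-hot] <- sample(seq_len(n - k))
      matrix(v, nrow, ncol)
    }
    list(plant = richness_layer(assign_vals(plant_hot), "raw", "plant-synthetic"),
         fungal = richness_layer(assign_vals(fungal_hot), "raw", "fungal-synthetic"),
         mask = cell_mask(matrix(TRUE, nrow, ncol), "all"),
         expected_overlap_percent = 100 * n_shared / k, q = q)
  })
}
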