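default_env_covariates <- c("temperature", "precipitation", "ph", "soc",
                            "nitrogen", "phosphorus", "elevation")

#' Global additive model of fungal on plant richness plus environment
#'
#' Penalized-spline additive model (thin-plate splines, `k` basis functions
#' per term, Gaussian family, REML) of fungal richness as a function of plant
#' richness and environmental covariates, fitted to a global cell sample. The
#' handle supports deviance queries and term-wise partial predictions.
#'
#' @param sample a cell sample data.frame with `fungal`, `plant`, covariates.
#' @param covariates covariate column names.
#' @param k basis dimension per smooth term.
#' @param include_plant drop the plant-richness term to obtain the reduced
#'   model of the deviance partition.
#' @return A `driver_fit`: list with the `mgcv` fit, `deviance`,
#'   `null_deviance`, and metadata.
#' @export
fit_global_driver_model <- function(sample, covariates = default_env_covariates,
                                    k = 3, include_plant = TRUE) {
  stopifnot(all(covariates %in% names(sample)))
  terms <- c(if (include_plant) "plant", covariates)
  if (nrow(sample) < 10 * length(terms)) stop("need at least 10 observations per smooth term")
  X <- as.matrix(sample[, terms, drop = FALSE])
  cc <- suppressWarnings(stats::cor(X))
  diag(cc) <- 0
  if (any(abs(cc) > 0.999, na.rm = TRUE)) stop("collinear design: near-duplicate covariates")
  fml <- stats::reformulate(sprintf("s(%s, k = %d, bs = 'tp')", terms, k),
                            response = "fungal")
  # REML step failures on degenerate inputs (e.g. zero residual variance) are
  # routine; convergence is reported in the handle rather than as a condition
  fit <- suppressWarnings(
    mgcv::gam(fml, data = sample, family = stats::gaussian(), method = "REML"))
  if (!fit$converged) warning("smooth model did not converge")
  structure(list(fit = fit, deviance = fit$deviance,
                 null_deviance = fit$null.deviance, terms = terms, k = k,
                 n = nrow(sample), converged = fit$converged),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("<driver_fit> fungal ~ %s (k = %d, n = %d)\n",
              paste(x$terms, collapse = " + "), x$k, x$n))
  cat(sprintf("  deviance %.4g (null %.4g), explained %.1f%%\n", x$deviance,
              x$null_deviance, 100 * (1 - x$deviance / x$null_deviance)))
  invisible(x)
}

dev_of <- function(x) {
  if (inherits(x, "driver_fit")) x$deviance
  else if (inherits(x, "gam") || inherits(x, "lm")) stats::deviance(x)
  else as.numeric(x)
}

#' Partial percent deviance explained by plant richness
#'
#' The share of the intercept-only deviance in fungal richness removed by the
#' plant-richness term on top of the environmental covariates:
#' `100 * (deviance(reduced) - deviance(full)) / deviance(null)`, where the
#' reduced model omits plant richness and the null model is intercept-only.
#'
#' @param full,reduced,null fitted models (`driver_fit`/`gam`) or deviances.
#' @return percent in \[0, 100\]. A reduced deviance below the full deviance
#'   (possible with penalized non-nested refits) is flagged with a warning and
#'   clipped to 0.
#' @export
partial_deviance_explained <- function(full, reduced, null) {
  df <- dev_of(full); dr <- dev_of(reduced); dn <- dev_of(null)
  if (dn == 0) stop("null deviance is zero")
  if (dr < df) {
    warning("reduced-model deviance below full-model deviance; clipping to 0")
    return(0)
  }
  100 * (dr - df) / dn
}

#' Deviance partition for plant richness in the global model
#'
#' Fits the full, reduced (no plant term) and null models to one sample and
#' returns the deviance partition.
#'
#' @inheritParams fit_global_driver_model
#' @return One-row data.frame: `dev_full`, `dev_reduced`, `dev_null`,
#'   `partial_pct`, `n`.
#' @export
deviance_partition <- function(sample, covariates = default_env_covariates, k = 3) {
  full <- fit_global_driver_model(sample, covariates, k, include_plant = TRUE)
  reduced <- fit_global_driver_model(sample, covariates, k, include_plant = FALSE)
  dev_null <- full$null_deviance
  data.frame(dev_full = full$deviance, dev_reduced = reduced$deviance,
             dev_null = dev_null,
             partial_pct = partial_deviance_explained(full, reduced, dev_null),
             n = nrow(sample))
}

#' Per-ecoregion driver table for the correlation-driver model
#'
#' Assembles, for one fungal guild, the ecoregion-level table of Spearman
#' correlations and covariate means computed from exactly the sampled cells
#' that produced each correlation.
#'
#' @param scan a [scan_all_scales()] result.
#' @param fungal_taxon `"am"` or `"ecm"`.
#' @return data.frame with `zone_id`, `biome_id`, `rho`, `n`, `host_pct` (the
#'   guild's own host-biomass %), covariate means, and consensus `plant_mean`,
#'   `fungal_mean`.
#' @export
zone_driver_table <- function(scan, fungal_taxon = c("am", "ecm")) {
  fungal_taxon <- match.arg(fungal_taxon)
  host_col <- paste0(fungal_taxon, "_host_pct")
  samples <- scan$samples[[fungal_taxon]]$ecoregion$samples
  corr <- scan$correlations
  corr <- corr[corr$scale == "ecoregion" &
                 corr$taxon_pair == paste0("plant-", fungal_taxon), ]
  rows <- lapply(samples, function(df) {
    zid <- attr(df, "zone_id")
    r <- corr[corr$zone_id == zid, ]
    if (!nrow(r)) return(NULL)
    means <- colMeans(df[, setdiff(names(df), c("cell", "row", "col",
                                                "ecoregion_id", "biome_id"))])
    out <- data.frame(zone_id = zid, biome_id = biome_of(scan$comparisons[[fungal_taxon]]$zones, zid),
                      rho = r$rho, n = r$n)
    out$host_pct <- means[[host_col]]
    for (nm in names(means)) out[[nm]] <- means[[nm]]
    names(out)[names(out) == "plant"] <- "plant_mean"
    names(out)[names(out) == "fungal"] <- "fungal_mean"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Additive model of zonal correlations on hypothesized drivers
#'
#' Models ecoregion-level plant-fungal Spearman correlations as smooth
#' functions of host-plant biomass %, climate-stability index and human
#' development % (the three hypothesized drivers), with environmental and
#' richness covariate means to absorb other variation. Thin-plate splines,
#' `k` basis functions, Gaussian family, REML.
#'
#' @param zone_table output of [zone_driver_table()].
#' @param k basis dimension per term.
#' @param min_zones minimum ecoregions required.
#' @param drivers,covariates term sets (columns of `zone_table`).
#' @return List of class `correlation_driver_fit`: `fit` (mgcv), `partials`
#'   (per-term partial effects with standard errors and partial residuals),
#'   `deviance_explained` (percent), `n_zones`.
#' @export
fit_correlation_driver_model <- function(zone_table, k = 4, min_zones = 50,
                                         drivers = c("host_pct", "climate_stability", "human_dev"),
                                         covariates = c(default_env_covariates,
                                                        "plant_mean", "fungal_mean")) {
  terms <- c(drivers, covariates)
  stopifnot(all(terms %in% names(zone_table)))
  if (nrow(zone_table) < min_zones) stop("insufficient zones for the correlation-driver model")
  X <- as.matrix(zone_table[, terms])
  cc <- suppressWarnings(stats::cor(X))
  cc[!is.finite(cc)] <- 1
  diag(cc) <- 0
  if (any(abs(cc) > 0.999)) stop("perfect collinearity among driver-model covariates")
  fml <- stats::reformulate(sprintf("s(%s, k = %d, bs = 'tp')", terms, k),
                            response = "rho")
  fit <- mgcv::gam(fml, data = zone_table, family = stats::gaussian(),
                   method = "REML")
  tp <- stats::predict(fit, type = "terms", se.fit = TRUE)
  res <- stats::residuals(fit)
  partials <- do.call(rbind, lapply(seq_along(terms), function(i) {
    col <- grep(paste0("\\(", terms[i], ","), colnames(tp$fit))
    if (!length(col)) col <- i
    data.frame(term = terms[i], x = zone_table[[terms[i]]],
               effect = tp$fit[, col], se = tp$se.fit[, col],
               partial_residual = tp$fit[, col] + res)
  }))
  structure(list(fit = fit, partials = partials,
                 deviance_explained = 100 * (1 - fit$deviance / fit$null.deviance),
                 n_zones = nrow(zone_table), terms = terms, k = k),
            class = "correlation_driver_fit")
}

#' @export
print.correlation_driver_fit <- function(x, ...) {
  cat(sprintf("<correlation_driver_fit> rho ~ %d smooth terms (k = %d), %d zones\n",
              length(x$terms), x$k, x$n_zones))
  cat(sprintf("  deviance explained %.1f%%\n", x$deviance_explained))
  invisible(x)
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("degenerate scaling: constant variable")
  (x - r[1]) / (r[2] - r[1])
}

#' Paired plant/fungal linear responses to an environmental gradient
#'
#' Within one zone's cell sample, fits two linear models on \[0, 1\]-scaled
#' variables — plant richness and fungal richness each regressed on the
#' environmental variable, with the other guild's richness and host-biomass %
#' as covariates to absorb host-symbiont coupling — and extracts the
#' environmental coefficients. Zones are usable only with at least `min_cells`
#' cells and at least 10 unique values of the environmental variable.
#'
#' @param sample a zone cell sample.
#' @param env_var environmental column name.
#' @param host_col host-biomass column name (e.g. `"am_host_pct"`).
#' @param min_cells minimum cells.
#' @return One-row data.frame (`sign_pair`): `zone_id`, `env_var`,
#'   `plant_est`, `plant_p`, `fungal_est`, `fungal_p`, `rho`, `n`.
#' @export
fit_zone_sign_models <- function(sample, env_var, host_col = "am_host_pct",
                                 min_cells = 100) {
  stopifnot(all(c(env_var, host_col, "plant", "fungal") %in% names(sample)))
  if (nrow(sample) < min_cells) stop("zone has fewer than min_cells cells")
  if (length(unique(sample[[env_var]])) < 10) {
    stop("environmental variable has fewer than 10 unique values")
  }
  rho <- spearman_correlation(sample)$rho
  d <- data.frame(plant = minmax01(sample$plant), fungal = minmax01(sample$fungal),
                  env = minmax01(sample[[env_var]]),
                  host = minmax01(sample[[host_col]]))
  coef_of <- function(fml) {
    fit <- stats::lm(fml, data = d)
    sm <- stats::coef(summary(fit))
    if (!"env" %in% rownames(sm)) stop("singular design: environmental term dropped")
    sm["env", c("Estimate", "Pr(>|t|)")]
  }
  pc <- coef_of(plant ~ env + fungal + host)
  fc <- coef_of(fungal ~ env + plant + host)
  data.frame(zone_id = attr(sample, "zone_id") %||% NA_integer_, env_var = env_var,
             plant_est = unname(pc[1]), plant_p = unname(pc[2]),
             fungal_est = unname(fc[1]), fungal_p = unname(fc[2]),
             rho = rho, n = nrow(sample))
}

#' Sign-concordance chi-squared test
#'
#' Cross-tabulates, across zones, whether the plant and fungal environmental
#' coefficients share a sign against whether the zone's plant-fungal
#' correlation is positive, and tests independence with a two-sided Pearson
#' chi-squared test. Coefficient pairs where either p-value is at or above
#' `alpha` are excluded as unreliable; the filter only drops zones, never
#' alters recorded signs. The uncorrected statistic is primary; the
#' Yates-corrected value is reported in diagnostics.
#'
#' @param pairs data.frame of sign pairs from [fit_zone_sign_models()].
#' @param alpha coefficient p-value filter.
#' @return `concordance_result`: `table` (2x2 counts), `statistic`, `p`,
#'   `statistic_corrected`, `p_corrected`, `n_used`, `n_excluded`,
#'   `expected_lt5` flag.
#' @export
sign_concordance_test <- function(pairs, alpha = 0.05) {
  keep <- pairs$plant_p < alpha & pairs$fungal_p < alpha & pairs$rho != 0
  used <- pairs[keep, , drop = FALSE]
  if (!nrow(used)) stop("empty table after p-value filtering")
  agree <- factor(sign(used$plant_est) == sign(used$fungal_est),
                  levels = c(TRUE, FALSE), labels = c("same_sign", "opposite_sign"))
  pos <- factor(used$rho > 0, levels = c(TRUE, FALSE),
                labels = c("rho_positive", "rho_negative"))
  tab <- table(agree, pos)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table after filtering (empty row or column)")
  }
  raw <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  corr <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  structure(list(table = unclass(tab), statistic = unname(raw$statistic),
                 p = raw$p.value, statistic_corrected = unname(corr$statistic),
                 p_corrected = corr$p.value, n_used = nrow(used),
                 n_excluded = nrow(pairs) - nrow(used),
                 expected_lt5 = any(raw$expected < 5)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  print(x$table)
  cat(sprintf("  X-squared = %.4g, p = %.3g (uncorrected; Yates: %.4g, p = %.3g)\n",
              x$statistic, x$p, x$statistic_corrected, x$p_corrected))
  cat(sprintf("  zones used = %d, excluded by p filter = %d%s\n", x$n_used,
              x$n_excluded,
              if (x$expected_lt5) "; warning: expected counts < 5" else ""))
  invisible(x)
}

#' Per-zone covariate collinearity
#'
#' Maximum absolute pairwise Pearson correlation among the model covariates
#' within each zone's cell sample.
#'
#' @param samples named list of zone cell samples.
#' @param covariates covariate columns to screen.
#' @return data.frame: `zone_id`, `max_abs_cor`.
#' @export
zone_collinearity <- function(samples, covariates) {
  out <- lapply(samples, function(df) {
    X <- as.matrix(df[, covariates, drop = FALSE])
    cc <- suppressWarnings(stats::cor(X))
    diag(cc) <- 0
    data.frame(zone_id = attr(df, "zone_id"),
               max_abs_cor = max(abs(cc), na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Collinearity sensitivity of the sign-concordance test
#'
#' Re-runs [sign_concordance_test()] after dropping zones whose within-zone
#' covariate collinearity exceeds each cutoff.
#'
#' @param pairs sign-pair table.
#' @param zone_cor output of [zone_collinearity()].
#' @param cutoffs absolute-correlation cutoffs.
#' @param alpha coefficient p-value filter.
#' @return Named list (one element per cutoff): `result`
#'   (`concordance_result`), `dropped_fraction`, `n_zones`.
#' @export
collinearity_sensitivity <- function(pairs, zone_cor, cutoffs = c(0.85, 0.80),
                                     alpha = 0.05) {
  out <- list()
  for (ct in cutoffs) {
    bad <- zone_cor$zone_id[zone_cor$max_abs_cor > ct]
    keep <- !(pairs$zone_id %in% bad)
    out[[as.character(ct)]] <- list(
      result = sign_concordance_test(pairs[keep, , drop = FALSE], alpha = alpha),
      dropped_fraction = mean(!keep), n_zones = sum(keep))
  }
  out
}

#' Shapiro-Wilk normality screen of zonal richness samples
#'
#' Diagnostic (non-blocking) flagging of zones whose plant or fungal richness
#' values look non-normal. Samples above 5000 cells are subsampled (the test's
#' validity range is 3..5000); constant vectors are reported as not testable.
#'
#' @param samples named list of zone cell samples.
#' @param responses columns to screen.
#' @param seed subsampling seed.
#' @return data.frame: `zone_id`, `response`, `n`, `p`, `flagged`, `note`.
#' @export
normality_screen <- function(samples, responses = c("plant", "fungal"), seed = 1L) {
  rows <- list()
  for (df in samples) {
    for (resp in responses) {
      x <- df[[resp]]
      x <- x[!is.na(x)]
      note <- "ok"; p <- NA_real_
      if (length(x) < 3 || length(unique(x)) < 2) {
        note <- "not testable (too few or constant values)"
      } else {
        if (length(x) > 5000) {
          x <- with_seed(seed, sample(x, 5000))
        }
        p <- stats::shapiro.test(x)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        zone_id = attr(df, "zone_id") %||% NA_integer_, response = resp,
        n = length(x), p = p, flagged = !is.na(p) && p < 0.05, note = note)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
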