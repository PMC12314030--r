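#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the synthetic-world
#' configuration,
#' sampling quotas, mask and hotspot percentiles, smoother basis sizes,
#' Monte-Carlo settings and seeds. Defaults follow the published analysis
#' protocol (10,000 global and per-biome cells, up to 1000 per ecoregion with
#' a 100-cell minimum, 95th-percentile masks and hotspots, k = 3 for richness
#' models, k = 4 for the correlation-driver model, 1000 Monte-Carlo
#' iterations, coefficient filter at p < 0.05).
#'
#' @param world a [world_config()] describing the synthetic inputs.
#' @param quota_global,quota_biome,quota_ecoregion sampling quotas per scale.
#' @param min_cells minimum retained cells for a zone to be analysed.
#' @param q uncertainty/disagreement mask percentile.
#' @param hotspot_q hotspot percentile.
#' @param k_global,k_driver smooth basis dimensions.
#' @param min_zones minimum ecoregions for the correlation-driver model.
#' @param mc_iterations Monte-Carlo iterations.
#' @param env_vars environmental variables for the sign-concordance analysis.
#' @param alpha coefficient p-value filter.
#' @param collinearity_cutoffs cutoffs for the sensitivity re-runs.
#' @param seed master seed for sampling and Monte-Carlo.
#' @param out_dir output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(),
                            quota_global = 10000, quota_biome = 10000,
                            quota_ecoregion = 1000, min_cells = 100,
                            q = 95, hotspot_q = 95,
                            k_global = 3, k_driver = 4, min_zones = 50,
                            mc_iterations = 1000,
                            env_vars = c("temperature", "precipitation", "ph"),
                            alpha = 0.05, collinearity_cutoffs = c(0.85, 0.80),
                            seed = 1L, out_dir = "divermap-out") {
  stopifnot(inherits(world, "world_config"))
  if (min(quota_global, quota_biome, quota_ecoregion) <= 0) {
    stop("sampling quotas must be positive")
  }
  if (q <= 0 || q >= 100 || hotspot_q <= 0 || hotspot_q >= 100) {
    stop("percentiles must lie in (0, 100)")
  }
  if (mc_iterations < 2) stop("mc_iterations must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_cells < 3) stop("min_cells must be at least 3")
  structure(list(world = world, quota_global = quota_global,
                 quota_biome = quota_biome, quota_ecoregion = quota_ecoregion,
                 min_cells = min_cells, q = q, hotspot_q = hotspot_q,
                 k_global = k_global, k_driver = k_driver,
                 min_zones = min_zones, mc_iterations = mc_iterations,
                 env_vars = env_vars, alpha = alpha,
                 collinearity_cutoffs = collinearity_cutoffs,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration
#'
#' File round-trip of a [pipeline_config()] (the nested [world_config()]
#' included). JSON (`.json`, the default) is lossless for all numeric fields;
#' YAML (`.yaml`/`.yml`) is human-friendlier but stores doubles at 15
#' significant digits.
#'
#' @param config a `pipeline_config`.
#' @param path config file path; the extension selects the format.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$world <- unclass(x$world)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  w <- x$world
  world <- do.call(world_config, w)
  x$world <- NULL
  do.call(pipeline_config, c(list(world = world), x))
}

# hash of the analysis-relevant configuration; the output directory is
# excluded so reruns into different directories compare equal
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- config
  x$out_dir <- NULL
  jsonlite::write_json(lapply(unclass(x), unclass), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes every stage in protocol order — simulate, harmonize, scan,
#' drivers, Monte-Carlo, hotspots — writing tidy CSV/JSON outputs to
#' `config$out_dir` and returning a manifest. All randomness descends from
#' `config$seed` (and the world's own seed), so a rerun with the same
#' configuration reproduces every CSV byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest` list: `config_hash`, `files` (named paths),
#'   `results` (the in-memory stage outputs), `warnings`, `elapsed` (seconds
#'   per stage), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  files <- list(); elapsed <- c(); notes <- character()
  results <- list()
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(df, name) {
    write_result_csv(df, out(name), hash)
    files[[name]] <<- out(name)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    elapsed[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  world <- stage("simulate", make_world(config$world))

  scan <- stage("scan", {
    s <- scan_all_scales(world,
                         quotas = list(global = config$quota_global,
                                       biome = config$quota_biome,
                                       ecoregion = config$quota_ecoregion),
                         min_cells = config$min_cells, seed = config$seed,
                         q = config$q)
    emit(s$correlations, "correlations.csv")
    if (nrow(s$excluded)) emit(s$excluded, "excluded_zones.csv")
    ret <- do.call(rbind, lapply(names(s$comparisons), function(tx) {
      cbind(taxon_pair = paste0("plant-", tx),
            retained_fraction(s$comparisons[[tx]]$mask, world$zones))
    }))
    emit(ret, "retained_fraction.csv")
    s
  })
  results$scan <- scan

  results$smooth <- stage("smooth", {
    rows <- list(); comp_rows <- list()
    for (tx in names(scan$samples)) {
      fits <- lapply(scan$samples[[tx]]$ecoregion$samples, function(df) {
        tryCatch(fit_richness_smooth(df, k = config$k_global),
                 error = function(e) NULL)
      })
      fits <- do.call(rbind, fits)
      if (!is.null(fits)) {
        fits <- cbind(taxon_pair = paste0("plant-", tx), fits)
        rows[[tx]] <- fits
        ec <- scan$correlations[scan$correlations$scale == "ecoregion" &
                                  scan$correlations$taxon_pair == paste0("plant-", tx), ]
        cm <- tryCatch(compare_metrics(ec, fits), error = function(e) NULL)
        if (!is.null(cm)) comp_rows[[tx]] <- cbind(taxon_pair = paste0("plant-", tx), cm)
      }
    }
    fits <- do.call(rbind, rows)
    emit(fits, "smooth_fits.csv")
    if (length(comp_rows)) emit(do.call(rbind, comp_rows), "metric_comparison.csv")
    tests <- biome_sign_test(scan$correlations)
    emit(tests, "biome_tests.csv")
    list(fits = fits, biome_tests = tests)
  })

  results$drivers <- stage("drivers", {
    partition <- do.call(rbind, lapply(names(scan$samples), function(tx) {
      g <- scan$samples[[tx]]$global$samples[["0"]]
      cbind(taxon_pair = paste0("plant-", tx), deviance_partition(g, k = config$k_global))
    }))
    emit(partition, "deviance_partition.csv")

    driver_fits <- list(); partials <- list()
    for (tx in names(scan$samples)) {
      zt <- zone_driver_table(scan, tx)
      fit <- tryCatch(fit_correlation_driver_model(zt, k = config$k_driver,
                                                   min_zones = config$min_zones),
                      error = function(e) { notes <<- c(notes, sprintf(
                        "correlation-driver model skipped for %s: %s", tx,
                        conditionMessage(e))); NULL })
      if (!is.null(fit)) {
        driver_fits[[tx]] <- fit
        partials[[tx]] <- cbind(taxon_pair = paste0("plant-", tx), fit$partials)
      }
    }
    if (length(partials)) emit(do.call(rbind, partials), "driver_partials.csv")

    pairs <- list(); conc <- list(); colsens <- list(); screens <- list()
    for (tx in names(scan$samples)) {
      samples <- scan$samples[[tx]]$ecoregion$samples
      host_col <- paste0(tx, "_host_pct")
      for (ev in config$env_vars) {
        sp <- do.call(rbind, lapply(samples, function(df) {
          tryCatch(fit_zone_sign_models(df, ev, host_col = host_col,
                                        min_cells = config$min_cells),
                   error = function(e) NULL)
        }))
        if (is.null(sp)) next
        sp <- cbind(taxon_pair = paste0("plant-", tx), sp)
        pairs[[paste(tx, ev)]] <- sp
        key <- paste0(tx, ".", ev)
        conc[[key]] <- tryCatch({
          r <- sign_concordance_test(sp, alpha = config$alpha)
          zc <- zone_collinearity(samples, c(ev, "plant", "fungal", host_col))
          sens <- tryCatch(collinearity_sensitivity(sp, zc,
                                                    config$collinearity_cutoffs,
                                                    config$alpha),
                           error = function(e) NULL)
          list(counts = r$table, statistic = r$statistic, p = r$p,
               statistic_corrected = r$statistic_corrected,
               p_corrected = r$p_corrected, n_used = r$n_used,
               n_excluded = r$n_excluded, expected_lt5 = r$expected_lt5,
               sensitivity = lapply(sens, function(s) list(
                 statistic = s$result$statistic, p = s$result$p,
                 dropped_fraction = s$dropped_fraction, n_zones = s$n_zones)))
        }, error = function(e) list(error = conditionMessage(e)))
      }
      screens[[tx]] <- cbind(taxon_pair = paste0("plant-", tx),
                             normality_screen(samples, seed = config$seed))
    }
    if (length(pairs)) emit(do.call(rbind, pairs), "sign_pairs.csv")
    jsonlite::write_json(conc, out("concordance.json"), auto_unbox = TRUE,
                         digits = NA)
    files[["concordance.json"]] <- out("concordance.json")
    emit(do.call(rbind, screens), "normality_screen.csv")
    list(partition = partition, driver_fits = driver_fits, pairs = pairs,
         concordance = conc)
  })

  results$mc <- stage("mc", {
    rows <- lapply(names(scan$samples), function(tx) {
      g <- scan$samples[[tx]]$global$samples[["0"]]
      ref <- scan$correlations[scan$correlations$scale == "global" &
                                 scan$correlations$taxon_pair == paste0("plant-", tx), "rho"]
      inputs <- prepare_mc_inputs(world, tx, g)
      dist <- perturb_and_correlate(inputs, iterations = config$mc_iterations,
                                    seed = config$seed)
      mc_summary(dist, ref)
    })
    rows <- do.call(rbind, rows)
    emit(rows, "mc_summary.csv")
    rows
  })

  results$hotspots <- stage("hotspots", {
    rows <- list(); host_rows <- list()
    for (tx in names(scan$comparisons)) {
      comp <- scan$comparisons[[tx]]
      mask <- comp$mask
      union_of <- function(layers) Reduce(union_hotspots,
        lapply(layers, hotspot_mask, mask = mask, q = config$hotspot_q))
      fh <- union_of(world$taxa[[tx]]$studies)
      ph <- union_of(world$taxa$plant$studies)
      glob <- overlap_summary(fh, ph, world$zones)
      glob$mode <- "crosstab"
      within <- biome_hotspot_overlap(world$taxa[[tx]]$studies,
                                      world$taxa$plant$studies, mask,
                                      world$zones, q = config$hotspot_q)
      if (!is.null(within) && nrow(within)) within$mode <- "within"
      res <- rbind(glob, within)
      res <- cbind(taxon_pair = paste0("plant-", tx), res)
      rows[[tx]] <- res

      host <- world$covariates[[paste0(tx, "_host_pct")]]
      bio <- matrix(biome_of(world$zones, world$zones$values), nrow(host))
      hm <- stats::aggregate(list(host_pct = host[mask$values]),
                             by = list(biome_id = bio[mask$values]), FUN = mean)
      hv <- tryCatch(cbind(taxon_pair = paste0("plant-", tx),
                           overlap_vs_host_prevalence(
                             res[res$scope == "biome" & res$mode == "within", ], hm)),
                     error = function(e) NULL)
      if (!is.null(hv)) host_rows[[tx]] <- hv
    }
    res <- do.call(rbind, rows)
    emit(res, "hotspot_overlap.csv")
    if (length(host_rows)) emit(do.call(rbind, host_rows), "hotspot_host_check.csv")
    res
  })

  manifest <- structure(list(config_hash = hash, files = files,
                             results = results, warnings = notes,
                             elapsed = elapsed),
                        class = "run_manifest")
  jsonlite::write_json(list(config_hash = hash,
                            files = lapply(files, identity),
                            warnings = notes, elapsed = as.list(elapsed)),
                       out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s\n", substr(x$config_hash, 1, 8)))
  cat(sprintf("  %d output files, %d warnings\n", length(x$files),
              length(x$warnings)))
  for (nm in names(x$elapsed)) cat(sprintf("  %-10s %6.1fs\n", nm, x$elapsed[[nm]]))
  invisible(x)
}
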