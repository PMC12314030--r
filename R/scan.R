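#' Stratified random cell sampling
#'
#' Draws up to `quota` distinct mask-retained cells uniformly without
#' replacement, globally or within each biome or ecoregion, and extracts
#' consensus plant/fungal richness and covariate values at the sampled cells.
#' Zones with fewer than `min_cells` retained cells are excluded and reported.
#' One master seed spawns a deterministic substream per zone, so a zone's
#' sample does not depend on the order zones are visited.
#'
#' @param comp a `comparison` from [build_comparison()].
#' @param scale `"global"`, `"biome"`, or `"ecoregion"`.
#' @param quota maximum cells per zone (global counts as one zone).
#' @param min_cells minimum retained cells for a zone to be analysed.
#' @param seed master seed.
#' @return A list with `samples` (named list of data.frames, one per included
#'   zone, with columns `cell`, `row`, `col`, `ecoregion_id`, `biome_id`,
#'   `plant`, `fungal`, and one column per covariate; sampling metadata in
#'   attributes `scale`, `zone_id`, `requested_n`, `achieved_n`, `seed`) and
#'   `excluded` (data.frame of zones dropped by the `min_cells` rule).
#' @export
sample_cells <- function(comp, scale = c("global", "biome", "ecoregion"),
                         quota, min_cells = 100, seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(inherits(comp, "comparison"), quota > 0)
  keep <- comp$mask$values & !is.na(comp$plant$values) & !is.na(comp$fungal$values)
  if (!any(keep)) stop("no masked cells available anywhere")
  eco <- comp$zones$values
  zone_ids_cell <- switch(scale,
    global = ifelse(keep, 0L, NA_integer_),
    biome = matrix(biome_of(comp$zones, eco), nrow(eco)),
    ecoregion = eco)
  zone_ids_cell[!keep] <- NA_integer_
  zone_levels <- sort(unique(zone_ids_cell[!is.na(zone_ids_cell)]))

  samples <- list()
  excluded <- data.frame(zone_id = integer(), n_masked = integer())
  for (zid in zone_levels) {
    cells <- which(zone_ids_cell == zid)
    if (length(cells) < min_cells) {
      excluded <- rbind(excluded, data.frame(zone_id = zid, n_masked = length(cells)))
      next
    }
    zseed <- (seed + 7919 * (zid + 1L)) %% .Machine$integer.max
    take <- with_seed(zseed, {
      if (length(cells) <= quota) cells else sort(sample(cells, quota))
    })
    rr <- arrayInd(take, dim(eco))
    df <- data.frame(cell = take, row = rr[, 1], col = rr[, 2],
                     ecoregion_id = eco[take],
                     biome_id = biome_of(comp$zones, eco[take]),
                     plant = comp$plant$values[take],
                     fungal = comp$fungal$values[take])
    for (cv in names(comp$covariates)) df[[cv]] <- comp$covariates[[cv]][take]
    attr(df, "scale") <- scale
    attr(df, "zone_id") <- zid
    attr(df, "requested_n") <- quota
    attr(df, "achieved_n") <- nrow(df)
    attr(df, "seed") <- zseed
    samples[[as.character(zid)]] <- df
  }
  list(samples = samples, excluded = excluded)
}

#' Spearman rank correlation for a cell sample
#'
#' Spearman's rho on average-rank (midrank) ties between two columns of a cell
#' sample (or any table of paired richness values, e.g. ground-sourced plot
#' data).
#'
#' @param sample data.frame containing the two columns.
#' @param x,y column names (defaults `"plant"`, `"fungal"`).
#' @return One-row data.frame: `rho`, `n`.
#' @export
spearman_correlation <- function(sample, x = "plant", y = "fungal") {
  xv <- sample[[x]]; yv <- sample[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 complete pairs")
  if (length(unique(xv)) < 2 || length(unique(yv)) < 2) {
    stop("constant input vector: Spearman correlation undefined")
  }
  data.frame(rho = stats::cor(xv, yv, method = "spearman"), n = length(xv))
}

#' Correlation scan at global, biome and ecoregion scales
#'
#' Builds the masked consensus comparison for each fungal guild, samples cells
#' at the three scales, and computes one Spearman correlation record per
#' scale x zone x taxon pair. Ecoregion cell samples are returned so that
#' downstream driver models reuse exactly the cells that produced each
#' correlation.
#'
#' @param world a `world_bundle`.
#' @param quotas list with elements `global`, `biome`, `ecoregion`.
#' @param min_cells minimum retained cells per zone.
#' @param seed master seed.
#' @param q mask percentile passed to [build_comparison()].
#' @param taxa fungal guilds to scan.
#' @return A list: `correlations` (data.frame with `taxon_pair`, `scale`,
#'   `zone_id`, `biome_id`, `rho`, `n`), `samples` (per guild, per scale,
#'   the [sample_cells()] output), `comparisons` (per guild), `excluded`.
#' @export
scan_all_scales <- function(world, quotas = list(global = 10000, biome = 10000,
                                                 ecoregion = 1000),
                            min_cells = 100, seed = 1L, q = 95,
                            taxa = c("am", "ecm")) {
  stopifnot(all(c("global", "biome", "ecoregion") %in% names(quotas)))
  recs <- list(); samples <- list(); comps <- list(); excluded <- list()
  for (tx in taxa) {
    comp <- build_comparison(world, tx, q = q)
    comps[[tx]] <- comp
    samples[[tx]] <- list()
    for (sc in c("global", "biome", "ecoregion")) {
      sm <- sample_cells(comp, sc, quota = quotas[[sc]], min_cells = min_cells,
                         seed = seed)
      samples[[tx]][[sc]] <- sm
      if (nrow(sm$excluded)) {
        excluded[[paste(tx, sc)]] <- cbind(taxon_pair = paste0("plant-", tx),
                                           scale = sc, sm$excluded)
      }
      for (zid in names(sm$samples)) {
        df <- sm$samples[[zid]]
        r <- spearman_correlation(df)
        recs[[length(recs) + 1L]] <- data.frame(
          taxon_pair = paste0("plant-", tx), scale = sc,
          zone_id = as.integer(zid),
          biome_id = if (sc == "ecoregion") biome_of(world$zones, as.integer(zid))
                     else if (sc == "biome") as.integer(zid) else NA_integer_,
          rho = r$rho, n = r$n)
      }
    }
  }
  list(correlations = do.call(rbind, recs), samples = samples,
       comparisons = comps,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame())
}

#' Per-biome one-sample t-tests on ecoregion correlations
#'
#' Tests, within each biome and taxon pair, whether the mean of the ecoregion
#' Spearman correlations differs from zero (two-sided one-sample t-test, raw
#' p-values, no multiplicity correction).
#'
#' @param ecoregion_records ecoregion-scale rows of the `correlations` table
#'   from [scan_all_scales()].
#' @return data.frame: `taxon_pair`, `biome_id`, `n_ecoregions`, `mean_rho`,
#'   `t`, `p`, `note` (`"ok"`, or why the test was not possible). If the input
#'   contains a single biome x pair group that is degenerate, an error is
#'   raised instead.
#' @export
biome_sign_test <- function(ecoregion_records) {
  df <- ecoregion_records[ecoregion_records$scale == "ecoregion", , drop = FALSE]
  if (!nrow(df)) stop("no ecoregion-scale correlation records")
  groups <- split(df, list(df$taxon_pair, df$biome_id), drop = TRUE)
  one <- function(g) {
    rho <- g$rho
    if (length(rho) < 2) stop("fewer than 2 ecoregion correlations in biome")
    if (stats::sd(rho) == 0) stop("zero variance among ecoregion correlations")
    tt <- stats::t.test(rho, mu = 0)
    data.frame(taxon_pair = g$taxon_pair[1], biome_id = g$biome_id[1],
               n_ecoregions = length(rho), mean_rho = mean(rho),
               t = unname(tt$statistic), p = tt$p.value, note = "ok")
  }
  if (length(groups) == 1) return(one(groups[[1]]))
  out <- lapply(groups, function(g) {
    tryCatch(one(g), error = function(e) data.frame(
      taxon_pair = g$taxon_pair[1], biome_id = g$biome_id[1],
      n_ecoregions = nrow(g), mean_rho = mean(g$rho), t = NA_real_,
      p = NA_real_, note = conditionMessage(e)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$taxon_pair, out$biome_id), ]
}

#' Penalized-spline fit of fungal on plant richness
#'
#' Thin-plate regression spline smooth of fungal richness on plant richness
#' (Gaussian family, REML smoothness selection, `k` basis functions),
#' capturing non-monotone zonal relationships the rank correlation cannot.
#'
#' @param sample a cell sample data.frame.
#' @param k basis dimension.
#' @return One-row data.frame: `zone_id`, `deviance_explained` (percent),
#'   `k`, `edf`, `n`, `converged`.
#' @export
fit_richness_smooth <- function(sample, k = 3) {
  n <- nrow(sample)
  if (n < 10 * k) stop("need at least 10*k observations")
  # REML step-failure warnings on degenerate (e.g. noise-free) inputs are
  # expected; convergence is reported in the record instead
  fit <- suppressWarnings(
    mgcv::gam(fungal ~ s(plant, k = k, bs = "tp"), data = sample,
              family = stats::gaussian(), method = "REML"))
  dev_expl <- 100 * (1 - fit$deviance / fit$null.deviance)
  data.frame(zone_id = attr(sample, "zone_id") %||% NA_integer_,
             deviance_explained = dev_expl, k = k,
             edf = sum(fit$edf), n = n, converged = fit$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agreement between correlation and smooth-fit strength metrics
#'
#' Spearman correlation, across ecoregions, between the absolute zonal
#' Spearman coefficient and the percent deviance explained by the zonal
#' smooth fit.
#'
#' @param corr ecoregion correlation records (`zone_id`, `rho`).
#' @param fits smooth-fit records (`zone_id`, `deviance_explained`).
#' @return One-row data.frame: `rho`, `n_zones`.
#' @export
compare_metrics <- function(corr, fits) {
  m <- merge(corr[, c("zone_id", "rho")],
             fits[, c("zone_id", "deviance_explained")], by = "zone_id")
  if (nrow(m) < 3) stop("need at least 3 matched zones")
  data.frame(rho = stats::cor(abs(m$rho), m$deviance_explained,
                              method = "spearman"),
             n_zones = nrow(m))
}
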