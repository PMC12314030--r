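#' Log-transform and standardize a richness layer
#'
#' The consensus-building chain applied to every source richness layer:
#' log(x + 1) for layers still on the species-count scale, then centring and
#' scaling to zero mean and unit (sample) standard deviation over non-missing
#' cells. Layers distributed already log-transformed skip the log step.
#'
#' @param layer a [richness_layer()] in `"raw"` or `"log1p"` state.
#' @param already_logged if `TRUE`, the layer is asserted to be in `"log1p"`
#'   state and only standardization is applied.
#' @return A `richness_layer` in `"standardized"` state. The centring and
#'   scaling constants are attached as attributes `center` and `scale`.
#' @export
log1p_standardize <- function(layer, already_logged = identical(layer$transform, "log1p")) {
  stopifnot(inherits(layer, "richness_layer"))
  if (layer$transform == "standardized") {
    stop("layer is already standardized")
  }
  if (already_logged) {
    if (layer$transform != "log1p") stop("already_logged = TRUE but layer state is ", layer$transform)
    v <- layer$values
  } else {
    if (layer$transform != "raw") stop("cannot log1p a layer in state ", layer$transform)
    v <- log1p(layer$values)
  }
  ok <- !is.na(v)
  if (!any(ok)) stop("all-nodata layer cannot be standardized")
  mu <- mean(v[ok])
  sdev <- stats::sd(v[ok])
  if (!is.finite(sdev) || sdev == 0) stop("zero-variance layer: standardization undefined")
  out <- richness_layer((v - mu) / sdev, transform = "standardized",
                        provenance = layer$provenance)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}

#' Consensus richness layer from two standardized sources
#'
#' Cellwise mean of two standardized richness layers; a cell missing in either
#' input is missing in the consensus.
#'
#' @param a,b standardized [richness_layer()]s on the same grid.
#' @return A `richness_layer` with provenance `"consensus"`.
#' @export
consensus_mean <- function(a, b) {
  stopifnot(inherits(a, "richness_layer"), inherits(b, "richness_layer"))
  check_same_grid(a, b)
  if (a$transform != "standardized" || b$transform != "standardized") {
    stop("consensus requires both layers standardized")
  }
  richness_layer((a$values + b$values) / 2, transform = "standardized",
                 provenance = "consensus")
}

#' Cross-study disagreement as a two-value coefficient of variation
#'
#' For two values the CV reduces to half the absolute difference divided by
#' their mean. Because standardized layers contain negatives, both layers are
#' first shifted by one common constant, `-min(a, b) + 1e-6`, making every
#' value strictly positive. The shift affects CV magnitudes but for two values
#' the rank order of cells is shift-invariant, which is all that percentile
#' exclusion uses; the shift applied is recorded in the `shift` attribute.
#'
#' @param a,b standardized [richness_layer()]s on the same grid.
#' @return An [uncertainty_layer()] (dialect `"sd"` is not used here: values
#'   are stored as a unitless ratio under dialect `"cv_percent"` scaled by
#'   100 for consistency with published CV layers).
#' @export
pairwise_cv <- function(a, b) {
  stopifnot(inherits(a, "richness_layer"), inherits(b, "richness_layer"))
  check_same_grid(a, b)
  if (a$transform != b$transform) stop("state mismatch between layers")
  if (a$transform != "standardized") stop("pairwise_cv expects standardized layers")
  lo <- suppressWarnings(min(c(a$values, b$values), na.rm = TRUE))
  if (!is.finite(lo)) stop("no overlapping data cells")
  shift <- -lo + 1e-6
  av <- a$values + shift
  bv <- b$values + shift
  cv <- (abs(av - bv) / 2) / ((av + bv) / 2)
  out <- uncertainty_layer(100 * cv, dialect = "cv_percent",
                           provenance = paste(a$provenance, b$provenance, sep = "|"))
  attr(out, "shift") <- shift
  out
}

#' Percentile-based uncertainty mask
#'
#' Retains cells whose spread is less than or equal to the `q`-th percentile
#' (linear-interpolation, type-7 quantile) of the layer's non-missing spread
#' values; "top-percentile" cells, strictly above the threshold, are excluded.
#'
#' @param u an [uncertainty_layer()].
#' @param q percentile in (0, 100); 95 excludes the top-5% most uncertain cells.
#' @return A [cell_mask()]; the threshold used is attached as attribute
#'   `threshold`.
#' @export
percentile_mask <- function(u, q = 95) {
  stopifnot(inherits(u, "uncertainty_layer"), q > 0, q < 100)
  v <- u$values
  ok <- !is.na(v)
  if (!any(ok)) stop("empty uncertainty layer")
  thr <- stats::quantile(v[ok], q / 100, type = 7, names = FALSE)
  keep <- ok & v <= thr
  out <- cell_mask(keep, provenance = sprintf("%s<=p%g", u$provenance, q))
  attr(out, "threshold") <- thr
  out
}

#' Intersect retention masks
#'
#' Cellwise logical AND across masks: a cell is retained only if every
#' contributing mask retains it.
#'
#' @param masks a list of [cell_mask()]s on one grid (a single mask is allowed).
#' @return A [cell_mask()] with concatenated provenance.
#' @export
combine_masks <- function(masks) {
  if (inherits(masks, "cell_mask")) masks <- list(masks)
  stopifnot(length(masks) >= 1, all(vapply(masks, inherits, logical(1), "cell_mask")))
  do.call(check_same_grid, c(masks, list(what = "masks")))
  v <- masks[[1]]$values
  if (length(masks) > 1) for (m in masks[-1]) v <- v & m$values
  cell_mask(v, provenance = unlist(lapply(masks, `[[`, "provenance")))
}

#' Fraction of cells retained by a mask
#'
#' Percentage of retained cells among cells that carry data, globally and
#' (when a zone map is given) per ecoregion and per biome.
#'
#' @param mask a [cell_mask()].
#' @param zones optional [zone_map()] on the same grid.
#' @param domain optional logical matrix marking cells that carry data
#'   (defaults to all cells; pass e.g. `!is.na(layer$values)` to restrict to a
#'   land/data domain).
#' @return A data.frame with columns `scale`, `zone_id`, `n_cells`,
#'   `n_retained`, `percent`.
#' @export
retained_fraction <- function(mask, zones = NULL, domain = NULL) {
  stopifnot(inherits(mask, "cell_mask"))
  if (is.null(domain)) domain <- matrix(TRUE, nrow(mask$values), ncol(mask$values))
  check_same_grid(mask, domain)
  keep <- mask$values & domain
  res <- data.frame(scale = "global", zone_id = NA_integer_,
                    n_cells = sum(domain), n_retained = sum(keep),
                    percent = 100 * sum(keep) / sum(domain))
  if (!is.null(zones)) {
    check_same_grid(mask, zones)
    z <- zones$values
    for (scale in c("biome", "ecoregion")) {
      ids <- if (scale == "biome") matrix(biome_of(zones, z), nrow(z)) else z
      ids[!domain] <- NA
      tot <- table(ids)
      kept <- table(factor(ids[keep], levels = names(tot)))
      res <- rbind(res, data.frame(
        scale = scale, zone_id = as.integer(names(tot)),
        n_cells = as.integer(tot), n_retained = as.integer(kept),
        percent = 100 * as.integer(kept) / as.integer(tot)))
    }
  }
  rownames(res) <- NULL
  res
}

#' Build the masked consensus pair for one plant-fungal comparison
#'
#' Applies the full harmonization chain the analysis uses before any
#' correlation is computed: each of the four source layers (two plant studies,
#' two fungal studies) is log1p-standardized; per-study uncertainty masks
#' exclude each layer's top-(100−q)% most uncertain cells; cross-study
#' disagreement masks exclude the top-(100−q)% of the two-value CV between the
#' standardized study layers of each taxon; all six masks are intersected; and
#' consensus layers are the cellwise means. Plant layers are masked
#' differently in the AM and the ECM comparison because the fungal-side masks
#' differ.
#'
#' @param world a `world_bundle` from [make_world()] or [make_fixture()].
#' @param fungal_taxon `"am"` or `"ecm"`.
#' @param q percentile used for every uncertainty/disagreement mask.
#' @return A list of class `comparison` with elements `plant`, `fungal`
#'   (standardized consensus `richness_layer`s), `mask` (combined
#'   [cell_mask()]), `fungal_taxon`, `zones`, `covariates`, plus the
#'   standardized study layers and per-layer masks for downstream use.
#' @export
build_comparison <- function(world, fungal_taxon = c("am", "ecm"), q = 95) {
  fungal_taxon <- match.arg(fungal_taxon)
  std <- function(tx) lapply(world$taxa[[tx]]$studies, log1p_standardize)
  plant_std <- std("plant")
  fungal_std <- std(fungal_taxon)
  umask <- function(tx) lapply(world$taxa[[tx]]$uncertainty, percentile_mask, q = q)
  masks <- c(umask("plant"), umask(fungal_taxon),
             list(plant_disagreement = percentile_mask(pairwise_cv(plant_std[[1]], plant_std[[2]]), q = q),
                  fungal_disagreement = percentile_mask(pairwise_cv(fungal_std[[1]], fungal_std[[2]]), q = q)))
  mask <- combine_masks(masks)
  structure(list(
    plant = consensus_mean(plant_std[[1]], plant_std[[2]]),
    fungal = consensus_mean(fungal_std[[1]], fungal_std[[2]]),
    mask = mask, masks = masks, fungal_taxon = fungal_taxon,
    plant_std = plant_std, fungal_std = fungal_std,
    zones = world$zones, covariates = world$covariates, q = q
  ), class = "comparison")
}
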