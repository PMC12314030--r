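#' Percentile richness hotspots on one layer
#'
#' Hotspot cells are the mask-retained cells whose richness is strictly
#' greater than the `q`-th percentile (type-7 quantile) of retained values.
#' The strict comparison is deliberate (hotspots are the "top" tail), in
#' contrast to the `<=` retention rule of uncertainty masks.
#'
#' @param layer a [richness_layer()] (individual study layers, not consensus,
#'   are the convention for hotspot mapping).
#' @param mask a [cell_mask()] of retained cells.
#' @param q hotspot percentile in (0, 100).
#' @return A `hotspot_mask`: logical grid plus `source`, `q` and the
#'   `threshold` value used.
#' @export
hotspot_mask <- function(layer, mask, q = 95) {
  stopifnot(inherits(layer, "richness_layer"), inherits(mask, "cell_mask"),
            q > 0, q < 100)
  check_same_grid(layer, mask)
  keep <- mask$values & !is.na(layer$values)
  if (!any(keep)) stop("all cells masked: no retained values for the percentile")
  thr <- stats::quantile(layer$values[keep], q / 100, type = 7, names = FALSE)
  hot <- keep & layer$values > thr
  structure(list(values = hot, source = layer$provenance, q = q,
                 threshold = thr),
            class = c("hotspot_mask", "cell_mask"))
}

#' Union of two same-taxon hotspot masks with agreement counts
#'
#' A cell flagged by either study counts as a hotspot; the per-cell agreement
#' level (1 = one study, 2 = both) is retained.
#'
#' @param a,b `hotspot_mask`s for the same taxon on one grid.
#' @return A `hotspot_mask` with an `agreement` integer matrix (0/1/2).
#' @export
union_hotspots <- function(a, b) {
  stopifnot(inherits(a, "hotspot_mask"), inherits(b, "hotspot_mask"))
  check_same_grid(a, b)
  agreement <- a$values + b$values
  structure(list(values = a$values | b$values,
                 source = paste(a$source, b$source, sep = "|"),
                 q = a$q, threshold = c(a$threshold, b$threshold),
                 agreement = agreement),
            class = c("hotspot_mask", "cell_mask"))
}

#' Plant-fungal hotspot overlap accounting
#'
#' Overlap between a fungal and a plant hotspot mask, globally and (with a
#' zone map) per biome. The primary percent uses the fungal hotspot area as
#' denominator; the plant-denominator percent is also reported. With
#' `mode = "crosstab"` the global hotspot sets are cross-tabulated by biome;
#' `mode = "within"` requires recomputing hotspots inside each biome first
#' (see [biome_hotspot_overlap()]).
#'
#' @param fungal,plant `hotspot_mask`s on one grid.
#' @param zones optional [zone_map()] for per-biome rows.
#' @return data.frame with `scope`, `biome_id`, `fungal_cells`, `plant_cells`,
#'   `overlap_cells`, `overlap_pct_of_fungal`, `overlap_pct_of_plant`, and
#'   agreement counts when available.
#' @export
overlap_summary <- function(fungal, plant, zones = NULL) {
  stopifnot(inherits(fungal, "hotspot_mask"), inherits(plant, "hotspot_mask"))
  check_same_grid(fungal, plant)
  row_for <- function(scope, biome_id, sel) {
    f <- sum(fungal$values & sel); p <- sum(plant$values & sel)
    ov <- sum(fungal$values & plant$values & sel)
    if (scope == "global" && f == 0) stop("empty fungal hotspot set")
    data.frame(scope = scope, biome_id = biome_id, fungal_cells = f,
               plant_cells = p, overlap_cells = ov,
               overlap_pct_of_fungal = if (f > 0) 100 * ov / f else NA_real_,
               overlap_pct_of_plant = if (p > 0) 100 * ov / p else NA_real_)
  }
  all_sel <- matrix(TRUE, nrow(fungal$values), ncol(fungal$values))
  out <- row_for("global", NA_integer_, all_sel)
  if (!is.null(zones)) {
    check_same_grid(fungal, zones)
    bio <- matrix(biome_of(zones, zones$values), nrow(zones$values))
    for (b in sort(unique(bio[!is.na(bio)]))) {
      out <- rbind(out, row_for("biome", b, !is.na(bio) & bio == b))
    }
  }
  rownames(out) <- NULL
  out
}

#' Within-biome recomputed hotspot overlap
#'
#' Recomputes hotspot thresholds inside each biome (the percentile taken over
#' the biome's own retained cells) before measuring overlap, the alternative
#' to cross-tabulating globally thresholded hotspots by biome.
#'
#' @param fungal_layers,plant_layers lists of the per-study
#'   [richness_layer()]s of each taxon.
#' @param mask combined retention [cell_mask()].
#' @param zones a [zone_map()].
#' @param q hotspot percentile.
#' @return Per-biome data.frame as in [overlap_summary()].
#' @export
biome_hotspot_overlap <- function(fungal_layers, plant_layers, mask, zones, q = 95) {
  bio <- matrix(biome_of(zones, zones$values), nrow(zones$values))
  out <- list()
  for (b in sort(unique(bio[!is.na(bio)]))) {
    sel <- cell_mask(mask$values & !is.na(bio) & bio == b, "biome")
    union_of <- function(layers) {
      hs <- lapply(layers, hotspot_mask, mask = sel, q = q)
      Reduce(union_hotspots, hs)
    }
    res <- tryCatch({
      s <- overlap_summary(union_of(fungal_layers), union_of(plant_layers))
      s$scope <- "biome"; s$biome_id <- b
      s
    }, error = function(e) NULL)
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hotspot overlap versus host-plant prevalence
#'
#' Spearman correlation, across biomes, between hotspot overlap percent and
#' mean host-plant biomass percent — the check that overlap is (or is not)
#' greater where potential hosts dominate the vegetation.
#'
#' @param biome_summaries per-biome rows from [overlap_summary()] or
#'   [biome_hotspot_overlap()].
#' @param host_biomass_means data.frame with `biome_id`, `host_pct`.
#' @return One-row data.frame: `rho`, `n_biomes`.
#' @export
overlap_vs_host_prevalence <- function(biome_summaries, host_biomass_means) {
  m <- merge(biome_summaries[, c("biome_id", "overlap_pct_of_fungal")],
             host_biomass_means, by = "biome_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("need at least 3 biomes")
  if (length(unique(m$overlap_pct_of_fungal)) < 2) {
    stop("constant overlap percent: correlation undefined")
  }
  data.frame(rho = stats::cor(m$overlap_pct_of_fungal, m$host_pct,
                              method = "spearman"), n_biomes = nrow(m))
}
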