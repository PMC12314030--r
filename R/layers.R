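#' Gridded richness layer
#'
#' A single-band gridded surface of species-richness values. Cells with no
#' data are stored as `NA`. The `transform` state records where the layer sits
#' in the log1p -> standardize chain used to build consensus layers:
#' `"raw"` (species counts), `"log1p"` (log(x + 1) of counts), or
#' `"standardized"` (zero mean, unit sample SD over non-missing cells).
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param transform one of `"raw"`, `"log1p"`, `"standardized"`.
#' @param provenance label identifying the source study (or `"consensus"`).
#' @return A `richness_layer` object.
#' @export
richness_layer <- function(values, transform = c("raw", "log1p", "standardized"),
                           provenance = "unknown") {
  transform <- match.arg(transform)
  values <- as_layer_matrix(values)
  if (transform == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw richness values must be non-negative")
  }
  if (any(is.infinite(values))) stop("richness values must be finite or NA")
  structure(list(values = values, transform = transform, provenance = provenance),
            class = "richness_layer")
}

#' Gridded prediction-uncertainty layer
#'
#' Per-cell prediction spread in one of the dialects used by published
#' richness products: `"cv_percent"` (coefficient of variation, percent of the
#' mean), `"sd"` (standard deviation on the layer's own scale), or
#' `"iqr_ratio_percent"` (percentage ratio of the interquartile range to the
#' median).
#'
#' @param values numeric matrix of spread values, all `>= 0` (`NA` = nodata).
#' @param dialect one of `"cv_percent"`, `"sd"`, `"iqr_ratio_percent"`.
#' @param provenance label identifying the source study.
#' @return An `uncertainty_layer` object.
#' @export
uncertainty_layer <- function(values, dialect = c("cv_percent", "sd", "iqr_ratio_percent"),
                              provenance = "unknown") {
  dialect <- match.arg(dialect)
  values <- as_layer_matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("uncertainty values must be non-negative")
  structure(list(values = values, dialect = dialect, provenance = provenance),
            class = "uncertainty_layer")
}

#' Boolean cell-retention mask
#'
#' `TRUE` marks a retained cell, `FALSE` an excluded one. `NA` cells (nodata
#' in the source layer) are treated as excluded everywhere.
#'
#' @param values logical matrix.
#' @param provenance character vector naming the masks combined into this one.
#' @return A `cell_mask` object.
#' @export
cell_mask <- function(values, provenance = character()) {
  if (!is.matrix(values)) stop("mask values must be a matrix")
  storage.mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  structure(list(values = values, provenance = as.character(provenance)),
            class = "cell_mask")
}

#' Ecoregion/biome zone map
#'
#' Integer grid of ecoregion ids plus a lookup table mapping each ecoregion to
#' exactly one biome.
#'
#' @param values integer matrix of ecoregion ids (`NA` = nodata).
#' @param lookup data.frame with columns `ecoregion_id`, `biome_id`.
#' @return A `zone_map` object.
#' @export
zone_map <- function(values, lookup) {
  values <- as_layer_matrix(values)
  storage.mode(values) <- "integer"
  stopifnot(is.data.frame(lookup),
            all(c("ecoregion_id", "biome_id") %in% names(lookup)))
  if (anyDuplicated(lookup$ecoregion_id)) {
    stop("each ecoregion must map to exactly one biome")
  }
  ids <- unique(values[!is.na(values)])
  if (!all(ids %in% lookup$ecoregion_id)) {
    stop("zone map contains ecoregion ids missing from the lookup")
  }
  structure(list(values = values, lookup = lookup[order(lookup$ecoregion_id), ,
                                                  drop = FALSE]),
            class = "zone_map")
}

as_layer_matrix <- function(values) {
  if (!is.matrix(values)) stop("layer values must be a matrix")
  storage.mode(values) <- "double"
  values
}

layer_values <- function(x) {
  if (is.list(x) && !is.null(x$values)) x$values else as_layer_matrix(x)
}

#' @export
dim.richness_layer <- function(x) dim(x$values)
#' @export
dim.uncertainty_layer <- function(x) dim(x$values)
#' @export
dim.cell_mask <- function(x) dim(x$values)
#' @export
dim.zone_map <- function(x) dim(x$values)

check_same_grid <- function(..., what = "layers") {
  dims <- lapply(list(...), function(x) dim(layer_values(x)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L) {
    stop(sprintf("grid mismatch: %s must share one grid", what))
  }
  invisible(TRUE)
}

#' @export
print.richness_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<richness_layer> %d x %d cells, transform = %s, provenance = %s\n",
              nrow(v), ncol(v), x$transform, x$provenance))
  cat(sprintf("  non-missing: %d, range: [%.4g, %.4g]\n",
              sum(!is.na(v)), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.uncertainty_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<uncertainty_layer> %d x %d cells, dialect = %s, provenance = %s\n",
              nrow(v), ncol(v), x$dialect, x$provenance))
  invisible(x)
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d cells, retained = %d (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " & "), "\n")
  }
  invisible(x)
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d x %d cells, %d ecoregions in %d biomes\n",
              nrow(x$values), ncol(x$values), nrow(x$lookup),
              length(unique(x$lookup$biome_id))))
  invisible(x)
}

#' Biome id for each ecoregion id
#' @param zones a [zone_map()].
#' @param ecoregion_id integer vector of ecoregion ids.
#' @return integer vector of biome ids.
#' @export
biome_of <- function(zones, ecoregion_id) {
  idx <- match(ecoregion_id, zones$lookup$ecoregion_id)
  zones$lookup$biome_id[idx]
}
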