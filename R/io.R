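ASC_NODATA <- -9999

#' Write a layer to an ESRI ASCII grid
#'
#' Single-band plain-text raster (`.asc`) with nodata sentinel -9999 and a
#' unit-cell identity georeference. Layer metadata that the ASCII grid format
#' cannot carry (class, transform state, uncertainty dialect, provenance,
#' mask provenance) is written to a JSON sidecar at `<path>.json`.
#'
#' @param layer a [richness_layer()], [uncertainty_layer()], [cell_mask()],
#'   [zone_map()] (zone lookup is written to `<path>.lookup.csv`), or a plain
#'   numeric matrix (e.g. a covariate grid), which reads back as a matrix.
#' @param path output path (conventionally ending in `.asc`).
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  v <- layer_values(layer)
  if (inherits(layer, "cell_mask")) v <- v * 1
  meta <- list(class = if (is.matrix(layer)) "grid" else class(layer)[1])
  if (inherits(layer, "richness_layer")) {
    meta$transform <- layer$transform; meta$provenance <- layer$provenance
  } else if (inherits(layer, "uncertainty_layer")) {
    meta$dialect <- layer$dialect; meta$provenance <- layer$provenance
  } else if (inherits(layer, "hotspot_mask")) {
    meta$q <- layer$q; meta$threshold <- layer$threshold; meta$source <- layer$source
  } else if (inherits(layer, "cell_mask")) {
    meta$provenance <- layer$provenance
  }
  out <- v
  out[is.na(out)] <- ASC_NODATA
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           "xllcorner 0", "yllcorner 0", "cellsize 1",
           sprintf("NODATA_value %d", ASC_NODATA))
  body <- apply(out, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (inherits(layer, "zone_map")) {
    utils::write.csv(layer$lookup, paste0(path, ".lookup.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a layer from an ESRI ASCII grid
#'
#' Inverse of [write_layer()]: reconstructs the layer class from the JSON
#' sidecar when present (a bare `.asc` without sidecar is returned as a raw
#' [richness_layer()]). Integer grids round-trip exactly; doubles round-trip
#' to the printed precision (at least float32).
#'
#' @param path path to the `.asc` file.
#' @return The reconstructed layer object.
#' @export
read_layer <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get_num <- function(key) {
    ln <- hdr[grep(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- get_num("ncols"); nr <- get_num("nrows"); nd <- get_num("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) stop("corrupt ASCII grid: cell count mismatch")
  v <- matrix(vals, nrow = nr, byrow = TRUE)
  v[v == nd] <- NA
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list(class = "richness_layer")
  switch(meta$class,
    grid = v,
    richness_layer = richness_layer(v, meta$transform %||% "raw",
                                    meta$provenance %||% "unknown"),
    uncertainty_layer = uncertainty_layer(v, meta$dialect %||% "sd",
                                          meta$provenance %||% "unknown"),
    cell_mask = cell_mask(v == 1, unlist(meta$provenance)),
    hotspot_mask = structure(list(values = v == 1, source = meta$source,
                                  q = meta$q, threshold = unlist(meta$threshold)),
                             class = c("hotspot_mask", "cell_mask")),
    zone_map = {
      lk <- utils::read.csv(paste0(path, ".lookup.csv"))
      zone_map(v, lk)
    },
    stop("unknown layer class in sidecar: ", meta$class))
}

#' Write a tidy result table with a config-hash header comment
#'
#' @param df data.frame.
#' @param path output CSV path.
#' @param config_hash hash string recorded as a `#` comment on line one.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_csv()]
#' @param path CSV path.
#' @return data.frame (the header comment is skipped).
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
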