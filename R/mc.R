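#' Convert a CV-percent uncertainty layer to an SD layer
#'
#' `SD = (CV% / 100) * mean`, cellwise.
#'
#' @param u an [uncertainty_layer()] with dialect `"cv_percent"`.
#' @param mean_layer the matching central-tendency [richness_layer()].
#' @return A `spread_conversion`: list with `sd` (an [uncertainty_layer()] of
#'   dialect `"sd"`), `input_dialect`, `constant`.
#' @export
cv_to_sd <- function(u, mean_layer) {
  stopifnot(inherits(u, "uncertainty_layer"))
  if (u$dialect != "cv_percent") stop("dialect mismatch: expected cv_percent, got ", u$dialect)
  check_same_grid(u, mean_layer)
  sd_vals <- (u$values / 100) * layer_values(mean_layer)
  structure(list(sd = uncertainty_layer(sd_vals, "sd", u$provenance),
                 input_dialect = "cv_percent", constant = 1 / 100),
            class = "spread_conversion")
}

#' Convert an IQR-ratio-percent uncertainty layer to an SD layer
#'
#' `SD = (ratio% / 100) * median * 1.35`: the percentage ratio of the
#' interquartile range to the median is rescaled by the normal-theory constant
#' IQR/SD ~ 1.35. The approximation assumes roughly normal prediction
#' replicates (a warning notes this), and the median layer is treated as
#' equivalent to a mean layer downstream.
#'
#' @param u an [uncertainty_layer()] with dialect `"iqr_ratio_percent"`.
#' @param median_layer the matching median [richness_layer()].
#' @return A `spread_conversion` (see [cv_to_sd()]).
#' @export
iqr_ratio_to_sd <- function(u, median_layer) {
  stopifnot(inherits(u, "uncertainty_layer"))
  if (u$dialect != "iqr_ratio_percent") {
    stop("dialect mismatch: expected iqr_ratio_percent, got ", u$dialect)
  }
  check_same_grid(u, median_layer)
  warning("IQR-to-SD conversion assumes normally distributed prediction replicates")
  sd_vals <- (u$values / 100) * layer_values(median_layer) * 1.35
  structure(list(sd = uncertainty_layer(sd_vals, "sd", u$provenance),
                 input_dialect = "iqr_ratio_percent", constant = 1.35 / 100),
            class = "spread_conversion")
}

#' Convert any uncertainty dialect to an SD layer
#'
#' Dispatches on the layer's dialect; `"sd"` layers pass through unchanged.
#'
#' @inheritParams cv_to_sd
#' @param central_layer matching mean/median layer (ignored for `"sd"`).
#' @return A `spread_conversion`.
#' @export
to_sd <- function(u, central_layer = NULL) {
  switch(u$dialect,
         sd = structure(list(sd = u, input_dialect = "sd", constant = 1),
                        class = "spread_conversion"),
         cv_percent = cv_to_sd(u, central_layer),
         iqr_ratio_percent = suppressWarnings(iqr_ratio_to_sd(u, central_layer)))
}

#' Prepare per-layer inputs for Monte-Carlo error propagation
#'
#' Extracts, for each of the four study layers behind one plant-fungal
#' comparison, the sampled-cell values on the layer's distributed scale, the
#' per-cell SD (converted from the layer's uncertainty dialect against the
#' layer's own values), the pre-logged flag, and the standardization constants
#' of the full layer (mean and SD of the log1p values over all data cells, not
#' just the sample).
#'
#' @param world a `world_bundle`.
#' @param fungal_taxon `"am"` or `"ecm"`.
#' @param sample the global cell sample whose correlation is being propagated
#'   (its `cell` column indexes the grid).
#' @return List of class `mc_inputs` with one element per study layer.
#' @export
prepare_mc_inputs <- function(world, fungal_taxon = c("am", "ecm"), sample) {
  fungal_taxon <- match.arg(fungal_taxon)
  cells <- sample$cell
  layer_input <- function(layer, u, taxon_role) {
    pre_logged <- identical(layer$transform, "log1p")
    sdc <- to_sd(u, layer)$sd$values
    full <- if (pre_logged) layer$values else log1p(layer$values)
    ok <- !is.na(full)
    list(values = layer$values[cells], sd = sdc[cells], pre_logged = pre_logged,
         center = mean(full[ok]), scale = stats::sd(full[ok]),
         taxon_role = taxon_role, provenance = layer$provenance)
  }
  tx <- world$taxa
  structure(list(
    layer_input(tx$plant$studies[[1]], tx$plant$uncertainty[[1]], "plant"),
    layer_input(tx$plant$studies[[2]], tx$plant$uncertainty[[2]], "plant"),
    layer_input(tx[[fungal_taxon]]$studies[[1]], tx[[fungal_taxon]]$uncertainty[[1]], "fungal"),
    layer_input(tx[[fungal_taxon]]$studies[[2]], tx[[fungal_taxon]]$uncertainty[[2]], "fungal")),
    class = "mc_inputs", taxon_pair = paste0("plant-", fungal_taxon))
}

#' Monte-Carlo re-estimation of a correlation under prediction uncertainty
#'
#' Repeats, over a fixed cell sample: (1) perturb each study layer's sampled
#' values by Uniform(-SD, +SD) per cell; (2) log1p the perturbed values of
#' layers not distributed pre-logged (values below -1 are clamped to
#' -1 + 1e-9 and counted); (3) standardize with the full-layer constants;
#' (4) average the two study layers per taxon; (5) compute the Spearman
#' correlation between the perturbed plant and fungal consensus values. The
#' same cells are reused across iterations, so the spread of the returned
#' distribution reflects measurement error only. With `sd_scale` and one seed,
#' common random numbers are used across scale factors.
#'
#' @param inputs an `mc_inputs` object from [prepare_mc_inputs()].
#' @param iterations number of Monte-Carlo iterations.
#' @param seed master seed; iteration `i` uses substream `seed + i`.
#' @param sd_scale multiplier applied to every per-cell SD.
#' @return `mc_distribution`: list with `rho` (vector, one per iteration),
#'   `iterations`, `seed`, `sd_scale`, `clamped` (count of log1p clamps),
#'   `taxon_pair`.
#' @export
perturb_and_correlate <- function(inputs, iterations = 1000, seed = 1L,
                                  sd_scale = 1) {
  stopifnot(inherits(inputs, "mc_inputs"), iterations >= 1)
  n <- length(inputs[[1]]$values)
  rho <- numeric(iterations)
  clamped <- 0L
  roles <- vapply(inputs, `[[`, character(1), "taxon_role")
  for (i in seq_len(iterations)) {
    std <- with_seed((seed + i) %% .Machine$integer.max, {
      lapply(inputs, function(li) {
        pert <- li$values + stats::runif(n, -1, 1) * li$sd * sd_scale
        if (!li$pre_logged) {
          low <- pert < -1 + 1e-9
          clamped <<- clamped + sum(low)
          pert[low] <- -1 + 1e-9
          pert <- log1p(pert)
        }
        (pert - li$center) / li$scale
      })
    })
    plant <- Reduce(`+`, std[roles == "plant"]) / sum(roles == "plant")
    fungal <- Reduce(`+`, std[roles == "fungal"]) / sum(roles == "fungal")
    rho[i] <- stats::cor(plant, fungal, method = "spearman")
  }
  structure(list(rho = rho, iterations = iterations, seed = seed,
                 sd_scale = sd_scale, clamped = clamped,
                 taxon_pair = attr(inputs, "taxon_pair")),
            class = "mc_distribution")
}

#' Summarize a Monte-Carlo correlation distribution
#'
#' @param dist an `mc_distribution`.
#' @param reference_rho the unperturbed correlation the distribution is
#'   compared against.
#' @return One-row data.frame: `taxon_pair`, `reference_rho`, `mean`,
#'   `median`, `q2.5`, `q97.5`, `sign_fraction` (iterations matching the
#'   reference sign), `sign_stable` (`sign_fraction == 1`), `iterations`,
#'   `clamped`.
#' @export
mc_summary <- function(dist, reference_rho) {
  stopifnot(inherits(dist, "mc_distribution"))
  if (length(dist$rho) < 2) stop("need at least 2 iterations to summarize")
  qs <- stats::quantile(dist$rho, c(0.025, 0.975), names = FALSE)
  frac <- mean(sign(dist$rho) == sign(reference_rho))
  data.frame(taxon_pair = dist$taxon_pair %||% NA_character_,
             reference_rho = reference_rho, mean = mean(dist$rho),
             median = stats::median(dist$rho), q2.5 = qs[1], q97.5 = qs[2],
             sign_fraction = frac, sign_stable = frac == 1,
             iterations = dist$iterations, clamped = dist$clamped)
}
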