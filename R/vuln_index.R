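#' Derive vulnerability-index weights from adjusted odds ratios
#'
#' Variables whose adjusted-OR confidence interval excludes 1 are retained;
#' each weight is the adjusted OR minus 1 (the percentage increase in risk
#' per unit), further divided by 100 for a binary variable that enters the
#' map as an area-level population percentage (so the weight reads "change
#' in risk per 1% of the population"). By default ORs are taken at their
#' 2-decimal presentation precision, which reproduces published index
#' formulas built from printed tables; set `round_digits = NULL` to use the
#' unrounded estimates (e.g. in simulation experiments).
#'
#' @param ors an `or_table` (see [adjusted_ors()]) for the candidate
#'   variables.
#' @param kinds named character vector mapping each term to
#'   `"binary-population-percentage"` or `"continuous-percentage"`; terms
#'   absent from `kinds` default to continuous.
#' @param round_digits decimal places at which ORs are taken (default 2);
#'   `NULL` for unrounded.
#' @return object of class `index_weights`: data.frame with `name`,
#'   `weight`, `variable_kind`, `or`.
#' @examples
#' m3 <- or_table(
#'   term = c("low_education", "pct_residential",
#'            "avg_build_height_pctile", "std_build_height_pctile"),
#'   or = c(1.60, 1.01, 0.98, 1.03),
#'   ci_low = c(1.21, 1.00, 0.96, 1.01),
#'   ci_high = c(2.12, 1.02, 0.99, 1.04))
#' derive_weights(m3, kinds = c(low_education = "binary-population-percentage"))
#' @export
derive_weights <- function(ors, kinds = character(), round_digits = 2) {
  stopifnot(inherits(ors, "data.frame"))
  sig <- ors[ors$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    stop("no significant variables; vulnerability index undefined")
  or <- if (is.null(round_digits)) sig$or else round(sig$or, round_digits)
  kind <- ifelse(sig$term %in%
                   names(kinds)[kinds == "binary-population-percentage"],
                 "binary-population-percentage", "continuous-percentage")
  w <- ifelse(kind == "binary-population-percentage",
              (or - 1) / 100, or - 1)
  out <- data.frame(name = sig$term, weight = w, variable_kind = kind,
                    or = or, row.names = NULL)
  class(out) <- c("index_weights", "data.frame")
  out
}

#' @export
print.index_weights <- function(x, ...) {
  cat("Socio-environmental vulnerability index weights (OR - 1",
      "rule):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %+g x %s  [%s]\n", x$weight[i], x$name[i],
                x$variable_kind[i]))
  invisible(x)
}

#' Rasterize a planning-unit attribute to a zone-constant layer
#'
#' @param tpus TPU data.frame (`tpu_id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   attribute columns).
#' @param attribute column to rasterize.
#' @param template [raster_layer()] defining the output grid.
#' @return a [raster_layer()], constant within each zone; cells outside all
#'   zones are `NA`.
#' @export
rasterize_tpu <- function(tpus, attribute, template) {
  cc <- cell_centers(template)
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  for (k in seq_len(nrow(tpus))) {
    jj <- which(cc$x >= tpus$xmin[k] & cc$x < tpus$xmax[k])
    ii <- which(cc$y >= tpus$ymin[k] & cc$y < tpus$ymax[k])
    out[ii, jj] <- tpus[[attribute]][k]
  }
  raster_layer(out, origin = template$origin,
               resolution_m = template$resolution_m)
}

#' Compute the vulnerability-index raster
#'
#' Cellwise weighted sum of the input layers: for every retained variable
#' the layer named after it is multiplied by its weight and summed. Nodata
#' propagates (any `NA` input makes the output cell `NA`). The result is
#' exactly linear in each input layer.
#'
#' @param weights an [derive_weights()] `index_weights` object.
#' @param layers named list of co-registered [raster_layer()]s; must
#'   contain one layer per retained weight name (e.g. `low_education`,
#'   `pct_residential`, `avg_build_height_pctile`,
#'   `std_build_height_pctile`). Building-height layers are expected
#'   already percentile-normalized citywide (0-100).
#' @return object of class `vuln_raster`: a [raster_layer()] with a
#'   `weights` attribute recording provenance.
#' @export
compute_index_raster <- function(weights, layers) {
  miss <- setdiff(weights$name, names(layers))
  if (length(miss))
    stop("missing input layer(s) for index variable(s): ",
         paste(miss, collapse = ", "))
  used <- layers[weights$name]
  do.call(check_registration, used)
  acc <- matrix(0, nrow(used[[1]]$values), ncol(used[[1]]$values))
  for (k in seq_len(nrow(weights)))
    acc <- acc + weights$weight[k] * used[[k]]$values
  out <- raster_layer(acc, origin = used[[1]]$origin,
                      resolution_m = used[[1]]$resolution_m)
  attr(out, "weights") <- weights
  class(out) <- c("vuln_raster", class(out))
  out
}

#' Aggregate the vulnerability index to planning units
#'
#' Zone mean of the index over valid cells (cell centre in the zone's
#' rectangle, half-open), binned to the nearest 0.1 — the scale unit at
#' which the vulnerability map is reported. Zones with no valid cell (no
#' settlement) are flagged and carry no number.
#'
#' @param vuln a [compute_index_raster()] result (or any [raster_layer()]).
#' @param tpus TPU data.frame.
#' @return data.frame `tpu_id`, `index_mean`, `index_binned`, `n_cells`,
#'   `empty` (flag).
#' @export
aggregate_to_tpu <- function(vuln, tpus) {
  if (nrow(tpus) == 0L) stop("empty planning-unit list")
  cc <- cell_centers(vuln)
  out <- data.frame(tpu_id = tpus$tpu_id, index_mean = NA_real_,
                    index_binned = NA_real_, n_cells = 0L, empty = TRUE)
  for (k in seq_len(nrow(tpus))) {
    jj <- which(cc$x >= tpus$xmin[k] & cc$x < tpus$xmax[k])
    ii <- which(cc$y >= tpus$ymin[k] & cc$y < tpus$ymax[k])
    v <- vuln$values[ii, jj]
    v <- v[!is.na(v)]
    if (length(v)) {
      m <- mean(v)
      out$index_mean[k] <- m
      out$index_binned[k] <- round(m * 10) / 10
      out$n_cells[k] <- length(v)
      out$empty[k] <- FALSE
    }
  }
  out
}

#' Map the vulnerability index over the synthetic city
#'
#' Convenience wrapper for the mapping stage: builds the 400-m moving-
#' window environmental layers at the mapping resolution, percentile-
#' normalizes the building-height layers citywide, rasterizes the zone
#' census attribute for the low-education term, computes the index raster
#' and aggregates it to planning units.
#'
#' @param weights [derive_weights()] result. Retained *social* variables
#'   are mapped from zone-level population percentages: `low_education`
#'   uses the TPU census attribute `pct_low_education`; any other retained
#'   social variable must have a `pct_<name>` column in `tpus`.
#' @param rasters list with `land_use`, `vegetation`, `building_height`.
#' @param tpus TPU data.frame.
#' @param radius_m moving-window radius (default 400 m).
#' @return list `vuln` (index [raster_layer()]), `tpu_summary`, `layers`.
#' @export
map_vulnerability <- function(weights, rasters, tpus, radius_m = 400) {
  residential <- binarize_landuse(rasters$land_use)
  fr <- buffer_feature_rasters(residential, rasters$vegetation,
                               rasters$building_height, radius_m = radius_m)
  layers <- list(
    pct_residential = fr$pct_residential,
    pct_vegetation = fr$pct_vegetation,
    avg_build_height_pctile =
      percentile_normalize_raster(fr$avg_build_height_m),
    std_build_height_pctile =
      percentile_normalize_raster(fr$std_build_height_m))
  social <- setdiff(weights$name, names(layers))
  for (nm in social) {
    col <- if (nm == "low_education") "pct_low_education" else paste0("pct_", nm)
    if (!col %in% names(tpus))
      stop("TPU table lacks column `", col, "` needed for index variable `",
           nm, "`")
    layers[[nm]] <- rasterize_tpu(tpus, col, fr$pct_residential)
  }
  vuln <- compute_index_raster(weights, layers)
  list(vuln = vuln, tpu_summary = aggregate_to_tpu(vuln, tpus),
       layers = layers)
}

#' Quick image plot of a raster layer
#'
#' Minimal visualization helper (no cartographic styling): `image()` of the
#' grid in map orientation with an optional legend-friendly title.
#'
#' @param x a [raster_layer()].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.raster_layer <- function(x, main = NULL, ...) {
  cc <- cell_centers(x)
  graphics::image(cc$x, cc$y, t(x$values), asp = 1, xlab = "x (m)",
                  ylab = "y (m)", main = main, useRaster = TRUE, ...)
  invisible(x)
}
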