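#' Binarize a land-use layer into residential / non-residential
#'
#' Cells whose land-use class is one of `residential_classes` become 1, all
#' other classified cells 0; `NA` cells stay `NA`. The default class set is
#' the three residential categories of the Hong Kong land utilization map.
#'
#' @param land_use a categorical [raster_layer()] whose `levels` name the
#'   integer codes in `values`.
#' @param residential_classes character vector of class labels to treat as
#'   residential.
#' @return a 0/1 [raster_layer()].
#' @export
binarize_landuse <- function(land_use,
                             residential_classes = c("private residential",
                                                     "public residential",
                                                     "rural settlement")) {
  if (length(residential_classes) == 0L)
    stop("`residential_classes` must be non-empty")
  if (is.null(land_use$levels))
    stop("`land_use` has no class levels; not a categorical layer")
  unknown <- setdiff(residential_classes, land_use$levels)
  if (length(unknown))
    warning("unknown land-use class label(s): ",
            paste(unknown, collapse = ", "))
  codes <- which(land_use$levels %in% residential_classes)
  v <- land_use$values
  out <- (v %in% codes) * 1
  dim(out) <- dim(v)
  out[is.na(v)] <- NA
  raster_layer(out, origin = land_use$origin,
               resolution_m = land_use$resolution_m)
}

#' Built-environment features within a circular buffer of each point
#'
#' For every subject location, computes the four built-environment measures
#' over the cells whose centre lies within `radius_m` of the point:
#' percentage residential, percentage vegetated, and the mean and standard
#' deviation of building height over *built* cells (height > 0) only (set
#' `built_cells_only = FALSE` to average over all valid cells with
#' non-building ground as 0 m). Buffers are clipped at the raster edge; the
#' denominator is the number of valid in-extent cells, and subjects whose
#' buffer is more than half outside the extent are flagged.
#'
#' @param x,y subject coordinates in metres.
#' @param residential 0/1 [raster_layer()] (see [binarize_landuse()]).
#' @param vegetation 0/1 [raster_layer()].
#' @param building_height [raster_layer()] of heights in metres, 0 = no
#'   building.
#' @param radius_m buffer radius in metres (default 400).
#' @param built_cells_only logical; see Description.
#' @param ids optional subject identifiers for error messages.
#' @return data.frame with columns `pct_residential`, `pct_vegetation`,
#'   `avg_build_height_m`, `std_build_height_m`, `no_buildings` (flag: no
#'   built cell in buffer, avg/std reported as 0), `edge_flag`.
#' @export
buffer_features <- function(x, y, residential, vegetation, building_height,
                            radius_m = 400, built_cells_only = TRUE,
                            ids = seq_along(x)) {
  check_registration(residential, vegetation, building_height)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (radius_m <= 0) stop("`radius_m` must be positive")
  r <- residential$resolution_m
  d <- dim(residential$values)
  ext <- raster_extent(residential)
  out_of_extent <- x < ext["xmin"] | x >= ext["xmax"] |
    y < ext["ymin"] | y >= ext["ymax"]
  if (any(out_of_extent))
    stop("points outside raster extent: ",
         paste(utils::head(ids[out_of_extent], 10L), collapse = ", "))
  cx <- residential$origin[1] + (seq_len(d[2]) - 0.5) * r
  cy <- residential$origin[2] + (seq_len(d[1]) - 0.5) * r
  # reference count for the edge flag: disc cell count away from any edge
  full_n <- sum(disc_kernel(r, radius_m))
  n <- length(x)
  res <- data.frame(pct_residential = numeric(n), pct_vegetation = numeric(n),
                    avg_build_height_m = numeric(n),
                    std_build_height_m = numeric(n),
                    no_buildings = logical(n), edge_flag = logical(n))
  rv <- residential$values; vv <- vegetation$values; hv <- building_height$values
  for (s in seq_len(n)) {
    jr <- which(abs(cx - x[s]) <= radius_m)
    ir <- which(abs(cy - y[s]) <= radius_m)
    if (!length(jr) || !length(ir)) stop("empty buffer for subject ", ids[s])
    dx2 <- (cx[jr] - x[s])^2
    dy2 <- (cy[ir] - y[s])^2
    inside <- outer(dy2, dx2, "+") <= radius_m^2
    rs <- rv[ir, jr, drop = FALSE][inside]
    vs <- vv[ir, jr, drop = FALSE][inside]
    hs <- hv[ir, jr, drop = FALSE][inside]
    valid <- !is.na(rs)
    n_valid <- sum(valid)
    if (n_valid == 0L) stop("empty buffer for subject ", ids[s])
    res$pct_residential[s] <- 100 * sum(rs[valid] == 1) / n_valid
    res$pct_vegetation[s] <- 100 * sum(vs[valid] == 1, na.rm = TRUE) / n_valid
    h <- hs[valid]
    built <- if (built_cells_only) h[h > 0] else h
    if (length(built) == 0L) {
      res$no_buildings[s] <- TRUE
    } else {
      res$avg_build_height_m[s] <- mean(built)
      res$std_build_height_m[s] <-
        if (length(built) > 1L) stats::sd(built) else 0
    }
    res$edge_flag[s] <- n_valid < 0.5 * full_n
  }
  res
}

#' Percentile-normalize a numeric vector to a 0-100 scale
#'
#' Hazen plotting position: `100 * (rank - 0.5) / n` with average ranks for
#' ties, computed over the non-missing values. Order-preserving and invariant
#' under strictly increasing transforms of the input.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector of percentiles in `[0, 100]`; `NA` stays `NA`.
#' @export
percentile_normalize <- function(values) {
  ok <- is.finite(values)
  if (!any(ok)) stop("`values` must contain at least one finite value")
  out <- rep(NA_real_, length(values))
  out[ok] <- 100 * (rank(values[ok], ties.method = "average") - 0.5) / sum(ok)
  out
}

#' Moving-window buffer-feature rasters
#'
#' Computes, for every cell of the mapping grid, the same four buffer
#' summaries as [buffer_features()] evaluated at the cell centre, using FFT
#' convolution with a disc kernel (identical centre-within-radius rule).
#' Used for mapping-stage layers covering areas without subjects, and as a
#' fast feature path for large simulated cohorts.
#'
#' @inheritParams buffer_features
#' @return list of [raster_layer()]: `pct_residential`, `pct_vegetation`,
#'   `avg_build_height_m`, `std_build_height_m`. Cells with an empty valid
#'   buffer are `NA`; cells without built cells get avg = std = 0.
#' @export
buffer_feature_rasters <- function(residential, vegetation, building_height,
                                   radius_m = 400) {
  check_registration(residential, vegetation, building_height)
  res_s <- focal_disc_sums(residential, radius_m, indicator = TRUE)
  veg_s <- focal_disc_sums(vegetation, radius_m, indicator = TRUE)
  h <- building_height
  built <- raster_layer((!is.na(h$values) & h$values > 0) * 1,
                        origin = h$origin, resolution_m = h$resolution_m)
  nb <- focal_disc_sums(built, radius_m, indicator = TRUE)$sum
  hs <- focal_disc_sums(h, radius_m)$sum
  h2 <- raster_layer(h$values^2, origin = h$origin,
                     resolution_m = h$resolution_m)
  h2s <- focal_disc_sums(h2, radius_m)$sum
  n_valid <- res_s$n
  pct_res <- 100 * res_s$sum / n_valid
  pct_veg <- 100 * veg_s$sum / n_valid
  pct_res[n_valid == 0] <- NA
  pct_veg[n_valid == 0] <- NA
  avg <- ifelse(nb > 0, hs / pmax(nb, 1), 0)
  var_ <- ifelse(nb > 1, (h2s - hs^2 / pmax(nb, 1)) / pmax(nb - 1, 1), 0)
  sd_ <- sqrt(pmax(var_, 0))
  avg[n_valid == 0] <- NA
  sd_[n_valid == 0] <- NA
  mk <- function(m) raster_layer(m, origin = residential$origin,
                                 resolution_m = residential$resolution_m)
  list(pct_residential = mk(pct_res), pct_vegetation = mk(pct_veg),
       avg_build_height_m = mk(avg), std_build_height_m = mk(sd_))
}

#' Percentile-normalize a raster citywide
#'
#' Applies [percentile_normalize()] over all valid cells of a layer, for
#' mapping-stage building-height normalization (the map covers areas without
#' subjects, so normalization is citywide rather than cohort-based).
#'
#' @param layer a [raster_layer()].
#' @return a [raster_layer()] of percentiles in `[0, 100]`.
#' @export
percentile_normalize_raster <- function(layer) {
  v <- layer$values
  out <- v
  ok <- !is.na(v)
  out[ok] <- percentile_normalize(v[ok])
  raster_layer(out, origin = layer$origin, resolution_m = layer$resolution_m)
}
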