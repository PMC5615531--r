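#' Construct a raster layer
#'
#' A minimal planar raster: a numeric (or integer-coded categorical) matrix
#' with a lower-left origin in metres and a square cell size. Row 1 of the
#' matrix is the *bottom* row of the grid; cells are half-open, i.e. cell
#' `(i, j)` covers `x in [x0 + (j-1)*res, x0 + j*res)` and
#' `y in [y0 + (i-1)*res, y0 + i*res)`. Missing cells are `NA`.
#'
#' @param values numeric matrix (row 1 = southernmost row).
#' @param origin length-2 numeric, `(x, y)` of the lower-left corner in metres.
#' @param resolution_m cell edge length in metres (> 0).
#' @param levels optional character vector naming integer codes of a
#'   categorical layer (e.g. land-use classes); code `k` means `levels[k]`.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(values, origin = c(0, 0), resolution_m = 10,
                         levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(resolution_m) || length(resolution_m) != 1L ||
      !is.finite(resolution_m) || resolution_m <= 0)
    stop("`resolution_m` must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite numbers")
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("raster cells must be finite or NA")
  structure(
    list(values = values, origin = as.numeric(origin),
         resolution_m = as.numeric(resolution_m), levels = levels),
    class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_layer: %d rows x %d cols @ %g m\n", d[1], d[2],
              x$resolution_m))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$origin[1], x$origin[1] + d[2] * x$resolution_m,
              x$origin[2], x$origin[2] + d[1] * x$resolution_m))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: min %g, mean %g, max %g (%d NA)\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  if (!is.null(x$levels))
    cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.raster_layer <- function(x, ...) x$values

#' Coordinates of cell centres
#'
#' @param layer a [raster_layer()].
#' @return list with `x` (column-centre eastings) and `y` (row-centre
#'   northings), in metres.
#' @export
cell_centers <- function(layer) {
  d <- dim(layer$values)
  r <- layer$resolution_m
  list(x = layer$origin[1] + (seq_len(d[2]) - 0.5) * r,
       y = layer$origin[2] + (seq_len(d[1]) - 0.5) * r)
}

raster_extent <- function(layer) {
  d <- dim(layer$values)
  c(xmin = layer$origin[1],
    xmax = layer$origin[1] + d[2] * layer$resolution_m,
    ymin = layer$origin[2],
    ymax = layer$origin[2] + d[1] * layer$resolution_m)
}

#' Check that raster layers share extent and registration
#'
#' @param ... two or more [raster_layer()] objects.
#' @return invisibly `TRUE`; errors if any layer differs in origin,
#'   resolution or dimensions.
#' @export
check_registration <- function(...) {
  ls <- list(...)
  ref <- ls[[1]]
  for (l in ls[-1]) {
    if (!isTRUE(all.equal(l$origin, ref$origin)) ||
        !isTRUE(all.equal(l$resolution_m, ref$resolution_m)) ||
        !identical(dim(l$values), dim(ref$values)))
      stop("raster layers are not co-registered (extent/origin/resolution differ)")
  }
  invisible(TRUE)
}

# row/col of the cell containing each point under the half-open convention.
# Returns a list(i, j); points outside the extent get NA indices.
point_cell <- function(layer, x, y) {
  r <- layer$resolution_m
  j <- floor((x - layer$origin[1]) / r) + 1L
  i <- floor((y - layer$origin[2]) / r) + 1L
  d <- dim(layer$values)
  bad <- i < 1L | i > d[1] | j < 1L | j > d[2]
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  list(i = as.integer(i), j = as.integer(j))
}

#' Resample a raster by nearest neighbour
#'
#' The value at any coordinate is the value of the source cell containing it,
#' so refinement to a finer grid is value-preserving and resampling to the
#' same resolution is the identity.
#'
#' @param layer a [raster_layer()].
#' @param target_resolution_m new cell size in metres (> 0).
#' @return a [raster_layer()] covering the same extent.
#' @export
resample_raster <- function(layer, target_resolution_m) {
  if (!is.numeric(target_resolution_m) || length(target_resolution_m) != 1L ||
      !is.finite(target_resolution_m) || target_resolution_m <= 0)
    stop("`target_resolution_m` must be a single positive number")
  ext <- raster_extent(layer)
  nx <- max(1L, round((ext["xmax"] - ext["xmin"]) / target_resolution_m))
  ny <- max(1L, round((ext["ymax"] - ext["ymin"]) / target_resolution_m))
  cx <- layer$origin[1] + (seq_len(nx) - 0.5) * target_resolution_m
  cy <- layer$origin[2] + (seq_len(ny) - 0.5) * target_resolution_m
  jj <- pmin.int(dim(layer$values)[2],
                 pmax.int(1L, floor((cx - layer$origin[1]) / layer$resolution_m) + 1L))
  ii <- pmin.int(dim(layer$values)[1],
                 pmax.int(1L, floor((cy - layer$origin[2]) / layer$resolution_m) + 1L))
  raster_layer(layer$values[ii, jj, drop = FALSE], origin = layer$origin,
               resolution_m = target_resolution_m, levels = layer$levels)
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point under the half-open
#' cell convention (`x in [x0, x0 + res)`). Points on `NA` cells return `NA`
#' so callers can flag and exclude them.
#'
#' @param layer a [raster_layer()].
#' @param x,y point coordinates in metres.
#' @param ids optional identifiers used in the error message for points
#'   falling outside the raster extent.
#' @return numeric vector of cell values.
#' @export
extract_at_points <- function(layer, x, y, ids = seq_along(x)) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  ij <- point_cell(layer, x, y)
  out <- is.na(ij$i)
  if (any(out))
    stop("points outside raster extent: ",
         paste(utils::head(ids[out], 10L), collapse = ", "),
         if (sum(out) > 10L) sprintf(" (and %d more)", sum(out) - 10L) else "")
  layer$values[cbind(ij$i, ij$j)]
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/nodata_value` header followed by rows north to south). Categorical
#' levels, if any, are written to a `<path>.levels.json` sidecar.
#'
#' @param layer a [raster_layer()].
#' @param path output file path (conventionally `.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  d <- dim(layer$values)
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", layer$origin[1]),
           sprintf("yllcorner %.10g", layer$origin[2]),
           sprintf("cellsize %.10g", layer$resolution_m),
           sprintf("nodata_value %.10g", nodata))
  v <- layer$values
  v[is.na(v)] <- nodata
  rows <- vapply(rev(seq_len(d[1])), function(i)
    paste(formatC(v[i, ], format = "g", digits = 15), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), path)
  if (!is.null(layer$levels))
    jsonlite::write_json(layer$levels, paste0(path, ".levels.json"))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @return a [raster_layer()]; the nodata sentinel becomes `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  ncols <- as.integer(val["ncols"]); nrows <- as.integer(val["nrows"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != ncols * nrows)
    stop("malformed ASCII grid: expected ", ncols * nrows, " cells, got ",
         length(body))
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]  # file is north-to-south
  m[m == val["nodata_value"]] <- NA
  lv <- NULL
  side <- paste0(path, ".levels.json")
  if (file.exists(side)) lv <- unlist(jsonlite::read_json(side))
  raster_layer(m, origin = c(val["xllcorner"], val["yllcorner"]),
               resolution_m = val["cellsize"], levels = lv)
}

# ---- moving-window (focal) disc statistics via FFT convolution ----

# 0/1 disc kernel of cell offsets whose centre-to-centre distance <= radius.
disc_kernel <- function(resolution_m, radius_m) {
  k <- floor(radius_m / resolution_m)
  off <- (-k):k
  d2 <- outer(off^2, off^2, "+") * resolution_m^2
  (d2 <= radius_m^2) * 1
}

# full 2-D convolution by FFT, returning the "same"-sized central part so
# out[i, j] = sum_k K[k] * A[i + off_k]. A must be finite (no NA).
conv2d_same <- function(A, K) {
  da <- dim(A); dk <- dim(K)
  n1 <- da[1] + dk[1] - 1L; n2 <- da[2] + dk[2] - 1L
  Ap <- matrix(0, n1, n2); Ap[seq_len(da[1]), seq_len(da[2])] <- A
  Kp <- matrix(0, n1, n2); Kp[seq_len(dk[1]), seq_len(dk[2])] <- K
  full <- Re(stats::fft(stats::fft(Ap) * stats::fft(Kp), inverse = TRUE)) / (n1 * n2)
  r0 <- (dk[1] - 1L) / 2L; c0 <- (dk[2] - 1L) / 2L
  full[r0 + seq_len(da[1]), c0 + seq_len(da[2])]
}

# Focal sums of `values` (NA treated as 0) and of the valid-cell indicator,
# over a centre-within-radius disc. Counts are rounded to kill FFT noise.
focal_disc_sums <- function(layer, radius_m, indicator = FALSE) {
  K <- disc_kernel(layer$resolution_m, radius_m)
  v <- layer$values
  ok <- !is.na(v)
  v[!ok] <- 0
  s <- conv2d_same(v, K)
  n <- round(conv2d_same(ok * 1, K))
  if (indicator) s <- round(s)
  list(sum = s, n = n)
}
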