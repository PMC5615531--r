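#' Write and read the cohort table as CSV
#'
#' The documented header is: `id, x, y, older_age, male, not_married,
#' low_education, living_alone, dementia, cardiovascular, respiratory,
#' smoking, alcohol, physical_activity, gds15`. Missing values are empty
#' fields.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[cohort_schema()[cohort_schema() %in% names(cohort)]],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

cohort_schema <- function() {
  c("id", "x", "y", "older_age", "male", "not_married", "low_education",
    "living_alone", "dementia", "cardiovascular", "respiratory", "smoking",
    "alcohol", "physical_activity", "gds15")
}

#' @rdname write_cohort_csv
#' @param check_gds15 require the `gds15` outcome column (default `TRUE`).
#' @export
read_cohort_csv <- function(path, check_gds15 = TRUE) {
  d <- utils::read.csv(path)
  need <- setdiff(cohort_schema(), if (check_gds15) NULL else "gds15")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort CSV schema error; missing column(s): ",
         paste(miss, collapse = ", "))
  bin <- c("older_age", "male", "not_married", "low_education",
           "living_alone", "dementia", "cardiovascular", "respiratory",
           "smoking", "alcohol")
  for (b in bin) {
    bad <- which(!(d[[b]] %in% c(0, 1, NA)))
    if (length(bad))
      stop("column `", b, "` not binary at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("gds15" %in% names(d)) {
    bad <- which(!(is.na(d$gds15) | (d$gds15 >= 0 & d$gds15 <= 15)))
    if (length(bad))
      stop("`gds15` outside [0, 15] at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  d
}

#' Write and read the planning-unit grid as GeoJSON
#'
#' Each TPU becomes a Polygon feature (rectangle ring, closed,
#' counter-clockwise) with `tpu_id` and the `pct_*` attribute columns as
#' properties.
#'
#' @param tpus TPU data.frame.
#' @param path GeoJSON path.
#' @return `path` invisibly.
#' @export
write_tpu_geojson <- function(tpus, path) {
  props <- setdiff(names(tpus), c("xmin", "xmax", "ymin", "ymax"))
  feats <- lapply(seq_len(nrow(tpus)), function(k) {
    ring <- list(c(tpus$xmin[k], tpus$ymin[k]), c(tpus$xmax[k], tpus$ymin[k]),
                 c(tpus$xmax[k], tpus$ymax[k]), c(tpus$xmin[k], tpus$ymax[k]),
                 c(tpus$xmin[k], tpus$ymin[k]))
    list(type = "Feature",
         properties = as.list(tpus[k, props, drop = FALSE]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tpu_geojson
#' @param extent_m optional city extent; if given, a warning is raised when
#'   the zones' total area differs from the extent area (overlap or gap).
#' @export
read_tpu_geojson <- function(path, extent_m = NULL) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) stop("not a FeatureCollection")
  rows <- lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    c(list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys)),
      f$properties)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (!is.null(extent_m)) {
    area <- sum((out$xmax - out$xmin) * (out$ymax - out$ymin))
    if (abs(area - extent_m^2) > 1e-6 * extent_m^2)
      warning(sprintf(
        "TPU polygons cover %.4g m^2 but the extent is %.4g m^2 (overlap or gap)",
        area, extent_m^2))
  }
  out[c("tpu_id", "xmin", "xmax", "ymin", "ymax",
        setdiff(names(out), c("tpu_id", "xmin", "xmax", "ymin", "ymax")))]
}

#' Pipeline configuration
#'
#' @param city a [city_config()] (used when `simulate = TRUE`).
#' @param simulate generate the synthetic study (`TRUE`) or read inputs
#'   from `input_dir` (`FALSE`).
#' @param input_dir directory with `land_use.asc`, `vegetation.asc`,
#'   `building_height.asc`, `cohort.csv`, `tpu.geojson` when
#'   `simulate = FALSE`.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param radius_m buffer radius in metres.
#' @param features_at `"point"` or `"cell"` (see [synth_study()]).
#' @param round_or_digits OR rounding used for index weights (default 2,
#'   the presentation precision; `NULL` = unrounded).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(city = city_config(), simulate = TRUE,
                            input_dir = NULL, out_dir = NULL,
                            radius_m = 400, features_at = "cell",
                            round_or_digits = 2) {
  structure(list(city = city, simulate = simulate, input_dir = input_dir,
                 out_dir = out_dir, radius_m = radius_m,
                 features_at = features_at,
                 round_or_digits = round_or_digits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' City fields go under a `city:` block (`extent_m`, `n_subjects`, `seed`,
#' ...); top-level fields mirror [pipeline_config()] arguments. Round-trips
#' losslessly with [write_pipeline_yaml()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  city_args <- y$city %||% list()
  if (!is.null(city_args$true_betas))
    city_args$true_betas <- unlist(city_args$true_betas)
  if (!is.null(city_args$marginals))
    city_args$marginals <- unlist(city_args$marginals)
  if (!is.null(city_args$confounder_marginals))
    city_args$confounder_marginals <- unlist(city_args$confounder_marginals)
  city <- do.call(city_config, city_args)
  args <- y[setdiff(names(y), "city")]
  do.call(pipeline_config, c(list(city = city), args))
}

#' @rdname read_pipeline_yaml
#' @param config a `pipeline_config`.
#' @export
write_pipeline_yaml <- function(config, path) {
  y <- unclass(config)
  city <- unclass(y$city)
  # named vectors go out as YAML maps so names survive the round trip
  for (nm in c("true_betas", "marginals", "confounder_marginals"))
    city[[nm]] <- as.list(city[[nm]])
  y$city <- city
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole vulnerability-mapping pipeline
#'
#' Executes simulate (optional) -> extract buffer features -> fit Models
#' 1-3 -> derive index weights from the Model-3 adjusted ORs -> map the
#' index at the city's base resolution -> aggregate to planning units ->
#' validate the map at subject locations. Every stage appends its sample
#' sizes and parameters to a run log; when `out_dir` is set, rasters
#' (.asc), the cohort (CSV), TPU summaries (GeoJSON) and the fit/validation
#' results (JSON) are written there.
#'
#' @param config a [pipeline_config()].
#' @return list with `data` (analytic table), `fits` (Models 1-3),
#'   `weights`, `map` ([map_vulnerability()] output), `validation`, `tpus`,
#'   `log` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  if (config$simulate) {
    st <- synth_study(config$city, radius_m = config$radius_m,
                      features_at = config$features_at)
    say("simulate: n=%d subjects, %d cases / %d controls, seed=%d",
        nrow(st$cohort), sum(st$cohort$case, na.rm = TRUE),
        sum(st$cohort$case == 0, na.rm = TRUE), config$city$seed)
    rasters <- st$rasters; tpus <- st$tpus
    cohort <- st$cohort; feats <- st$features
  } else {
    if (is.null(config$input_dir)) stop("`input_dir` required when simulate = FALSE")
    rasters <- list(
      land_use = read_ascii_grid(file.path(config$input_dir, "land_use.asc")),
      vegetation = read_ascii_grid(file.path(config$input_dir, "vegetation.asc")),
      building_height = read_ascii_grid(file.path(config$input_dir,
                                                  "building_height.asc")))
    check_registration(rasters$land_use, rasters$vegetation,
                       rasters$building_height)
    cohort <- read_cohort_csv(file.path(config$input_dir, "cohort.csv"))
    tpus <- read_tpu_geojson(file.path(config$input_dir, "tpu.geojson"))
    residential <- binarize_landuse(rasters$land_use)
    feats <- buffer_features(cohort$x, cohort$y, residential,
                             rasters$vegetation, rasters$building_height,
                             radius_m = config$radius_m, ids = cohort$id)
    say("extract: %d subjects, %g-m buffers", nrow(cohort), config$radius_m)
  }
  d <- prepare_analysis_data(cohort, feats)
  cc <- complete_case_filter(d, c("case", model_terms(3)))
  say("complete-case: %d retained, %d removed", nrow(cc$data), cc$n_removed)
  say("cases/controls after filtering: %d / %d", sum(cc$data$case),
      sum(cc$data$case == 0))
  fits <- lapply(1:3, function(m) fit_depression_model(cc$data, m))
  names(fits) <- paste0("model", 1:3)
  say("fit: model 3 loglik %.2f, converged %s, n_used %d",
      fits$model3$loglik, fits$model3$converged, fits$model3$n_used)
  ors <- adjusted_ors(fits$model3)
  ors <- ors[ors$term %in% candidate_index_terms(), , drop = FALSE]
  weights <- derive_weights(ors, kinds = binary_kinds(),
                            round_digits = config$round_or_digits)
  say("weights: %s", paste(sprintf("%s=%+g", weights$name, weights$weight),
                           collapse = ", "))
  mp <- map_vulnerability(weights, rasters, tpus, radius_m = config$radius_m)
  say("map: index range [%.3f, %.3f] over %d TPUs",
      min(mp$vuln$values, na.rm = TRUE), max(mp$vuln$values, na.rm = TRUE),
      nrow(mp$tpu_summary))
  val <- validate_index_raster(mp$vuln, cc$data)
  say("validate: OR per 0.1 = %.3f (%.3f, %.3f), n=%d",
      val$or_per_scale_unit$or, val$or_per_scale_unit$ci_low,
      val$or_per_scale_unit$ci_high, val$n_subjects)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_ascii_grid(mp$vuln, file.path(od, "vuln_index.asc"))
    write_cohort_csv(cohort, file.path(od, "cohort.csv"))
    write_tpu_geojson(cbind(tpus,
                            index_mean = mp$tpu_summary$index_mean,
                            index_binned = mp$tpu_summary$index_binned),
                      file.path(od, "tpu_index.geojson"))
    jsonlite::write_json(
      list(weights = weights,
           model3 = list(beta = fits$model3$coefficients,
                         se = fits$model3$se,
                         n_used = fits$model3$n_used,
                         loglik = fits$model3$loglik,
                         converged = fits$model3$converged),
           validation = list(or_per_0.1 = val$or_per_scale_unit$or,
                             ci = c(val$or_per_scale_unit$ci_low,
                                    val$or_per_scale_unit$ci_high),
                             n = val$n_subjects),
           log = log),
      file.path(od, "results.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
    say("wrote outputs to %s", od)
  }
  list(data = cc$data, fits = fits, weights = weights, map = mp,
       validation = val, tpus = tpus, log = log)
}
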