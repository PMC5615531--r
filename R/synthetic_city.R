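#' Configuration for the synthetic city and cohort
#'
#' Bundles every knob of the synthetic study: city geometry, planning units,
#' cohort size, covariate marginals, and the true outcome model. Defaults
#' emulate the study conditions of the source cohort: ~4000 subjects aged
#' 65+, case prevalence 364/3930 (9.26%), control-group covariate marginals
#' (older ages 9.5%, male 50.5%, not married 28.1%, low education 65.5%,
#' living alone 12.9%), a strong positive dependence between not-married and
#' living-alone (Pearson r 0.55), and built-environment heterogeneity giving
#' a strongly positive correlation (~0.8) between average and standard
#' deviation of building height over 400-m buffers.
#'
#' `true_betas` holds the 16 coefficients of the outcome model, in the
#' order: intercept, older_age, male, not_married, low_education,
#' living_alone, pct_residential, pct_vegetation, avg_build_height_pctile,
#' std_build_height_pctile, dementia, physical_activity, cardiovascular,
#' respiratory, alcohol, smoking. Continuous environmental terms are on
#' their 0-100 scales and physical activity on its standardized scale, so
#' coefficients are directly comparable to fitted log odds ratios. Defaults
#' use the published adjusted effect sizes for the social/environmental
#' terms and modest assumed effects for the lifestyle/medical confounders.
#'
#' @param extent_m side of the square city in metres.
#' @param base_resolution_m raster cell size (must divide `extent_m`).
#' @param n_tpu number of rectangular planning units (a perfect square works
#'   best; tiles are arranged on a near-square grid).
#' @param n_subjects cohort size.
#' @param seed integer random seed; every generated artifact is a
#'   deterministic function of it.
#' @param true_betas numeric length 16, see Details.
#' @param prevalence_target expected case fraction used to calibrate the
#'   intercept; `NULL` keeps `true_betas[1]` as is.
#' @param residential_fraction target fraction of city cells that are
#'   residential.
#' @param vegetation_fraction target fraction of vegetated cells.
#' @param marginals named vector of Bernoulli rates for `older_age`, `male`,
#'   `not_married`, `low_education`, `living_alone`.
#' @param nm_la_corr target Pearson correlation between not_married and
#'   living_alone.
#' @param confounder_marginals named rates for the binary lifestyle/medical
#'   confounders.
#' @param missing_rate fraction of cohort rows given one missing analysis
#'   value (default 0.35%, i.e. ~14 of 4000).
#' @return object of class `city_config`.
#' @export
city_config <- function(extent_m = 4000, base_resolution_m = 10, n_tpu = 64,
                        n_subjects = 4000, seed = 1,
                        true_betas = default_true_betas(),
                        prevalence_target = 364 / 3930,
                        residential_fraction = 0.33,
                        vegetation_fraction = 0.23,
                        marginals = c(older_age = 0.095, male = 0.505,
                                      not_married = 0.281,
                                      low_education = 0.655,
                                      living_alone = 0.129),
                        nm_la_corr = 0.55,
                        confounder_marginals = c(dementia = 0.07,
                                                 cardiovascular = 0.25,
                                                 respiratory = 0.12,
                                                 alcohol = 0.15,
                                                 smoking = 0.30),
                        missing_rate = 0.0035) {
  if (extent_m <= 0) stop("`extent_m` must be positive")
  if (n_subjects < 0) stop("`n_subjects` must be non-negative")
  if (length(true_betas) != 16L) stop("`true_betas` must have 16 entries")
  if (abs(extent_m / base_resolution_m -
          round(extent_m / base_resolution_m)) > 1e-9)
    stop("`base_resolution_m` must divide `extent_m`")
  need <- c("older_age", "male", "not_married", "low_education",
            "living_alone")
  if (!all(need %in% names(marginals)))
    stop("`marginals` must name: ", paste(need, collapse = ", "))
  structure(list(extent_m = extent_m, base_resolution_m = base_resolution_m,
                 n_tpu = n_tpu, n_subjects = n_subjects, seed = seed,
                 true_betas = true_betas,
                 prevalence_target = prevalence_target,
                 residential_fraction = residential_fraction,
                 vegetation_fraction = vegetation_fraction,
                 marginals = marginals, nm_la_corr = nm_la_corr,
                 confounder_marginals = confounder_marginals,
                 missing_rate = missing_rate),
            class = "city_config")
}

#' Default true coefficients of the synthetic outcome model
#'
#' Social and environmental log odds ratios match the published adjusted
#' estimates (ORs 1.26, 1.13, 1.24, 1.60, 1.31 for the social indicators;
#' 1.01, 1.00, 0.98, 1.03 per percentage point for the environmental
#' measures); confounder effects are assumed values, stated as such.
#'
#' @return named numeric vector of length 16.
#' @export
default_true_betas <- function() {
  c(intercept = -2.5,
    older_age = log(1.26), male = log(1.13), not_married = log(1.24),
    low_education = log(1.60), living_alone = log(1.31),
    pct_residential = log(1.01), pct_vegetation = 0,
    avg_build_height_pctile = log(0.98), std_build_height_pctile = log(1.03),
    dementia = log(2.0), physical_activity = log(0.85),
    cardiovascular = log(1.2), respiratory = log(1.2),
    alcohol = log(1.1), smoking = log(1.2))
}

model_covariates <- function() {
  c("older_age", "male", "not_married", "low_education", "living_alone",
    "pct_residential", "pct_vegetation", "avg_build_height_pctile",
    "std_build_height_pctile", "dementia", "physical_activity",
    "cardiovascular", "respiratory", "alcohol", "smoking")
}

# land-use legend of the synthetic city; first three are residential
landuse_levels <- function() {
  c("private residential", "public residential", "rural settlement",
    "commercial", "industrial", "open space", "road")
}

# paint a random rectangle of cells (in cell index space) with a value
paint_rect <- function(m, value, min_side, max_side) {
  d <- dim(m)
  w <- sample.int(max_side - min_side + 1L, 1L) + min_side - 1L
  h <- sample.int(max_side - min_side + 1L, 1L) + min_side - 1L
  i0 <- sample.int(max(d[1] - h + 1L, 1L), 1L)
  j0 <- sample.int(max(d[2] - w + 1L, 1L), 1L)
  m[i0:min(i0 + h - 1L, d[1]), j0:min(j0 + w - 1L, d[2])] <- value
  m
}

#' Generate the synthetic city rasters
#'
#' Builds three co-registered layers with a blocky patch structure: a
#' categorical land-use layer (rectangular residential estates of the three
#' residential classes over a non-residential background), a 0/1 vegetation
#' mask (rectangular patches), and a building-height layer. Buildings are
#' clustered footprints: each estate draws a height scale (lognormal across
#' estates) and its buildings draw heights around that scale with large
#' within-estate spread, so 400-m buffer averages and standard deviations of
#' height are spatially autocorrelated and strongly positively correlated
#' with each other.
#'
#' @param config a [city_config()].
#' @return list of [raster_layer()]: `land_use`, `vegetation`,
#'   `building_height`. Deterministic function of `config$seed`.
#' @export
generate_rasters <- function(config) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed)
  n <- as.integer(round(config$extent_m / config$base_resolution_m))
  lu <- matrix(6, n, n)                       # open space background
  for (k in seq_len(max(2L, round(n * n / 8000)))) {
    lu <- paint_rect(lu, sample(c(4, 5, 7), 1L), max(2L, n %/% 20), max(3L, n %/% 6))
  }
  # residential estates until the target fraction is reached
  estate_id <- matrix(0L, n, n)
  target <- config$residential_fraction
  if (target >= 1) {
    lu[] <- sample(1:3, n * n, replace = TRUE)
    estate_id[] <- sample.int(max(4L, config$n_tpu), n * n, replace = TRUE)
  } else {
    e <- 0L
    guard <- 0L
    while (mean(lu <= 3) < target && guard < 10000L) {
      e <- e + 1L; guard <- guard + 1L
      cls <- sample(1:3, 1L, prob = c(0.45, 0.35, 0.20))
      side_min <- max(2L, n %/% 40)            # ~100 m estates
      side_max <- max(3L, n %/% 10)            # ~400 m estates
      mask <- matrix(FALSE, n, n)
      mask <- paint_rect(mask, TRUE, side_min, side_max)
      lu[mask] <- cls
      estate_id[mask] <- e
    }
  }
  # vegetation patches
  veg <- matrix(0, n, n)
  guard <- 0L
  while (mean(veg) < config$vegetation_fraction && guard < 10000L) {
    guard <- guard + 1L
    veg <- paint_rect(veg, 1, max(2L, n %/% 25), max(3L, n %/% 5))
  }
  # buildings: mostly on residential estates, a few on commercial patches
  h <- matrix(0, n, n)
  n_estates <- max(estate_id)
  if (n_estates > 0L) {
    scale_e <- exp(stats::rnorm(n_estates, mean = log(26), sd = 0.45))
    fill_e <- stats::runif(n_estates, 0.35, 0.75)
    res_cells <- which(estate_id > 0L)
    u <- stats::runif(length(res_cells))
    built <- res_cells[u < fill_e[estate_id[res_cells]]]
    if (length(built))
      h[built] <- scale_e[estate_id[built]] *
        exp(stats::rnorm(length(built), mean = 0, sd = 0.65))
  }
  com <- which(lu == 4)
  if (length(com)) {
    u <- stats::runif(length(com))
    cb <- com[u < 0.3]
    if (length(cb))
      h[cb] <- exp(stats::rnorm(length(cb), mean = log(30), sd = 0.7))
  }
  mk <- function(v, levels = NULL)
    raster_layer(v, origin = c(0, 0), resolution_m = config$base_resolution_m,
                 levels = levels)
  list(land_use = mk(lu, levels = landuse_levels()),
       vegetation = mk(veg), building_height = mk(h))
}

#' Generate the planning-unit (TPU) grid
#'
#' Tiles the city extent with `n_tpu` rectangular zones on a near-square
#' grid and assigns each a census-style percentage of low-educated
#' population, drawn around the cohort marginal (mean 65.5%).
#'
#' @param config a [city_config()].
#' @return data.frame with `tpu_id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `pct_low_education`.
#' @export
generate_tpu <- function(config) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed + 7L)
  nz <- max(1L, config$n_tpu)
  ncol_z <- ceiling(sqrt(nz))
  nrow_z <- ceiling(nz / ncol_z)
  xs <- seq(0, config$extent_m, length.out = ncol_z + 1)
  ys <- seq(0, config$extent_m, length.out = nrow_z + 1)
  grid <- expand.grid(cx = seq_len(ncol_z), cy = seq_len(nrow_z))
  grid <- grid[seq_len(min(nrow(grid), nz)), , drop = FALSE]
  out <- data.frame(tpu_id = seq_len(nrow(grid)),
                    xmin = xs[grid$cx], xmax = xs[grid$cx + 1],
                    ymin = ys[grid$cy], ymax = ys[grid$cy + 1])
  ab <- 20                                       # Beta concentration
  for (nm in names(config$marginals)) {
    mu <- unname(config$marginals[nm])
    out[[paste0("pct_", nm)]] <-
      100 * stats::rbeta(nrow(grid), mu * ab, (1 - mu) * ab)
  }
  out
}

#' Generate the synthetic cohort (without outcomes)
#'
#' Places `n_subjects` uniformly on residential cells (uniform within the
#' cell), then draws the five binary social indicators at the configured
#' marginals. Not-married and living-alone are drawn jointly from the 2x2
#' distribution matching their marginals and the target Pearson correlation
#' (0.55 by default); the remaining indicators are independent. Lifestyle
#' and medical confounders are independent of the exposures: binary rates
#' from `confounder_marginals` plus a non-negative physical-activity score
#' (gamma, mean 100) emulating a PASE-like scale.
#'
#' @param config a [city_config()].
#' @param land_use categorical [raster_layer()] from [generate_rasters()].
#' @return data.frame (one row per subject): `id`, `x`, `y`, binary
#'   indicators, confounders, `physical_activity`.
#' @export
generate_cohort <- function(config, land_use) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  cols <- c("id", "x", "y", "older_age", "male", "not_married",
            "low_education", "living_alone", "dementia", "cardiovascular",
            "respiratory", "smoking", "alcohol", "physical_activity")
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  res_codes <- which(land_use$levels %in% c("private residential",
                                            "public residential",
                                            "rural settlement"))
  res_cells <- which(land_use$values %in% res_codes)
  if (!length(res_cells)) stop("land-use layer has no residential cells")
  d <- dim(land_use$values)
  pick <- res_cells[sample.int(length(res_cells), n, replace = TRUE)]
  i <- (pick - 1L) %% d[1] + 1L
  j <- (pick - 1L) %/% d[1] + 1L
  r <- land_use$resolution_m
  # uniform within the half-open cell so the point maps back to that cell
  x <- land_use$origin[1] + (j - 1L) * r + stats::runif(n) * r * (1 - 1e-9)
  y <- land_use$origin[2] + (i - 1L) * r + stats::runif(n) * r * (1 - 1e-9)
  m <- config$marginals
  # joint draw of (not_married, living_alone) at the target phi coefficient
  p1 <- unname(m["not_married"]); p2 <- unname(m["living_alone"])
  phi <- config$nm_la_corr
  p11 <- p1 * p2 + phi * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- min(max(p11, 0), min(p1, p2))     # clamp to the Frechet bounds
  cell <- sample.int(4L, n, replace = TRUE,
                     prob = c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11))
  nm <- as.integer(cell %in% c(1L, 2L))
  la <- as.integer(cell %in% c(1L, 3L))
  cm <- config$confounder_marginals
  data.frame(id = seq_len(n), x = x, y = y,
             older_age = stats::rbinom(n, 1, m["older_age"]),
             male = stats::rbinom(n, 1, m["male"]),
             not_married = nm,
             low_education = stats::rbinom(n, 1, m["low_education"]),
             living_alone = la,
             dementia = stats::rbinom(n, 1, cm["dementia"]),
             cardiovascular = stats::rbinom(n, 1, cm["cardiovascular"]),
             respiratory = stats::rbinom(n, 1, cm["respiratory"]),
             smoking = stats::rbinom(n, 1, cm["smoking"]),
             alcohol = stats::rbinom(n, 1, cm["alcohol"]),
             physical_activity = stats::rgamma(n, shape = 4, scale = 25))
}

#' Simulate depression outcomes from the true logistic model
#'
#' Each subject's case probability is the inverse logit of the linear
#' predictor at `config$true_betas`, evaluated on the modelling scales
#' (percentile-normalized building heights 0-100, standardized physical
#' activity). If `config$prevalence_target` is set, the intercept is
#' recalibrated (one-dimensional root find) so the cohort's expected case
#' fraction equals the target. The case indicator is Bernoulli; GDS-15 is
#' then drawn uniform on 8-15 for cases and 0-7 for controls, so the score
#' dichotomy at >= 8 reproduces the indicator exactly.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param features data.frame aligned to `cohort` rows with columns
#'   `pct_residential`, `pct_vegetation`, `avg_build_height_pctile`,
#'   `std_build_height_pctile` (see [buffer_features()] and
#'   [percentile_normalize()]).
#' @param config a [city_config()].
#' @return `cohort` with added columns `case` (0/1), `gds15` (0-15) and
#'   `true_p` (the simulation probability).
#' @export
simulate_outcomes <- function(cohort, features, config) {
  stopifnot(inherits(config, "city_config"))
  if (nrow(cohort) != nrow(features))
    stop("`features` rows (", nrow(features),
         ") do not align with `cohort` rows (", nrow(cohort), ")")
  set.seed(config$seed + 2L)
  n <- nrow(cohort)
  if (n == 0L) {
    cohort$case <- integer(0); cohort$gds15 <- integer(0)
    cohort$true_p <- numeric(0)
    return(cohort)
  }
  pa <- cohort$physical_activity
  pa_std <- if (stats::sd(pa) > 0) (pa - mean(pa)) / stats::sd(pa) else pa * 0
  X <- cbind(cohort$older_age, cohort$male, cohort$not_married,
             cohort$low_education, cohort$living_alone,
             features$pct_residential, features$pct_vegetation,
             features$avg_build_height_pctile,
             features$std_build_height_pctile,
             cohort$dementia, pa_std, cohort$cardiovascular,
             cohort$respiratory, cohort$alcohol, cohort$smoking)
  beta <- config$true_betas
  eta <- drop(X %*% beta[-1])
  b0 <- beta[1]
  if (!is.null(config$prevalence_target)) {
    tgt <- config$prevalence_target
    f <- function(b) mean(stats::plogis(b + eta)) - tgt
    b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  p <- stats::plogis(b0 + eta)
  case <- stats::rbinom(n, 1, p)
  gds <- ifelse(case == 1L, sample(8:15, n, replace = TRUE),
                sample(0:7, n, replace = TRUE))
  cohort$case <- case
  cohort$gds15 <- as.integer(gds)
  cohort$true_p <- p
  cohort
}

#' Inject missing values into a cohort table
#'
#' Marks `round(rate * n)` randomly chosen rows as incomplete by setting one
#' randomly chosen analysis field to `NA`, to exercise complete-case
#' filtering at a realistic rate (default 0.35% of rows, ~14 in 4000).
#'
#' @param cohort data.frame.
#' @param rate fraction of rows to degrade.
#' @param columns candidate columns for the missing value.
#' @param seed integer seed.
#' @return cohort with injected `NA`s.
#' @export
inject_missing <- function(cohort, rate = 0.0035,
                           columns = c("older_age", "male", "not_married",
                                       "low_education", "living_alone",
                                       "gds15", "physical_activity"),
                           seed = 1) {
  set.seed(seed)
  n_bad <- round(rate * nrow(cohort))
  if (n_bad == 0L) return(cohort)
  rows <- sample.int(nrow(cohort), n_bad)
  cols <- sample(columns, n_bad, replace = TRUE)
  for (k in seq_len(n_bad)) cohort[rows[k], cols[k]] <- NA
  cohort
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator: rasters, planning units, cohort, buffer
#' features at each subject's address, cohort-based percentile
#' normalization of the building-height features, outcome simulation, and
#' (optionally) missingness injection. `features_at = "cell"` evaluates
#' buffer features at the subject's containing-cell centre from
#' moving-window rasters (fast path for large simulation studies, at most
#' half a cell of displacement); `"point"` evaluates at the exact address.
#'
#' @param config a [city_config()].
#' @param radius_m buffer radius (default 400 m).
#' @param features_at `"cell"` or `"point"`, see Description.
#' @param inject_missingness logical; apply [inject_missing()] at
#'   `config$missing_rate`.
#' @return list with `config`, `rasters`, `residential` (binarized),
#'   `tpus`, `cohort` (with outcomes), `features` (aligned to cohort,
#'   including percentile columns), `feature_rasters` (when
#'   `features_at = "cell"`).
#' @export
synth_study <- function(config = city_config(), radius_m = 400,
                        features_at = c("cell", "point"),
                        inject_missingness = TRUE) {
  features_at <- match.arg(features_at)
  rasters <- generate_rasters(config)
  tpus <- generate_tpu(config)
  residential <- binarize_landuse(rasters$land_use)
  cohort <- generate_cohort(config, rasters$land_use)
  feature_rasters <- NULL
  if (features_at == "cell") {
    feature_rasters <- buffer_feature_rasters(residential,
                                              rasters$vegetation,
                                              rasters$building_height,
                                              radius_m = radius_m)
    feats <- data.frame(
      pct_residential = extract_at_points(feature_rasters$pct_residential,
                                          cohort$x, cohort$y, cohort$id),
      pct_vegetation = extract_at_points(feature_rasters$pct_vegetation,
                                         cohort$x, cohort$y, cohort$id),
      avg_build_height_m = extract_at_points(
        feature_rasters$avg_build_height_m, cohort$x, cohort$y, cohort$id),
      std_build_height_m = extract_at_points(
        feature_rasters$std_build_height_m, cohort$x, cohort$y, cohort$id))
  } else {
    feats <- buffer_features(cohort$x, cohort$y, residential,
                             rasters$vegetation, rasters$building_height,
                             radius_m = radius_m, ids = cohort$id)
  }
  feats$avg_build_height_pctile <- percentile_normalize(feats$avg_build_height_m)
  feats$std_build_height_pctile <- percentile_normalize(feats$std_build_height_m)
  cohort <- simulate_outcomes(cohort, feats, config)
  if (inject_missingness && config$missing_rate > 0)
    cohort <- inject_missing(cohort, rate = config$missing_rate,
                             seed = config$seed + 3L)
  list(config = config, rasters = rasters, residential = residential,
       tpus = tpus, cohort = cohort, features = feats,
       feature_rasters = feature_rasters)
}
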