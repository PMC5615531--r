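#' Validate the mapped vulnerability index against the cohort outcome
#'
#' The four-step validation of the index map: (1) extract the mapped index
#' at each subject's location (done by the caller or
#' [validate_index_raster()]), (2) refit the outcome on the index *alone*
#' (univariate logistic), (3) report the OR and 95% Wald CI, (4) rescale to
#' a 0.1-point index increase — the map's scale unit — as
#' `exp(0.1 * beta)`, with the CI rescaled on the coefficient (identical by
#' algebra to pre-dividing the index by 0.1).
#'
#' @param index_values numeric vulnerability-index value per subject.
#' @param outcomes 0/1 case indicators aligned to `index_values`.
#' @return object of class `vuln_validation`: list with `or_per_scale_unit`
#'   (one-row `or_table` for a 0.1-point increase), `or_per_unit`,
#'   `pct_risk_increase_per_0.1`, `n_subjects`, `n_excluded` (subjects on
#'   nodata cells), `fit`.
#' @export
validate_index <- function(index_values, outcomes) {
  if (length(index_values) != length(outcomes))
    stop("`index_values` and `outcomes` lengths differ")
  ok <- !is.na(index_values) & !is.na(outcomes)
  n_excluded <- sum(!ok)
  iv <- index_values[ok]; y <- outcomes[ok]
  if (length(unique(iv)) < 2L)
    stop("index is constant across subjects; validation undefined")
  fit <- irls_logit(y ~ index, data.frame(y = y, index = iv))
  b <- fit$coefficients["index"]; s <- fit$se["index"]
  z <- stats::qnorm(0.975)
  per01 <- or_table(term = "index (per 0.1)", or = exp(0.1 * b),
                    ci_low = exp(0.1 * (b - z * s)),
                    ci_high = exp(0.1 * (b + z * s)))
  per1 <- or_table(term = "index (per 1.0)", or = exp(b),
                   ci_low = exp(b - z * s), ci_high = exp(b + z * s))
  structure(list(or_per_scale_unit = per01, or_per_unit = per1,
                 pct_risk_increase_per_0.1 = 100 * (per01$or - 1),
                 n_subjects = length(y), n_excluded = n_excluded,
                 fit = fit),
            class = "vuln_validation")
}

#' @export
print.vuln_validation <- function(x, ...) {
  cat("Vulnerability-index validation (univariate logistic)\n")
  cat(sprintf("n = %d subjects (%d excluded on nodata cells)\n",
              x$n_subjects, x$n_excluded))
  print(x$or_per_scale_unit)
  cat(sprintf("risk increase per 0.1-point index: %.1f%%\n",
              x$pct_risk_increase_per_0.1))
  invisible(x)
}

#' Extract the mapped index at subject locations and validate
#'
#' @param vuln index [raster_layer()] from [compute_index_raster()].
#' @param cohort data.frame with `x`, `y`, `case` (and optional `id`).
#' @return a [validate_index()] report; subjects on nodata cells are
#'   excluded and counted.
#' @export
validate_index_raster <- function(vuln, cohort) {
  ids <- if (!is.null(cohort$id)) cohort$id else seq_len(nrow(cohort))
  iv <- extract_at_points(vuln, cohort$x, cohort$y, ids)
  validate_index(iv, cohort$case)
}

#' End-to-end parameter-recovery experiment
#'
#' Repeats the full synthetic pipeline over seeds: generate city and cohort,
#' extract buffer features, fit the fully adjusted model (Model 3), derive
#' index weights, map the index, and validate it at subject locations. For
#' every true coefficient it reports bias, RMSE and 95% CI coverage across
#' seeds, plus the distribution of the validation OR per 0.1 point. Stage
#' failures (e.g. no significant variable in a null simulation) are
#' recorded per seed, not fatal.
#'
#' @param config a [city_config()]; `config$seed + seed_offset + k` seeds
#'   replicate `k`.
#' @param n_seeds number of replicates (>= 2).
#' @param seed_offset base offset added to `config$seed` per replicate.
#' @param map_index logical; run the mapping + validation stages (set
#'   `FALSE` to study only coefficient recovery, which is much faster).
#' @return object of class `recovery_report`: list with `coefficients`
#'   (data.frame: term, true, bias, rmse, coverage, n_ok), `validation_or`
#'   (per-seed OR per 0.1, possibly with NAs), `n_seeds`, `failures`.
#' @export
run_recovery_experiment <- function(config = city_config(), n_seeds = 50,
                                    seed_offset = 1000L, map_index = TRUE) {
  if (n_seeds < 2L) stop("`n_seeds` must be at least 2")
  terms <- model_terms(3)
  true <- config$true_betas[-1]
  names(true) <- terms       # config order matches model-3 term order
  est <- se <- matrix(NA_real_, n_seeds, length(terms),
                      dimnames = list(NULL, terms))
  val_or <- rep(NA_real_, n_seeds)
  failures <- character(0)
  for (k in seq_len(n_seeds)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- config$seed + seed_offset + k
      st <- synth_study(cfg, features_at = "cell")
      d <- prepare_analysis_data(st$cohort, st$features)
      d <- complete_case_filter(d, c("case", terms))$data
      fit <- fit_depression_model(d, model_id = 3)
      est[k, ] <- fit$coefficients[terms]
      se[k, ] <- fit$se[terms]
      if (map_index) {
        ors <- adjusted_ors(fit)
        ors <- ors[ors$term %in% candidate_index_terms(), , drop = FALSE]
        w <- derive_weights(ors, kinds = binary_kinds(), round_digits = NULL)
        mp <- map_vulnerability(w, st$rasters, st$tpus)
        cc <- st$cohort[!is.na(st$cohort$case), ]
        val_or[k] <- validate_index_raster(mp$vuln, cc)$or_per_scale_unit$or
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures <- c(failures, sprintf("seed %d: %s", k, res))
  }
  z <- stats::qnorm(0.975)
  cover <- est - z * se <= rep(true, each = n_seeds) &
    est + z * se >= rep(true, each = n_seeds)
  coefs <- data.frame(
    term = terms, true = unname(true),
    bias = colMeans(est, na.rm = TRUE) - true,
    rmse = sqrt(colMeans((est - rep(true, each = n_seeds))^2, na.rm = TRUE)),
    coverage = colMeans(cover, na.rm = TRUE),
    n_ok = colSums(!is.na(est)), row.names = NULL)
  structure(list(coefficients = coefs, validation_or = val_or,
                 n_seeds = n_seeds, failures = failures),
            class = "recovery_report")
}

#' Candidate variables of the vulnerability index
#'
#' The nine social and environmental measures eligible for the index; the
#' lifestyle/medical confounders adjust the model but never enter the map.
#'
#' @return character vector of term names.
#' @export
candidate_index_terms <- function() {
  c("older_age", "male", "not_married", "low_education", "living_alone",
    "pct_residential", "pct_vegetation", "avg_build_height_pctile",
    "std_build_height_pctile")
}

#' Variable kinds of the binary model terms
#'
#' Named vector marking every subject-level binary indicator as a
#' `binary-population-percentage` variable for [derive_weights()] (such
#' variables enter the map as area-level population percentages, so their
#' OR-minus-1 weight is divided by 100).
#'
#' @return named character vector.
#' @export
binary_kinds <- function() {
  b <- c("older_age", "male", "not_married", "low_education", "living_alone",
         "dementia", "cardiovascular", "respiratory", "alcohol", "smoking")
  stats::setNames(rep("binary-population-percentage", length(b)), b)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d seeds (%d failures)\n",
              x$n_seeds, length(x$failures)))
  print(transform(x$coefficients, true = round(true, 3),
                  bias = round(bias, 4), rmse = round(rmse, 4)))
  v <- x$validation_or[!is.na(x$validation_or)]
  if (length(v))
    cat(sprintf("validation OR per 0.1: mean %.3f (range %.3f-%.3f, %d seeds)\n",
                mean(v), min(v), max(v), length(v)))
  invisible(x)
}
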