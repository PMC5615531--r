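#' Assemble the analytic dataset from cohort and buffer features
#'
#' Column-binds the subject table and its buffer features, defines the case
#' indicator from the GDS-15 dichotomy (score >= 8 = case, < 8 = control,
#' the cutoff recommended for Asian elderly populations), percentile-
#' normalizes the building-height features over the analytic cohort when not
#' already present, and standardizes the physical-activity score to zero
#' mean / unit variance (`physical_activity_std`) so that confounder's
#' coefficient is scale-free.
#'
#' @param cohort data.frame with subject covariates and `gds15` (or `case`).
#' @param features data.frame of buffer features aligned to `cohort` rows.
#' @return data.frame ready for [fit_depression_model()].
#' @export
prepare_analysis_data <- function(cohort, features) {
  if (nrow(cohort) != nrow(features))
    stop("`features` rows do not align with `cohort` rows")
  d <- cbind(cohort, features[setdiff(names(features), names(cohort))])
  if (is.null(d$case)) {
    if (is.null(d$gds15)) stop("cohort has neither `case` nor `gds15`")
    d$case <- as.integer(d$gds15 >= 8)
  }
  if (is.null(d$avg_build_height_pctile))
    d$avg_build_height_pctile <- percentile_normalize(d$avg_build_height_m)
  if (is.null(d$std_build_height_pctile))
    d$std_build_height_pctile <- percentile_normalize(d$std_build_height_m)
  pa <- d$physical_activity
  s <- stats::sd(pa, na.rm = TRUE)
  d$physical_activity_std <- if (is.finite(s) && s > 0)
    (pa - mean(pa, na.rm = TRUE)) / s else pa * 0
  d
}

#' Term lists of the three adjusted models
#'
#' Model 1: social indicators only; Model 2: environmental measures only;
#' Model 3: both. The six lifestyle/medical confounders are always
#' included.
#'
#' @param model_id 1, 2 or 3.
#' @param height_scale `"percentile"` (default; building heights enter as
#'   0-100 percentiles) or `"raw"` (metres).
#' @return character vector of term names.
#' @export
model_terms <- function(model_id, height_scale = c("percentile", "raw")) {
  height_scale <- match.arg(height_scale)
  social <- c("older_age", "male", "not_married", "low_education",
              "living_alone")
  env <- c("pct_residential", "pct_vegetation",
           if (height_scale == "percentile")
             c("avg_build_height_pctile", "std_build_height_pctile")
           else c("avg_build_height_m", "std_build_height_m"))
  conf <- c("dementia", "physical_activity_std", "cardiovascular",
            "respiratory", "alcohol", "smoking")
  switch(as.character(model_id),
         "1" = c(social, conf),
         "2" = c(env, conf),
         "3" = c(social, env, conf),
         stop("`model_id` must be 1, 2 or 3"))
}

#' Fit an adjusted depression-risk model
#'
#' Fits Model 1, 2 or 3 (see [model_terms()]) with the internal IRLS engine
#' after complete-case filtering on the model variables.
#'
#' @param data analytic data.frame from [prepare_analysis_data()].
#' @param model_id 1 (social), 2 (environmental) or 3 (both); confounders
#'   always included.
#' @param height_scale passed to [model_terms()].
#' @return an [irls_logit()] fit; `fit$model_id` records which model.
#' @export
fit_depression_model <- function(data, model_id = 3,
                                 height_scale = c("percentile", "raw")) {
  terms <- model_terms(model_id, height_scale)
  miss <- setdiff(c("case", terms), names(data))
  if (length(miss))
    stop("analytic data lacks column(s): ", paste(miss, collapse = ", "))
  f <- stats::reformulate(terms, response = "case")
  fit <- irls_logit(f, data)
  fit$model_id <- model_id
  fit
}
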