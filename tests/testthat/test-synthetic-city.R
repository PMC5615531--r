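test_that("every generated artifact is a deterministic function of the seed", {
  cfg <- small_city(seed = 4)
  r1 <- generate_rasters(cfg)
  r2 <- generate_rasters(cfg)
  expect_identical(r1$land_use$values, r2$land_use$values)
  expect_identical(r1$vegetation$values, r2$vegetation$values)
  expect_identical(r1$building_height$values, r2$building_height$values)
  s1 <- synth_study(cfg)
  s2 <- synth_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$tpus, s2$tpus)
  # a different seed changes the city
  r3 <- generate_rasters(small_city(seed = 5))
  expect_false(identical(r1$building_height$values,
                         r3$building_height$values))
})

test_that("degenerate residential fraction 1 paints the whole city residential", {
  cfg <- city_config(extent_m = 300, n_subjects = 10, seed = 2,
                     residential_fraction = 1)
  r <- generate_rasters(cfg)
  expect_true(all(r$land_use$values <= 3))
  expect_true(all(binarize_landuse(r$land_use)$values == 1))
})

test_that("config invariants are enforced", {
  expect_error(city_config(extent_m = -1), "positive")
  expect_error(city_config(true_betas = 1:5), "16")
  expect_error(city_config(extent_m = 1005, base_resolution_m = 10),
               "divide")
})

test_that("cohort marginals and dependence match the configured targets", {
  cfg <- city_config(seed = 6)
  r <- generate_rasters(cfg)
  co <- generate_cohort(cfg, r$land_use)
  expect_equal(nrow(co), 4000)
  expect_lt(abs(100 * mean(co$low_education) - 65.5), 2)
  expect_lt(abs(cor(co$not_married, co$living_alone) - 0.55), 0.1)
  expect_true(all(co$physical_activity >= 0))
  # empty cohort keeps the schema
  co0 <- generate_cohort(city_config(n_subjects = 0), r$land_use)
  expect_equal(nrow(co0), 0)
  expect_true(all(c("x", "y", "living_alone") %in% names(co0)))
  # no residential cells is a generation error
  bare <- raster_layer(matrix(6, 5, 5), resolution_m = 10,
                       levels = r$land_use$levels)
  expect_error(generate_cohort(cfg, bare), "residential")
})

test_that("all subjects lie on residential cells", {
  st <- synth_study(small_city(seed = 8, n_subjects = 1500),
                    inject_missingness = FALSE)
  codes <- extract_at_points(st$rasters$land_use, st$cohort$x, st$cohort$y)
  expect_true(all(codes %in% 1:3))
})

test_that("outcome simulation hits the prevalence target", {
  # null model with intercept 0: prevalence 1/2
  cfg0 <- small_city(seed = 10, n_subjects = 4000)
  cfg0$true_betas <- rep(0, 16)
  cfg0$prevalence_target <- NULL
  r <- generate_rasters(cfg0)
  co <- generate_cohort(cfg0, r$land_use)
  zero_feats <- data.frame(pct_residential = 0, pct_vegetation = 0,
                           avg_build_height_pctile = 0,
                           std_build_height_pctile = 0)[rep(1, nrow(co)), ]
  out <- simulate_outcomes(co, zero_feats, cfg0)
  expect_lt(abs(mean(out$case) - 0.5), 0.02)
  # calibrated intercept: empirical prevalence near 364/3930
  st <- synth_study(city_config(seed = 12), inject_missingness = FALSE)
  expect_lt(abs(mean(st$cohort$case) - 364 / 3930), 0.01)
  # convergence of the case fraction at large n
  cfgL <- city_config(extent_m = 1000, n_subjects = 50000, seed = 13)
  rL <- generate_rasters(cfgL)
  coL <- generate_cohort(cfgL, rL$land_use)
  zf <- zero_feats[rep(1, nrow(coL)), ]
  outL <- simulate_outcomes(coL, zf, cfgL)
  expect_lt(abs(mean(outL$case) - 364 / 3930), 0.005)
  # misaligned features are an error
  expect_error(simulate_outcomes(co, zero_feats[1:5, ], cfg0), "align")
})

test_that("GDS-15 dichotomy at 8 reproduces the case indicator exactly", {
  st <- synth_study(small_city(seed = 14), inject_missingness = FALSE)
  expect_identical(st$cohort$gds15 >= 8, st$cohort$case == 1)
  expect_true(all(st$cohort$gds15 %in% 0:15))
})

test_that("a single-exposure effect is recovered by refitting across seeds", {
  betas <- rep(0, 16)
  betas[5] <- log(1.6)                 # low education only
  ok <- logical(50)
  for (k in 1:50) {
    cfg <- city_config(extent_m = 400, n_subjects = 4000, seed = 100 + k,
                       true_betas = betas, prevalence_target = 364 / 3930,
                       residential_fraction = 1)
    r <- generate_rasters(cfg)
    co <- generate_cohort(cfg, r$land_use)
    zf <- data.frame(pct_residential = 0, pct_vegetation = 0,
                     avg_build_height_pctile = 0,
                     std_build_height_pctile = 0)[rep(1, nrow(co)), ]
    out <- simulate_outcomes(co, zf, cfg)
    fit <- irls_logit(case ~ low_education, out)
    or <- exp(fit$coefficients["low_education"])
    ok[k] <- or >= 1.2 && or <= 2.1
  }
  expect_gte(mean(ok), 0.9)
})

test_that("planning units tile the extent with percentage attributes in range", {
  cfg <- small_city(seed = 3)
  tp <- generate_tpu(cfg)
  expect_equal(nrow(tp), 16)
  area <- sum((tp$xmax - tp$xmin) * (tp$ymax - tp$ymin))
  expect_equal(area, cfg$extent_m^2)
  expect_true(all(tp$pct_low_education >= 0 & tp$pct_low_education <= 100))
  expect_false(any(duplicated(tp$tpu_id)))
})
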