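test_that("2x2 tables are rebuilt from group sizes and percentages", {
  t1 <- reconstruct_table(364, 19.8, 3566, 12.9)
  expect_equal(unlist(t1), c(a = 72, b = 292, c = 460, d = 3106))
  t2 <- reconstruct_table(364, 39.6, 3566, 28.1)
  expect_equal(unlist(t2), c(a = 144, b = 220, c = 1002, d = 2564))
  t3 <- reconstruct_table(100, 0, 100, 0)
  expect_equal(unlist(t3), c(a = 0, b = 100, c = 0, d = 100))
  expect_error(reconstruct_table(-1, 10, 10, 10), "non-negative")
  expect_error(reconstruct_table(10, 110, 10, 10), "\\[0, 100\\]")
})

test_that("crude OR and Woolf CI follow the log-OR closed form", {
  or <- crude_or(two_by_two(10, 10, 10, 10))
  expect_equal(or$or, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(or$ci_low), -log(or$ci_high))
  # independent closed-form check before trusting the fixture
  tab <- two_by_two(5, 5, 2, 8)
  got <- crude_or(tab)
  se <- sqrt(1 / 5 + 1 / 5 + 1 / 2 + 1 / 8)
  expect_equal(got$or, 4)
  expect_equal(got$ci_low, exp(log(4) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(got$ci_high, exp(log(4) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(round(c(got$ci_low, got$ci_high), 1), c(0.5, 29.1))
  expect_error(crude_or(two_by_two(0, 5, 5, 5)), "zero cell.*a")
})

test_that("group comparison is Welch's t-test, degenerate cases included", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  same <- group_compare(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # cross-check against the Welch closed form
  set.seed(21)
  a <- rnorm(1000); b <- rnorm(1000)
  got <- group_compare(a, b)
  v1 <- var(a) / 1000; v2 <- var(b) / 1000
  tt <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 999 + v2^2 / 999)
  expect_equal(got$t, tt, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(tt), df), tolerance = 1e-10)
  # proportions compared as 0/1 vectors
  case <- c(rep(1, 72), rep(0, 292))       # 19.8% of 364
  ctrl <- c(rep(1, 460), rep(0, 3106))     # 12.9% of 3566
  expect_lt(group_compare(case, ctrl)$p_value, 0.05)
  # constant equal groups
  expect_equal(group_compare(c(1, 1), c(1, 1))$p_value, 1)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  d <- data.frame(x = rnorm(50))
  d$y <- -d$x
  d$z <- rnorm(50)
  r <- correlation_matrix(d)
  expect_equal(r, t(r))
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  expect_equal(r["x", "y"], -1)
  expect_true(all(r >= -1 & r <= 1))
  d$c <- 5
  expect_warning(rc <- correlation_matrix(d), "constant")
  expect_true(is.na(rc["c", "x"]))
})

test_that("complete-case filter removes exactly the incomplete rows", {
  d <- data.frame(a = 1:10, b = 1:10)
  expect_equal(complete_case_filter(d)$n_removed, 0)
  d$b[c(3, 8)] <- NA
  f <- complete_case_filter(d)
  expect_equal(nrow(f$data), 8)
  expect_equal(f$n_removed, 2)
  # generator-scale check: 3944 rows, 14 degraded, 3930 retained
  cfg <- city_config(n_subjects = 3944, seed = 2)
  r <- generate_rasters(city_config(extent_m = 500, n_subjects = 0, seed = 2))
  co <- generate_cohort(cfg, r$land_use)
  co$gds15 <- 0L
  co <- inject_missing(co, rate = 0.0035, seed = 3)
  f2 <- complete_case_filter(co)
  expect_equal(f2$n_removed, 14)
  expect_equal(nrow(f2$data), 3930)
  expect_error(complete_case_filter(data.frame(a = c(NA, NA))), "all rows")
})

test_that("IRLS maximizes the Bernoulli likelihood", {
  # balanced binary predictor with identical case rates: beta exactly 0
  d <- data.frame(case = c(rep(1, 5), rep(0, 15), rep(1, 10), rep(0, 30)),
                  exposed = c(rep(1, 20), rep(0, 40)))
  f <- irls_logit(case ~ exposed, d)
  expect_equal(unname(f$coefficients["exposed"]), 0, tolerance = 1e-9)
  # cross-check coefficients and SEs against glm on random data
  set.seed(31)
  n <- 400
  dd <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  dd$y <- rbinom(n, 1, plogis(-1 + 0.8 * dd$x1 - 0.5 * dd$x2))
  ours <- irls_logit(y ~ x1 + x2, dd)
  ref <- glm(y ~ x1 + x2, data = dd, family = binomial)
  expect_equal(ours$coefficients, coef(ref), tolerance = 1e-7)
  expect_equal(ours$se, sqrt(diag(vcov(ref))), tolerance = 1e-5)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-9)
  # the log-likelihood never decreases across iterations
  expect_true(all(diff(ours$loglik_trace) >= -1e-9))
})

test_that("IRLS agrees with a derivative-free likelihood grid search", {
  set.seed(8)
  d <- data.frame(x1 = rnorm(20), x2 = rbinom(20, 1, 0.5))
  d$y <- rbinom(20, 1, plogis(0.5 + d$x1 - d$x2))
  fit <- irls_logit(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  grid <- bf_loglik_grid(X, d$y)
  expect_equal(unname(fit$coefficients), unname(grid), tolerance = 1e-3)
})

test_that("degenerate designs are reported, not silently fitted", {
  set.seed(12)
  d <- data.frame(x = rnorm(60))
  d$y <- as.integer(d$x > 0)          # perfectly separated
  expect_warning(f <- irls_logit(y ~ x, d), "separation")
  expect_false(f$converged)
  expect_error(adjusted_ors(f), "converge")
  d2 <- data.frame(x1 = rnorm(40))
  d2$x2 <- d2$x1                      # exactly collinear
  d2$y <- rbinom(40, 1, 0.5)
  expect_error(irls_logit(y ~ x1 + x2, d2), "x2")
  expect_error(irls_logit(y ~ x1, transform(d2, y = 1)), "at least one")
})

test_that("univariate logistic reproduces the crude OR algebraically", {
  tab <- reconstruct_table(364, 19.8, 3566, 12.9)
  d <- expand_two_by_two(tab)
  fit <- irls_logit(case ~ exposed, d)
  crude <- crude_or(tab)
  expect_equal(unname(exp(fit$coefficients["exposed"])), crude$or,
               tolerance = 1e-10)
  # model-based Wald CI equals the Woolf table CI
  ors <- adjusted_ors(fit)
  expect_equal(ors$ci_low, crude$ci_low, tolerance = 1e-6)
  expect_equal(ors$ci_high, crude$ci_high, tolerance = 1e-6)
  expect_equal(round(c(ors$or, ors$ci_low, ors$ci_high), 2),
               c(1.66, 1.26, 2.19))
})

test_that("adjusted ORs follow the exp(beta +/- 1.96 se) closed form", {
  fake <- structure(list(coefficients = c("(Intercept)" = -1, x = 0),
                         se = c("(Intercept)" = 0.2, x = 0.1),
                         converged = TRUE), class = "irls_logit")
  o <- adjusted_ors(fake)
  expect_equal(o$or, 1)
  expect_equal(round(c(o$ci_low, o$ci_high), 2), c(0.82, 1.22))
  fake$coefficients["x"] <- log(2)
  fake$se["x"] <- 0
  o2 <- adjusted_ors(fake)
  expect_equal(o2$or, 2)
  expect_equal(o2$ci_low, 2)
  expect_equal(o2$ci_high, 2)
  expect_true(o2$significant)    # degenerate CI [2, 2] excludes 1
})

test_that("CI-excludes-1 test has ~5% type-I error under the null", {
  set.seed(17)
  hits <- matrix(NA, 500, 2)
  for (r in 1:500) {
    d <- data.frame(x1 = rnorm(300), x2 = rbinom(300, 1, 0.5))
    d$y <- rbinom(300, 1, 0.3)       # outcome independent of both
    o <- adjusted_ors(irls_logit(y ~ x1 + x2, d))
    hits[r, ] <- o$significant
  }
  rates <- colMeans(hits)
  expect_true(all(abs(rates - 0.05) < 0.02))
})
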