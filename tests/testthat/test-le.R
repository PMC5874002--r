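test_that("occupancy starts at the indicator and conserves mass", {
  p <- ground_truth()
  oc <- occupancy(p, ref_profile, start_age = 65, start_state = 2,
                  grid_step = 0.5, max_age = 100)
  expect_equal(oc$age[1], 65)
  expect_equal(unlist(oc[1, -1]), c(p_healthy = 0, p_limited = 1, p_dead = 0))
  expect_lt(max(abs(rowSums(oc[, -1]) - 1)), 1e-10)

  # immortal toy: the living occupancies sum to one at every age
  im <- toy_params(q12 = 0.15, q21 = 0.1)
  oci <- occupancy(im, ref_profile, 60, 1, grid_step = 0.25, max_age = 110)
  expect_lt(max(abs(oci$p_healthy + oci$p_limited - 1)), 1e-12)
  expect_equal(max(oci$p_dead), 0)
})

test_that("alive-dead toy occupancy follows the exponential survivor", {
  mu <- 0.08
  p <- toy_params(q13 = mu)
  oc <- occupancy(p, ref_profile, 60, 1, grid_step = 0.25, max_age = 110)
  expect_lt(max(abs(oc$p_healthy - exp(-mu * (oc$age - 60)))), 1e-8)
})

test_that("state expectancies integrate the occupancy correctly", {
  # constant-mortality toy: e11 = 1/mu
  mu <- 0.05
  # the disabled-start row is immortal in this toy, so silence the
  # truncation diagnostic that it (correctly) triggers
  e <- suppressWarnings(state_expectancies(toy_params(q13 = mu), ref_profile,
                                           60, grid_step = 0.01,
                                           max_age = 460))
  expect_lt(abs(e[1, 1] - 1 / mu), 1e-6)
  expect_equal(e[1, 2], 0)

  # no transitions at all: all time is spent in the starting state
  e0 <- suppressWarnings(state_expectancies(toy_params(), ref_profile, 60,
                                            grid_step = 0.25, max_age = 100))
  expect_equal(e0[1, 1], 40, tolerance = 1e-10)
  expect_equal(e0[2, 2], 40, tolerance = 1e-10)
  expect_equal(e0[1, 2] + e0[2, 1], 0)

  # truncation diagnostic fires when max_age is too low
  expect_warning(state_expectancies(toy_params(q13 = 0.01), ref_profile,
                                    60, grid_step = 0.25, max_age = 80),
                 "truncat")

  # expectancies are non-negative and total LE decreases with start age
  tot <- vapply(c(60, 70, 80, 90), function(a) {
    e <- state_expectancies(ground_truth(), ref_profile, a)
    expect_true(all(e >= 0))
    sum(e[1, ])
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("expectancies are insensitive to the integration grid", {
  prof <- list(female = 1, overweight = 0, obese = 0)
  tot <- vapply(c(0.1, 0.25, 0.5), function(gs)
    sum(state_expectancies(ground_truth(), prof, 60, grid_step = gs)[1, ]),
    numeric(1))
  expect_lt(abs(tot[2] - tot[1]), 0.2)
  expect_lt(abs(tot[3] - tot[1]), 0.2)
})

test_that("prevalence model matches an independent logistic fit", {
  co <- test_cohort()
  prev <- fit_prevalence(co$data)
  d <- co$data[order(co$data$id, co$data$age), ]
  base <- d[!duplicated(d$id), ]
  base$y <- as.numeric(base$state == 2)
  base$agec <- base$age - 70
  base$female <- as.numeric(base$sex == "female")
  base$overweight <- as.numeric(base$bmi_cat == "overweight")
  base$obese <- as.numeric(base$bmi_cat == "obese")
  ref <- stats::glm(y ~ agec + female + overweight + obese, binomial, base)
  expect_equal(unname(prev$coef), unname(coef(ref)), tolerance = 1e-5)
  pr <- predict_prevalence(prev, list(female = 1, overweight = 1, obese = 0),
                           75)
  expect_true(pr > 0 && pr < 1)
  expect_equal(pr, unname(stats::predict(
    ref, data.frame(agec = 5, female = 1, overweight = 1, obese = 0),
    type = "response")), tolerance = 1e-5)
})

test_that("marginal expectancies weight the state-conditional rows", {
  p <- toy_params(0.1, 0.05, 0.02, 0.1)
  # prevalence forced to zero: marginal equals the healthy-start row
  prev0 <- structure(list(coef = c(`(Intercept)` = -50, age = 0, female = 0,
                                   overweight = 0, obese = 0),
                          vcov = diag(5) * 0, n = 1, age_center = 70),
                     class = "prevalence_model")
  le <- marginal_life_expectancies(p, prev0, ref_profile, 65, max_age = 250)
  e <- state_expectancies(p, ref_profile, 65, max_age = 250)
  expect_equal(le$dfle, e[1, 1], tolerance = 1e-10)
  expect_equal(le$dle, e[1, 2], tolerance = 1e-10)
  expect_equal(le$total_le, le$dfle + le$dle)
  expect_equal(le$pct_disabled, 100 * le$dle / le$total_le)

  # conditional reporting ignores the prevalence weights entirely
  prev5 <- prev0; prev5$coef[1] <- 0.5
  lec <- marginal_life_expectancies(p, prev5, ref_profile, 65,
                                    max_age = 250, conditional = TRUE)
  expect_equal(lec$dfle, e[1, 1], tolerance = 1e-10)
  lem <- marginal_life_expectancies(p, prev5, ref_profile, 65, max_age = 250)
  expect_true(lem$dle > lec$dle)  # weighting towards the disabled row
})

test_that("zero covariance collapses the simulated intervals", {
  spec <- msm_spec()
  fit0 <- structure(list(par = ground_truth(),
                         cov = matrix(0, 20, 20), se = rep(0, 20),
                         spec = spec),
                    class = "msm_fit")
  prev <- structure(list(coef = c(`(Intercept)` = -1, age = 0.05,
                                  female = 0.5, overweight = 0, obese = 0),
                         vcov = diag(5) * 0, n = 1, age_center = 70),
                    class = "prevalence_model")
  ci <- simulate_cis(fit0, prev, ref_profile, ages = c(65, 75), n_sim = 25,
                     seed = 1)
  expect_equal(ci$lower, ci$estimate, tolerance = 1e-12)
  expect_equal(ci$upper, ci$estimate, tolerance = 1e-12)
  expect_equal(attr(ci, "n_rejected"), 0L)
})

test_that("every simulation draw satisfies total = DFLE + DLE", {
  co <- test_cohort(n = 300, seed = 12)
  fit <- suppressWarnings(msm_fit(co$data))
  prev <- fit_prevalence(co$data)
  en <- mslife:::le_draw_engine(fit, prev, list(p = ref_profile),
                                ages = c(60, 80), n_sim = 40, seed = 2)
  tot <- en$draws[, 1, , "total_le"]
  expect_equal(tot, en$draws[, 1, , "dfle"] + en$draws[, 1, , "dle"],
               tolerance = 1e-12)
  expect_true(all(en$draws >= 0))
})

test_that("interval width shrinks with the cohort size", {
  width <- vapply(c(400, 1600), function(n) {
    co <- test_cohort(n = n, seed = 21)
    fit <- suppressWarnings(msm_fit(co$data))
    prev <- fit_prevalence(co$data)
    ci <- simulate_cis(fit, prev, ref_profile, ages = 60, n_sim = 150,
                       seed = 4)
    w <- ci[ci$quantity == "total_le", ]
    w$upper - w$lower
  }, numeric(1))
  expect_lt(width[2], width[1])
})
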