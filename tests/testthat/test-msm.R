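test_that("intensity matrix follows the log-linear parameterisation", {
  spec <- msm_spec()
  pars <- rep(0, 20)
  Q <- intensity_matrix(pars, ref_profile, age = 70, spec = spec)
  expect_equal(Q[1, 2], 1); expect_equal(Q[2, 1], 1)
  expect_equal(Q[1, 3], 1); expect_equal(Q[2, 3], 1)
  expect_equal(diag(Q), c(`1` = -2, `2` = -2, `3` = 0))
  expect_equal(rowSums(Q), c(`1` = 0, `2` = 0, `3` = 0))
  expect_equal(Q[3, ], c(`1` = 0, `2` = 0, `3` = 0))

  # one year of age multiplies the disability-incidence intensity by 1.06
  p <- toy_params(0.1, 0.1, 0.1, 0.1, beta_age = c(log(1.06), 0, 0, 0))
  Q70 <- intensity_matrix(p, ref_profile, 70)
  Q71 <- intensity_matrix(p, ref_profile, 71)
  expect_equal(Q71[1, 2] / Q70[1, 2], 1.06)
  expect_equal(Q71[2, 1], Q70[2, 1])

  # female/male intensity ratio equals the female HR
  pf <- toy_params(0.1, 0.1, 0.1, 0.1, beta_female = c(log(1.82), 0, 0, 0))
  Qf <- intensity_matrix(pf, list(female = 1, overweight = 0, obese = 0), 70)
  Qm <- intensity_matrix(pf, ref_profile, 70)
  expect_equal(Qf[1, 2] / Qm[1, 2], 1.82)

  expect_error(intensity_matrix(rep(800, 20), ref_profile, 70), "overflow")
  expect_error(intensity_matrix(rep(0, 19), ref_profile, 70), "length")
})

test_that("transition probabilities are stochastic and match closed forms", {
  # zero-length interval
  p <- ground_truth()
  expect_equal(transition_probability(p, ref_profile, 70, 70),
               diag(3), ignore_attr = TRUE)

  # single-exit toy: P13(t) = 1 - exp(-mu t)
  mu <- 0.2
  pe <- toy_params(q13 = mu)
  P <- transition_probability(pe, ref_profile, 70, 75)
  expect_equal(P[1, 3], 1 - exp(-mu * 5), tolerance = 1e-12)
  expect_equal(P[1, 1], exp(-mu * 5), tolerance = 1e-12)

  # Chapman-Kolmogorov under a constant generator
  pc <- toy_params(0.12, 0.08, 0.02, 0.2)
  Pac <- transition_probability(pc, ref_profile, 60, 70)
  Pab <- transition_probability(pc, ref_profile, 60, 64)
  Pbc <- transition_probability(pc, ref_profile, 64, 70)
  expect_equal(Pac, Pab %*% Pbc, tolerance = 1e-12)

  # property: random generators give row-stochastic P in [0,1], agreeing
  # with an independent dense matrix exponential
  set.seed(31)
  for (i in 1:20) {
    pr <- toy_params(exp(stats::rnorm(1, -2)), exp(stats::rnorm(1, -2)),
                     exp(stats::rnorm(1, -3)), exp(stats::rnorm(1, -2)))
    dt <- stats::runif(1, 0, 15)
    P <- transition_probability(pr, ref_profile, 70, 70 + dt)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    Q <- intensity_matrix(pr, ref_profile, 70)
    Pref <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
    expect_lt(max(abs(P - Pref)), 1e-10)
  }
})

test_that("likelihood matches exponential closed forms and limits", {
  # alive at 70, exact death at 70 + t, only 1 -> 3 active:
  # log L = -mu t + log mu
  mu <- 0.25; t <- 3.7
  d <- data.frame(id = 1, age = c(70, 70 + t), state = c(1L, 3L),
                  obstype = c("panel", "death"),
                  female = 0, overweight = 0, obese = 0)
  expect_equal(msm_loglik(toy_params(q13 = mu), d),
               -mu * t + log(mu), tolerance = 1e-12)

  # censoring immediately after baseline contributes ~ log(1) = 0
  dc <- d; dc$age[2] <- 70 + 1e-9; dc$state[2] <- NA
  dc$obstype[2] <- "censored"
  expect_equal(msm_loglik(ground_truth(), dc), 0, tolerance = 1e-6)

  # likelihood is invariant to subject ordering
  co <- test_cohort(n = 150, seed = 3)
  ll1 <- msm_loglik(ground_truth(), co$data)
  shuf <- co$data[order(-co$data$id, co$data$age), ]
  expect_equal(msm_loglik(ground_truth(), shuf), ll1)

  # splitting an interval at an intermediate point, marginalising the
  # unobserved state by Chapman-Kolmogorov, leaves the contribution intact
  pc <- toy_params(0.12, 0.08, 0.02, 0.2)
  d2 <- data.frame(id = 1, age = c(70, 78), state = c(1L, 2L),
                   obstype = "panel", female = 0, overweight = 0, obese = 0)
  P1 <- transition_probability(pc, ref_profile, 70, 74)
  P2 <- transition_probability(pc, ref_profile, 74, 78)
  expect_equal(msm_loglik(pc, d2), log((P1 %*% P2)[1, 2]), tolerance = 1e-12)
})

test_that("dataset validation rejects malformed sequences", {
  base <- data.frame(id = c(1, 1), age = c(70, 70), state = c(1L, 2L),
                     obstype = "panel", female = 0, overweight = 0,
                     obese = 0)
  expect_error(msm_loglik(ground_truth(), base), "strictly increasing")
  d2 <- data.frame(id = c(1, 1, 1), age = c(70, 75, 80),
                   state = c(1L, 3L, 1L),
                   obstype = c("panel", "death", "panel"),
                   female = 0, overweight = 0, obese = 0)
  expect_error(msm_loglik(ground_truth(), d2))
  d3 <- data.frame(id = 1:2, age = 70, state = 1L, obstype = "interview",
                   female = 0, overweight = 0, obese = 0)
  expect_error(msm_loglik(ground_truth(), d3), "obstype")
})

test_that("panel likelihood agrees with the discrete-time forward oracle", {
  co <- test_cohort(n = 10, seed = 8)
  pars <- ground_truth()
  ours <- msm_loglik(pars, co$data, by_subject = TRUE)
  ref <- oracle_loglik(pars, co$data, dt = 0.01)
  expect_equal(length(ours), 10L)
  expect_lt(max(abs(ours - ref[names(ours)])), 1e-3)
})

test_that("duplicating the dataset leaves the MLE and halves the covariance", {
  co <- test_cohort(n = 150, seed = 3)
  f1 <- suppressWarnings(msm_fit(co$data))
  d2 <- co$data
  d2$id <- d2$id + 10000
  f2 <- suppressWarnings(msm_fit(rbind(co$data, d2)))
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  # compare on the well-identified parameters (finite, non-degenerate se);
  # effects with essentially no events drift along a flat likelihood
  keep <- f1$se < 5 & f1$se > 1e-4
  expect_equal(f2$par[keep], f1$par[keep], tolerance = 1e-3)
  expect_equal(diag(f2$cov)[keep] / diag(f1$cov)[keep],
               rep(0.5, sum(keep)), ignore_attr = TRUE, tolerance = 0.05)
})

test_that("initialising at the truth converges quickly and cleanly", {
  co <- test_cohort(n = 300, seed = 12)
  fit <- suppressWarnings(msm_fit(co$data, init = ground_truth()))
  expect_equal(fit$convergence$code, 0L)
  expect_lt(fit$convergence$gradient_max_norm, 1)
  expect_gte(fit$loglik, msm_loglik(ground_truth(), co$data))
})

test_that("recovered log-hazard-ratio error shrinks with sample size", {
  idx <- c("age[1-2]", "age[2-1]", "age[2-3]", "female[1-2]", "female[2-3]")
  err <- vapply(c(1000, 8000), function(n) {
    co <- test_cohort(n = n, seed = 44, age_top = 90)
    fit <- suppressWarnings(msm_fit(co$data))
    sum(abs(fit$par[idx] - ground_truth()[idx]))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("hazard-ratio tables exponentiate and bracket correctly", {
  spec <- msm_spec()
  fake <- structure(list(par = stats::setNames(c(rep(0, 4), rep(log(2), 4),
                                                 log(0.64), rep(0, 7),
                                                 rep(0.3, 4)),
                                               mslife:::param_names(spec)),
                         se = stats::setNames(rep(0.13265, 20),
                                              mslife:::param_names(spec)),
                         spec = spec),
                    class = "msm_fit")
  hr <- hazard_ratios(fake)
  expect_equal(nrow(hr), 16L)
  age12 <- hr[hr$covariate == "age" & hr$transition == "Disability incidence", ]
  expect_equal(age12$hr, 2)
  fem12 <- hr[hr$covariate == "female" &
                hr$transition == "Disability incidence", ]
  expect_equal(fem12$hr, 0.64)
  expect_equal(round(fem12$lower, 2), 0.49)
  expect_equal(round(fem12$upper, 2), 0.83)
  expect_true(all(hr$lower <= hr$hr & hr$hr <= hr$upper))
})
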