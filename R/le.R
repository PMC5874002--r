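# State-occupancy curves, state-specific expected years, prevalence
# weighting into population (marginal) life expectancies, and percentile
# confidence intervals by parameter simulation.

# Accumulated occupancy matrices P(start_age, a) on an age grid, with the
# generator refreshed at every grid point (age advances along the grid).
# Returns ages plus an nages x 3 x 3 array; rows give both living start
# states in one pass.
occupancy_array <- function(params, spec, profile, start_age,
                            grid_step = 0.25, max_age = 115) {
  stopifnot(start_age < max_age, grid_step > 0)
  ages <- unique(c(seq(start_age, max_age, by = grid_step), max_age))
  n <- length(ages)
  out <- array(NA_real_, c(n, 3, 3))
  M <- diag(3)
  out[1, , ] <- M
  B <- par_matrix(params, spec)
  covs <- setdiff(spec$covariates, "age")
  zfix <- vapply(covs, function(k) as.numeric(profile[[k]]), numeric(1))
  bfix <- if (length(covs))
    as.numeric(zfix %*% B[covs, , drop = FALSE]) else numeric(4)
  lp0 <- B[1, ] + bfix
  bage <- if ("age" %in% spec$covariates) B["age", ] else numeric(4)
  for (j in seq_len(n - 1L)) {
    q <- exp(lp0 + bage * (ages[j] - spec$age_center))
    if (!all(is.finite(q))) stop("overflow in exp(): intensities not finite")
    pm <- pmat_alive(q[1], q[2], q[3], q[4], ages[j + 1L] - ages[j])
    Pstep <- rbind(c(pm$P11, pm$P12, pm$P13),
                   c(pm$P21, pm$P22, pm$P23),
                   c(0, 0, 1))
    M <- M %*% Pstep
    out[j + 1L, , ] <- M
  }
  list(ages = ages, P = out)
}

#' State-occupancy probabilities along an age grid
#'
#' \eqn{P_{rs}(start\_age, a)} for a fixed covariate profile, computed as a
#' stepwise product of interval matrix exponentials with the age-dependent
#' generator refreshed at each grid point.
#'
#' @param fitted An \code{\link{msm_fit}} (or a flat parameter vector).
#' @param profile Named list of covariate values (excluding age).
#' @param start_age Starting age in years.
#' @param start_state Starting state, 1 (healthy) or 2 (limited).
#' @param grid_step Grid step in years (default 0.25).
#' @param max_age Upper integration age (default 115).
#' @param spec Required when \code{fitted} is a bare parameter vector.
#' @return Data frame with \code{age}, \code{p_healthy}, \code{p_limited},
#'   \code{p_dead}; rows sum to 1.
#' @export
occupancy <- function(fitted, profile = list(), start_age, start_state = 1,
                      grid_step = 0.25, max_age = 115, spec = NULL) {
  pp <- .params_spec(fitted, spec)
  stopifnot(start_state %in% 1:2)
  oc <- occupancy_array(pp$params, pp$spec, profile, start_age,
                        grid_step, max_age)
  data.frame(age = oc$ages,
             p_healthy = oc$P[, start_state, 1],
             p_limited = oc$P[, start_state, 2],
             p_dead = oc$P[, start_state, 3])
}

.params_spec <- function(fitted, spec) {
  if (inherits(fitted, "msm_fit")) {
    list(params = fitted$par, spec = fitted$spec)
  } else {
    if (is.null(spec)) spec <- msm_spec()
    list(params = fitted, spec = spec)
  }
}

# Trapezoidal integration of the living-state occupancies.
expectancies_from_array <- function(oc, truncation_warn = TRUE) {
  ages <- oc$ages
  h <- diff(ages)
  w <- c(h / 2, 0) + c(0, h / 2)
  e <- matrix(0, 2, 2, dimnames = list(c("healthy", "limited"),
                                       c("healthy", "limited")))
  for (r in 1:2) for (s in 1:2) e[r, s] <- sum(w * oc$P[, r, s])
  tail_alive <- max(rowSums(oc$P[length(ages), 1:2, 1:2]))
  if (truncation_warn && tail_alive > 1e-3)
    warning(sprintf(paste0("living occupancy %.2g at max_age %.0f: ",
                           "expectancies are truncated; increase max_age"),
                    tail_alive, ages[length(ages)]))
  e
}

#' Expected years in each living state
#'
#' \eqn{e_{rs} = \int_{a_0}^{a_{max}} P_{rs}(a_0, a)\,da} by the
#' trapezoidal rule on the occupancy grid: expected years spent in living
#' state s between \code{start_age} and \code{max_age}, starting from
#' living state r.
#'
#' @inheritParams occupancy
#' @return 2x2 matrix (rows: starting state; columns: state occupied).
#' @export
state_expectancies <- function(fitted, profile = list(), start_age,
                               grid_step = 0.25, max_age = 115, spec = NULL) {
  pp <- .params_spec(fitted, spec)
  oc <- occupancy_array(pp$params, pp$spec, profile, start_age,
                        grid_step, max_age)
  expectancies_from_array(oc)
}

#' Fit the baseline disability-prevalence model
#'
#' Binary log-odds model for P(functionally limited | alive) on centred age
#' and the covariate dummies, fitted to each subject's baseline record by
#' direct maximisation of the Bernoulli likelihood. Used to weight the
#' state-conditional expectancies into population (marginal) life
#' expectancies.
#'
#' @param data Long-format dataset; the first record of each subject is
#'   used.
#' @param spec An \code{\link{msm_spec}} (provides covariates and the age
#'   centring constant).
#' @return Object of class \code{"prevalence_model"} with \code{coef} and
#'   \code{vcov}.
#' @export
fit_prevalence <- function(data, spec = msm_spec()) {
  data <- as.data.frame(data)
  if (is.null(data$female) && !is.null(data$sex))
    data$female <- as.numeric(data$sex == "female")
  if (is.null(data$overweight) && !is.null(data$bmi_cat))
    data$overweight <- as.numeric(data$bmi_cat == "overweight")
  if (is.null(data$obese) && !is.null(data$bmi_cat))
    data$obese <- as.numeric(data$bmi_cat == "obese")
  data <- data[order(data$id, data$age), , drop = FALSE]
  base <- data[!duplicated(data$id) & data$obstype == "panel", , drop = FALSE]
  y <- as.numeric(base$state == 2L)
  covs <- setdiff(spec$covariates, "age")
  X <- cbind(`(Intercept)` = 1, age = base$age - spec$age_center,
             as.matrix(base[covs]))
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    mu <- stats::plogis(as.numeric(X %*% b))
    -as.numeric(crossprod(X, y - mu))
  }
  opt <- stats::optim(numeric(ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 200L, reltol = 1e-12))
  mu <- stats::plogis(as.numeric(X %*% opt$par))
  info <- crossprod(X * (mu * (1 - mu)), X)
  vc <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
  coef <- stats::setNames(opt$par, colnames(X))
  structure(list(coef = coef, vcov = vc, n = length(y),
                 age_center = spec$age_center),
            class = "prevalence_model")
}

#' Predicted disability prevalence
#'
#' @param prev A \code{\link{fit_prevalence}} model.
#' @param profile Named list of covariate values.
#' @param age Age in years.
#' @return P(state 2 | alive) in (0, 1).
#' @export
predict_prevalence <- function(prev, profile, age) {
  b <- prev$coef
  eta <- b[1] + b["age"] * (age - prev$age_center)
  for (k in setdiff(names(b), c("(Intercept)", "age")))
    eta <- eta + b[k] * as.numeric(profile[[k]])
  as.numeric(stats::plogis(eta))
}

.le_point <- function(e, w1) {
  dfle <- w1 * e[1, 1] + (1 - w1) * e[2, 1]
  dle <- w1 * e[1, 2] + (1 - w1) * e[2, 2]
  total <- dfle + dle
  c(total_le = total, dfle = dfle, dle = dle,
    pct_disabled = 100 * dle / total)
}

#' Marginal (population) life expectancies at an age and profile
#'
#' Weights the state-conditional expectancies by the model-estimated
#' probability of being disabled at the starting age:
#' DFLE = w1 e11 + w2 e21, DLE = w1 e12 + w2 e22 with w2 = P(state 2 |
#' alive, start_age, profile), total LE = DFLE + DLE, and %% disabled =
#' 100 DLE / LE. With \code{conditional = TRUE} the healthy-start row is
#' reported instead (w1 = 1).
#'
#' @inheritParams occupancy
#' @param prev A \code{\link{fit_prevalence}} model.
#' @param conditional Report expectancies conditional on starting healthy.
#' @return Object of class \code{"le_set"}: the \code{e} matrix plus
#'   \code{total_le}, \code{dfle}, \code{dle}, \code{pct_disabled}.
#' @export
marginal_life_expectancies <- function(fitted, prev, profile = list(),
                                       start_age, grid_step = 0.25,
                                       max_age = 115, conditional = FALSE) {
  e <- state_expectancies(fitted, profile, start_age, grid_step, max_age)
  w1 <- if (conditional) 1 else 1 - predict_prevalence(prev, profile, start_age)
  pt <- .le_point(e, w1)
  structure(c(list(age = start_age, profile = profile, e = e, w_healthy = w1),
              as.list(pt)),
            class = "le_set")
}

#' @export
print.le_set <- function(x, ...) {
  cat(sprintf("Age %g: LE %.1f, DFLE %.1f, DLE %.1f, %%disabled %.1f\n",
              x$age, x$total_le, x$dfle, x$dle, x$pct_disabled))
  invisible(x)
}

# Shared draw engine: one set of parameter draws evaluated over several
# profiles and ages, so that derived contrasts/averages can be formed
# per draw. Returns point estimates and an array of draws
# [n_sim, profile, age, quantity].
le_draw_engine <- function(fitted, prev, profiles, ages, n_sim, seed,
                           grid_step = 0.25, max_age = 115,
                           conditional = FALSE) {
  stopifnot(inherits(fitted, "msm_fit"))
  qn <- c("total_le", "dfle", "dle", "pct_disabled")
  eval_one <- function(params) {
    vapply(profiles, function(pr) {
      vapply(ages, function(a) {
        oc <- occupancy_array(params, fitted$spec, pr, a, grid_step, max_age)
        e <- expectancies_from_array(oc, truncation_warn = FALSE)
        w1 <- if (conditional) 1 else 1 - predict_prevalence(prev, pr, a)
        .le_point(e, w1)
      }, numeric(4))
    }, matrix(0, 4, length(ages)))  # dims: quantity x age x profile
  }
  point <- eval_one(fitted$par)
  draws <- NULL
  n_rejected <- 0L
  if (n_sim > 0) {
    set.seed(seed)
    draws <- array(NA_real_, c(n_sim, length(profiles), length(ages), 4),
                   dimnames = list(NULL, names(profiles), ages, qn))
    b <- 1L
    while (b <= n_sim) {
      p <- MASS::mvrnorm(1, fitted$par, fitted$cov)
      val <- tryCatch(eval_one(p), error = function(e) NULL)
      if (is.null(val) || any(!is.finite(val))) {
        n_rejected <- n_rejected + 1L
        if (n_rejected > ceiling(0.1 * n_sim))
          stop("more than 10% of parameter draws rejected as numerically ",
               "unstable; the fitted covariance is likely degenerate")
        next
      }
      draws[b, , , ] <- aperm(val, c(3, 2, 1))
      b <- b + 1L
    }
  }
  list(point = point, draws = draws, quantities = qn,
       n_rejected = n_rejected)
}

#' Life expectancies with simulation-based confidence intervals
#'
#' Draws \code{n_sim} parameter vectors from a multivariate normal centred
#' at the MLE with the fitted covariance, recomputes all expectancies per
#' draw, and reports empirical 2.5/97.5 percentiles; point estimates are
#' the MLE plug-ins. The %% disabled interval is formed per draw (a ratio
#' of draws, not a delta method). Numerically unstable draws are rejected
#' and redrawn (error if they exceed 10%% of \code{n_sim}).
#'
#' @inheritParams marginal_life_expectancies
#' @param ages Vector of starting ages.
#' @param n_sim Number of parameter draws (default 1000).
#' @param seed Seed for the draws (default 20100101).
#' @return Data frame with one row per (age, quantity): \code{estimate},
#'   \code{lower}, \code{upper}; attribute \code{n_rejected}.
#' @export
simulate_cis <- function(fitted, prev, profile = list(), ages,
                         n_sim = 1000, seed = 20100101, grid_step = 0.25,
                         max_age = 115, conditional = FALSE) {
  en <- le_draw_engine(fitted, prev, list(p = profile), ages, n_sim, seed,
                       grid_step, max_age, conditional)
  out <- expand.grid(quantity = en$quantities, age = ages,
                     stringsAsFactors = FALSE)
  out$estimate <- as.numeric(en$point)   # quantity fastest, then age
  if (!is.null(en$draws)) {
    qlo <- apply(en$draws[, 1, , , drop = FALSE], c(3, 4), stats::quantile,
                 probs = 0.025, names = FALSE)
    qhi <- apply(en$draws[, 1, , , drop = FALSE], c(3, 4), stats::quantile,
                 probs = 0.975, names = FALSE)
    out$lower <- as.numeric(t(qlo))
    out$upper <- as.numeric(t(qhi))
  }
  out <- out[, c("age", setdiff(names(out), "age"))]
  attr(out, "n_rejected") <- en$n_rejected
  out
}
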