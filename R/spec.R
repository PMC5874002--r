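# Illness-death model with recovery: states 1 = healthy, 2 = functionally
# limited, 3 = dead (absorbing). Four transitions are modelled.

.TRANSITIONS <- data.frame(
  from  = c(1L, 2L, 1L, 2L),
  to    = c(2L, 1L, 3L, 3L),
  label = c("Disability incidence", "Recovery",
            "Mortality of non-disabled", "Mortality of disabled"),
  stringsAsFactors = FALSE
)

.trans_code <- function() paste0(.TRANSITIONS$from, "-", .TRANSITIONS$to)

#' Model specification for the three-state disability model
#'
#' Defines the state space (1 healthy, 2 functionally limited, 3 dead), the
#' four allowed transitions (1-2, 2-1, 1-3, 2-3; state 3 absorbing) and the
#' covariate design. Every covariate acts multiplicatively (proportional
#' hazards) on every allowed transition intensity. Age enters as a
#' time-dependent covariate in years, centred at \code{age_center}.
#'
#' @param covariates Ordered covariate names. \code{"age"} is treated
#'   specially (time-dependent, centred); any other name must be a numeric
#'   0/1 column of the data (or derivable from \code{sex}/\code{bmi_cat}).
#' @param age_center Centring constant for age, in years. Baseline
#'   intensities refer to a subject of this age with all other covariates 0.
#' @return An object of class \code{"msm_spec"}.
#' @export
msm_spec <- function(covariates = c("age", "female", "overweight", "obese"),
                     age_center = 70) {
  stopifnot(is.character(covariates), !anyDuplicated(covariates),
            is.numeric(age_center), length(age_center) == 1L,
            is.finite(age_center))
  structure(list(states = 1:3,
                 transitions = .TRANSITIONS,
                 covariates = covariates,
                 age_center = age_center),
            class = "msm_spec")
}

#' @export
print.msm_spec <- function(x, ...) {
  cat("Three-state illness-death model with recovery\n")
  cat("  transitions:", paste(.trans_code(), collapse = ", "), "\n")
  cat("  covariates :", paste(x$covariates, collapse = ", "),
      sprintf("(age centred at %g)\n", x$age_center))
  invisible(x)
}

# Names of the flat parameter vector: baseline block then one block per
# covariate, four transitions each, in the fixed transition order.
param_names <- function(spec) {
  tc <- .trans_code()
  c(paste0("logq[", tc, "]"),
    unlist(lapply(spec$covariates, function(k) paste0(k, "[", tc, "]"))))
}

n_params <- function(spec) 4L * (1L + length(spec$covariates))

# Reshape flat parameter vector into a (1 + k) x 4 coefficient matrix:
# row 1 = log baseline intensities, remaining rows = covariate log-HRs.
par_matrix <- function(params, spec) {
  p <- n_params(spec)
  if (length(params) != p)
    stop("parameter vector has length ", length(params), ", expected ", p)
  # -Inf is allowed (a switched-off transition); NA/NaN/+Inf are not
  if (anyNA(params) || any(params == Inf))
    stop("invalid parameters (NA or +Inf)")
  matrix(params, nrow = 1L + length(spec$covariates), ncol = 4L, byrow = TRUE,
         dimnames = list(c("(baseline)", spec$covariates), .trans_code()))
}

# Covariate row (excluding intercept) for one profile at one age.
profile_row <- function(spec, covariates, age) {
  vapply(spec$covariates, function(k) {
    if (k == "age") return(age - spec$age_center)
    v <- covariates[[k]]
    if (is.null(v)) stop("profile is missing covariate '", k, "'")
    as.numeric(v)
  }, numeric(1))
}

#' Transition intensity matrix
#'
#' Builds the 3x3 generator Q at a given age and covariate profile:
#' \eqn{q_{rs} = \exp(\theta_{rs} + \sum_k \beta_{k,rs} z_k)} on the four
#' allowed transitions, zero elsewhere off-diagonal, diagonal equal to minus
#' the row sum, and an all-zero absorbing third row.
#'
#' @param params Flat parameter vector (see \code{\link{msm_spec}} for the
#'   layout: 4 log baseline intensities then 4 log-HRs per covariate).
#' @param covariates Named list/vector of covariate values (e.g.
#'   \code{list(female = 1, overweight = 0, obese = 0)}).
#' @param age Age in years at which the intensities are evaluated.
#' @param spec An \code{\link{msm_spec}}.
#' @return A 3x3 intensity matrix with rows summing to zero.
#' @export
intensity_matrix <- function(params, covariates = list(), age = NULL,
                             spec = msm_spec()) {
  B <- par_matrix(params, spec)
  if (is.null(age)) age <- spec$age_center
  z <- profile_row(spec, covariates, age)
  lp <- B[1L, ] + as.numeric(z %*% B[-1L, , drop = FALSE])
  q <- exp(lp)
  if (!all(is.finite(q))) stop("overflow in exp(): intensities not finite")
  Q <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  for (i in seq_len(4L)) Q[.TRANSITIONS$from[i], .TRANSITIONS$to[i]] <- q[i]
  diag(Q) <- -rowSums(Q)
  Q
}

# Closed-form matrix exponential of the 2x2 living-state block, vectorised
# over intervals. For generators of this class the block eigenvalues are
# real (discriminant = ((a11-a22)/2)^2 + q12*q21 >= 0), so
#   expm(dt A) = e^{m dt} [ cosh(d dt) I + sinh(d dt)/d (A - m I) ],
# with m = trace/2 and d = sqrt(discriminant).
pmat_alive <- function(q12, q21, q13, q23, dt) {
  a11 <- -(q12 + q13)
  a22 <- -(q21 + q23)
  m  <- (a11 + a22) / 2
  d  <- sqrt(pmax(((a11 - a22) / 2)^2 + q12 * q21, 0))
  l1 <- m + d
  l2 <- m - d
  E1 <- exp(l1 * dt)
  E2 <- exp(l2 * dt)
  C  <- (E1 + E2) / 2
  x  <- d * dt
  # sinh(x)/x * dt * e^{m dt}; series branch keeps d -> 0 stable
  S  <- ifelse(x > 1e-6, (E1 - E2) / (2 * d), dt * exp(m * dt) * (1 + x^2 / 6))
  P11 <- pmin(pmax(C + S * (a11 - m), 0), 1)
  P22 <- pmin(pmax(C + S * (a22 - m), 0), 1)
  P12 <- pmin(pmax(S * q12, 0), 1)
  P21 <- pmin(pmax(S * q21, 0), 1)
  list(P11 = P11, P12 = P12, P13 = pmax(1 - P11 - P12, 0),
       P21 = P21, P22 = P22, P23 = pmax(1 - P21 - P22, 0))
}

#' Interval transition probability matrix
#'
#' Probability matrix P(age0, age1) of the continuous-time model. By default
#' the generator is held constant at its value at \code{age0} over the whole
#' interval (the panel-data convention used in the likelihood); a finer
#' internal grid that refreshes the age-dependent intensities can be
#' requested with \code{grid_step}.
#'
#' @inheritParams intensity_matrix
#' @param age0,age1 Interval endpoints in years, \code{age1 >= age0}.
#' @param grid_step Optional internal step (years) at which Q is refreshed.
#' @return A 3x3 row-stochastic matrix.
#' @export
transition_probability <- function(params, covariates = list(), age0, age1,
                                   spec = msm_spec(), grid_step = NULL) {
  if (age1 < age0) stop("age1 must be >= age0")
  if (is.null(grid_step)) {
    breaks <- c(age0, age1)
  } else {
    stopifnot(grid_step > 0)
    breaks <- unique(c(seq(age0, age1, by = grid_step), age1))
  }
  P <- diag(3)
  for (i in seq_len(length(breaks) - 1L)) {
    Q <- intensity_matrix(params, covariates, breaks[i], spec)
    pm <- pmat_alive(Q[1, 2], Q[2, 1], Q[1, 3], Q[2, 3],
                     breaks[i + 1L] - breaks[i])
    Pstep <- rbind(c(pm$P11, pm$P12, pm$P13),
                   c(pm$P21, pm$P22, pm$P23),
                   c(0, 0, 1))
    P <- P %*% Pstep
  }
  dimnames(P) <- list(1:3, 1:3)
  P
}
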