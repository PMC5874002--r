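# Panel likelihood for the three-state model: interval-censored state
# observations, exact death times and right censoring ("alive, state
# unknown"). The generator is held constant within each observation
# interval at its value at the interval start.

.OBSTYPES <- c("panel", "death", "censored")

# Validate a long-format dataset and flatten it into one row per
# consecutive observation pair. Covariate dummies are derived from
# sex / bmi_cat columns when not already present.
ms_intervals <- function(data, spec = msm_spec()) {
  req <- c("id", "age", "state", "obstype")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "))
  data <- as.data.frame(data)
  if (!all(data$obstype %in% .OBSTYPES))
    stop("obstype must be one of ", paste(.OBSTYPES, collapse = "/"))
  if (is.null(data$female) && !is.null(data$sex))
    data$female <- as.numeric(data$sex == "female")
  if (is.null(data$overweight) && !is.null(data$bmi_cat))
    data$overweight <- as.numeric(data$bmi_cat == "overweight")
  if (is.null(data$obese) && !is.null(data$bmi_cat))
    data$obese <- as.numeric(data$bmi_cat == "obese")
  covs <- setdiff(spec$covariates, "age")
  missing_cov <- setdiff(covs, names(data))
  if (length(missing_cov))
    stop("data lacks covariate column(s): ", paste(missing_cov, collapse = ", "))

  data <- data[order(data$id, data$age), , drop = FALSE]
  id <- data$id
  n <- nrow(data)
  same <- id[-1] == id[-n]           # consecutive rows in the same subject
  i0 <- which(same)                  # start record index
  i1 <- i0 + 1L                      # end record index

  dt <- data$age[i1] - data$age[i0]
  if (any(dt <= 0))
    stop("ages must be strictly increasing within subject")
  from <- data$state[i0]
  if (any(is.na(from)) || any(!from %in% 1:2))
    stop("interval start states must be observed and alive (1 or 2); ",
         "records after death are invalid")
  type <- data$obstype[i1]
  to <- data$state[i1]
  if (any(type == "death" & (is.na(to) | to != 3L)))
    stop("exact-death records must have state 3")
  if (any(type == "panel" & is.na(to)))
    stop("panel records must have an observed state")
  if (any(type == "censored" & !is.na(to) & to == 3L))
    stop("censored records are alive with unknown state")
  if (any(data$obstype[i0] %in% c("death", "censored")))
    stop("death/censored records must be terminal within subject")

  iv <- data.frame(id = id[i0], from = from, to = to,
                   type = match(type, .OBSTYPES),   # 1 panel, 2 death, 3 cens
                   age0 = data$age[i0], dt = dt)
  for (k in covs) iv[[k]] <- as.numeric(data[[k]][i0])
  attr(iv, "n_subjects") <- length(unique(id))
  iv
}

# Precompute everything about the data that the likelihood reuses at
# every parameter value: the per-interval design matrix and the index
# sets of each (start state, record type, end state) combination.
iv_prepare <- function(iv, spec) {
  covs <- setdiff(spec$covariates, "age")
  Z <- cbind(1, if ("age" %in% spec$covariates) iv$age0 - spec$age_center,
             as.matrix(iv[covs]))
  rows <- c("(baseline)", if ("age" %in% spec$covariates) "age", covs)
  pan <- iv$type == 1L
  f1 <- iv$from == 1L
  idx <- function(cond) which(cond)
  list(Z = Z, rows = rows, dt = iv$dt, n = nrow(iv), id = iv$id,
       i11 = idx(pan & f1 & iv$to == 1L), i12 = idx(pan & f1 & iv$to == 2L),
       i13 = idx(pan & f1 & iv$to == 3L),
       i21 = idx(pan & !f1 & iv$to == 1L), i22 = idx(pan & !f1 & iv$to == 2L),
       i23 = idx(pan & !f1 & iv$to == 3L),
       id1 = idx(iv$type == 2L & f1), id2 = idx(iv$type == 2L & !f1),
       ic1 = idx(iv$type == 3L & f1), ic2 = idx(iv$type == 3L & !f1))
}

# Per-interval log-likelihood contributions given the flat parameter
# vector; the fast path behind both msm_loglik() and the optimiser.
.prep_loglik <- function(params, prep, spec) {
  B <- tryCatch(par_matrix(params, spec), error = function(e) NULL)
  if (is.null(B)) return(rep(-Inf, prep$n))
  q <- exp(prep$Z %*% B[prep$rows, , drop = FALSE])  # n x 4: q12 q21 q13 q23
  if (!all(is.finite(q))) return(rep(-Inf, prep$n))
  P <- pmat_alive(q[, 1], q[, 2], q[, 3], q[, 4], prep$dt)
  lik <- numeric(prep$n)
  # panel-observed end state (including a panel-observed death)
  lik[prep$i11] <- P$P11[prep$i11]
  lik[prep$i12] <- P$P12[prep$i12]
  lik[prep$i13] <- P$P13[prep$i13]
  lik[prep$i21] <- P$P21[prep$i21]
  lik[prep$i22] <- P$P22[prep$i22]
  lik[prep$i23] <- P$P23[prep$i23]
  # exact death at the interval end: sum over the latent living state,
  # with the mortality intensities evaluated at the interval start
  i <- prep$id1
  lik[i] <- P$P11[i] * q[i, 3] + P$P12[i] * q[i, 4]
  i <- prep$id2
  lik[i] <- P$P21[i] * q[i, 3] + P$P22[i] * q[i, 4]
  # right-censored alive, state unknown
  i <- prep$ic1
  lik[i] <- P$P11[i] + P$P12[i]
  i <- prep$ic2
  lik[i] <- P$P21[i] + P$P22[i]
  log(lik)
}

.iv_loglik <- function(params, iv, spec) {
  .prep_loglik(params, iv_prepare(iv, spec), spec)
}

#' Panel log-likelihood of the three-state model
#'
#' Sums, over consecutive observation pairs within subject, the log of:
#' the interval transition probability (panel records), the density of an
#' exactly observed death marginalised over the latent living state
#' (death records), or the probability of being alive in either living
#' state (right-censored records).
#'
#' @param params Flat parameter vector (see \code{\link{msm_spec}}).
#' @param data Long-format dataset (columns \code{id, age, state, obstype}
#'   plus covariates).
#' @param spec An \code{\link{msm_spec}}.
#' @param by_subject If \code{TRUE}, return the per-subject contributions.
#' @return The log-likelihood (or a named vector of per-subject values).
#'   Zero-probability paths yield \code{-Inf}.
#' @export
msm_loglik <- function(params, data, spec = msm_spec(), by_subject = FALSE) {
  iv <- if (inherits(data, "ms_intervals")) data else ms_intervals(data, spec)
  ll <- .iv_loglik(params, iv, spec)
  if (by_subject) {
    tapply(ll, iv$id, sum)
  } else {
    sum(ll)
  }
}

# Crude initial values: observed r->s panel moves (treated as direct) and
# exact deaths over person-time at risk in r; floored at 1e-4.
crude_init <- function(iv, spec) {
  py <- c(sum(iv$dt[iv$from == 1L]), sum(iv$dt[iv$from == 2L]))
  cnt <- c(sum(iv$type == 1L & iv$from == 1L & iv$to == 2L),
           sum(iv$type == 1L & iv$from == 2L & iv$to == 1L),
           sum(iv$from == 1L & (iv$type == 2L |
                                  (iv$type == 1L & iv$to == 3L))),
           sum(iv$from == 2L & (iv$type == 2L |
                                  (iv$type == 1L & iv$to == 3L))))
  if (any(cnt == 0L))
    warning("no crude observations for transition(s) ",
            paste(.trans_code()[cnt == 0L], collapse = ", "))
  rate <- pmax(cnt / pmax(py, 1e-8), 1e-4)
  init <- numeric(n_params(spec))
  init[1:4] <- log(rate)
  names(init) <- param_names(spec)
  init
}

#' Fit the three-state model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximisation of the panel likelihood with numeric
#' derivatives; the covariance matrix is the inverse of the numerically
#' differenced observed information at the MLE (Moore-Penrose pseudo-inverse
#' with a warning when the information is singular).
#'
#' @param data Long-format panel dataset.
#' @param spec An \code{\link{msm_spec}}.
#' @param init Optional initial flat parameter vector; by default log crude
#'   rates for the baselines and 0 for the covariate effects.
#' @param control Passed to \code{\link[stats]{optim}} (after defaults
#'   \code{maxit = 500}, \code{reltol = 1e-10}).
#' @return An object of class \code{"msm_fit"}: \code{par} (named MLE),
#'   \code{loglik}, \code{cov}, \code{se}, \code{spec} and a
#'   \code{convergence} report (code, iteration/evaluation counts, max-norm
#'   of the numeric score at the MLE).
#' @export
msm_fit <- function(data, spec = msm_spec(), init = NULL, control = list()) {
  iv <- ms_intervals(data, spec)
  if (is.null(init)) init <- crude_init(iv, spec)
  if (length(init) != n_params(spec)) stop("init has the wrong length")
  prep <- iv_prepare(iv, spec)
  nll <- function(p) {
    v <- -sum(.prep_loglik(p, prep, spec))
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- stats::optim(init, nll, method = "BFGS", control = ctrl)
  if (opt$convergence != 0L)
    warning("optimiser did not report convergence (code ", opt$convergence,
            "); returning best parameters found")
  par <- opt$par
  names(par) <- param_names(spec)

  # numeric score (central differences) at the MLE, for the report
  h <- 1e-5
  grad <- vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h
    (nll(par + e) - nll(par - e)) / (2 * h)
  }, numeric(1))

  H <- stats::optimHess(par, nll)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) < 0)) {
    warning("observed information singular or indefinite; ",
            "using Moore-Penrose pseudo-inverse")
    cov <- MASS::ginv(H)
  }
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(par), names(par))

  structure(list(par = par, loglik = -opt$value, cov = cov,
                 se = sqrt(pmax(diag(cov), 0)), spec = spec,
                 convergence = list(code = opt$convergence,
                                    counts = opt$counts,
                                    gradient_max_norm = max(abs(grad))),
                 n_subjects = attr(iv, "n_subjects"),
                 n_intervals = nrow(iv), init = init),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("Three-state panel-data fit: %d subjects, %d intervals\n",
              x$n_subjects, x$n_intervals))
  cat(sprintf("  log-likelihood %.3f; convergence code %d; |score| %.2e\n",
              x$loglik, x$convergence$code, x$convergence$gradient_max_norm))
  print(round(cbind(estimate = x$par, se = x$se), 4))
  invisible(x)
}

#' Serialise a fitted model to JSON
#'
#' Writes the labelled MLE, covariance matrix, log-likelihood and
#' convergence report, plus the model's covariates and age-centring
#' constant, as a JSON file.
#'
#' @param fitted An \code{\link{msm_fit}} object.
#' @param path Output file path.
#' @export
write_msm_fit <- function(fitted, path) {
  stopifnot(inherits(fitted, "msm_fit"))
  obj <- list(parameter_names = names(fitted$par),
              mle = unname(fitted$par),
              covariance = apply(fitted$cov, 1, as.numeric,
                                 simplify = FALSE),
              log_likelihood = fitted$loglik,
              convergence = fitted$convergence,
              covariates = fitted$spec$covariates,
              age_center = fitted$spec$age_center,
              n_subjects = fitted$n_subjects,
              n_intervals = fitted$n_intervals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hazard-ratio table from a fitted model
#'
#' Exponentiated covariate effects per transition with Wald confidence
#' intervals \eqn{\exp(\beta \pm z_{1-\alpha/2} \, se)}.
#'
#' @param fitted An \code{\link{msm_fit}} object.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per transition x covariate: \code{hr},
#'   \code{lower}, \code{upper}, \code{se_log}.
#' @export
hazard_ratios <- function(fitted, conf_level = 0.95) {
  stopifnot(inherits(fitted, "msm_fit"))
  spec <- fitted$spec
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- expand.grid(transition = .TRANSITIONS$label,
                      covariate = spec$covariates,
                      stringsAsFactors = FALSE)
  nm <- paste0(rows$covariate, "[",
               .trans_code()[match(rows$transition, .TRANSITIONS$label)], "]")
  beta <- fitted$par[nm]
  se <- fitted$se[nm]
  data.frame(rows,
             hr = exp(beta), lower = exp(beta - z * se),
             upper = exp(beta + z * se), se_log = se,
             row.names = NULL)
}
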