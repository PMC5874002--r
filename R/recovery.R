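# Parameter-recovery simulation: generate cohorts from a known truth,
# refit the model, and summarise how well the hazard ratios are recovered.

#' Parameter-recovery simulation study
#'
#' Generates \code{n_replicates} synthetic cohorts from a known
#' ground-truth parameter vector, fits the three-state model to each, and
#' collects the estimated hazard ratios per transition and covariate. The
#' default cohort emulates the Santiago design scaled to 4000 subjects
#' with baseline ages 60-90 (interviews at 0/~4.5/~9.5 years,
#' administrative censoring at 10.5 years).
#'
#' @param n_replicates Number of simulated cohorts (default 25).
#' @param cohort A \code{\link{cohort_config}} template; its seed is
#'   replaced by a per-replicate seed derived from \code{seed}.
#' @param seed Master seed for the replicate seeds.
#' @return Object of class \code{"recovery_study"}: \code{estimates}
#'   (data frame: replicate, transition, covariate, hr),
#'   \code{truth} (generating HRs), \code{convergence_codes}.
#' @export
recovery_study <- function(n_replicates = 25,
                           cohort = cohort_config(n_subjects = 4000,
                                                  age_top = 90),
                           seed = 20100101) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  spec <- msm_spec()
  res <- vector("list", n_replicates)
  codes <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- cohort
    cfg$seed <- seeds[r]
    dat <- observe_cohort(cfg)$data
    fit <- suppressWarnings(msm_fit(dat, spec))
    codes[r] <- fit$convergence$code
    hr <- hazard_ratios(fit)
    res[[r]] <- cbind(replicate = r, hr[c("transition", "covariate", "hr")])
  }
  B <- par_matrix(cohort$true_params, spec)
  truth <- data.frame(transition = rep(.TRANSITIONS$label,
                                       times = length(spec$covariates)),
                      covariate = rep(spec$covariates, each = 4),
                      hr = exp(as.numeric(t(B[-1, , drop = FALSE]))))
  structure(list(estimates = do.call(rbind, res), truth = truth,
                 convergence_codes = codes, seed = seed),
            class = "recovery_study")
}

#' Median recovered hazard ratio
#'
#' @param study A \code{\link{recovery_study}}.
#' @param transition Transition label (e.g. "Disability incidence").
#' @param covariate Covariate name (e.g. "female").
#' @return Median of the replicate HR estimates.
#' @export
median_recovered_hr <- function(study, transition, covariate) {
  e <- study$estimates
  v <- e$hr[e$transition == transition & e$covariate == covariate]
  if (!length(v)) stop("no such transition/covariate in the study")
  stats::median(v)
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter-recovery study: %d replicates (%d converged)\n",
              length(x$convergence_codes), sum(x$convergence_codes == 0)))
  agg <- stats::aggregate(hr ~ transition + covariate, x$estimates,
                          stats::median)
  names(agg)[3] <- "median_hr"
  agg$truth_hr <- x$truth$hr[match(paste(agg$transition, agg$covariate),
                                   paste(x$truth$transition,
                                         x$truth$covariate))]
  print(agg, digits = 3)
  invisible(x)
}
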