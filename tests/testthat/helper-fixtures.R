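# Shared fixtures and toy-model builders.

# Flat parameter vector with given baseline intensities (on the rate
# scale; 0 switches a transition off) and optional covariate log-HR
# blocks, in the transition order 1-2, 2-1, 1-3, 2-3.
toy_params <- function(q12 = 0, q21 = 0, q13 = 0, q23 = 0,
                       beta_age = rep(0, 4), beta_female = rep(0, 4),
                       beta_overweight = rep(0, 4), beta_obese = rep(0, 4)) {
  th <- log(c(q12, q21, q13, q23))
  stats::setNames(c(th, beta_age, beta_female, beta_overweight, beta_obese),
                  mslife:::param_names(msm_spec()))
}

ref_profile <- list(female = 0, overweight = 0, obese = 0)

# Memoised medium cohorts so several tests can share one generation.
.fixture_env <- new.env(parent = emptyenv())

test_cohort <- function(n = 1216, seed = 20100101, age_top = 96) {
  key <- paste0("c", n, "_", seed, "_", age_top)
  if (is.null(.fixture_env[[key]])) {
    cfg <- cohort_config(n_subjects = n, seed = seed, age_top = age_top)
    .fixture_env[[key]] <- observe_cohort(cfg)
  }
  .fixture_env[[key]]
}

# One fitted default cohort (no CIs) shared across pattern checks.
test_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    co <- test_cohort()
    cfg <- analysis_config(data = co$data, n_sim = 0)
    .fixture_env$analysis <- suppressWarnings(run_full_analysis(cfg))
  }
  .fixture_env$analysis
}
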