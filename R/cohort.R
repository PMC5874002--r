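# Synthetic cohort generator emulating the Santiago ageing-survey design:
# community-dwelling subjects aged 60+ recruited at baseline, two
# follow-up interview waves (~4.5 and ~9.5 years later), deaths
# ascertained exactly from a registry up to an administrative cut-off,
# and a large right-censored "alive but state unknown" group.

#' Ground-truth parameter vector for the synthetic cohort
#'
#' Builds a flat parameter vector (layout of \code{\link{msm_spec}}) from
#' log baseline intensities and per-transition covariate log hazard
#' ratios. Defaults: covariate log-HRs equal the published point estimates
#' for the Santiago cohort (\code{\link{reference_hazard_ratios}}), and
#' baseline intensities (reference subject: male, normal BMI, age 70) are
#' calibrated so that simulated life expectancy at age 60 is in the
#' vicinity of the published values; exact calibration is not claimed.
#'
#' @param theta Log baseline intensities for transitions 1-2, 2-1, 1-3,
#'   2-3 at the reference profile.
#' @param beta_age,beta_female,beta_overweight,beta_obese Log hazard
#'   ratios per transition (same order).
#' @return Named flat parameter vector compatible with \code{msm_spec()}.
#' @export
ground_truth <- function(theta = log(c(0.095, 0.120, 0.012, 0.090)),
                         beta_age = log(c(1.06, 0.97, 1.06, 1.06)),
                         beta_female = log(c(1.82, 1.37, 0.15, 0.64)),
                         beta_overweight = log(c(1.03, 0.74, 0.93, 0.81)),
                         beta_obese = log(c(1.56, 1.42, 0.10, 0.91))) {
  p <- c(theta, beta_age, beta_female, beta_overweight, beta_obese)
  if (length(p) != 20L || anyNA(p) || any(p == Inf))
    stop("each block must contain four values, none NA or +Inf")
  stats::setNames(p, param_names(msm_spec()))
}

#' Configuration of the synthetic cohort
#'
#' All knobs of the generator. Defaults emulate the Santiago design:
#' 1216 subjects, baseline age 60+ drawn from per-sex decade weights,
#' two follow-up waves at 4.5 and 9.5 years with +/- 0.5 y per-subject
#' jitter, administrative censoring at 10.5 years, and wave non-response
#' probabilities calibrated to the published follow-up flow (interviewed /
#' dead / alive-unknown at each stage).
#'
#' @param n_subjects Number of subjects.
#' @param sex_fraction_female Proportion of women.
#' @param age_weights 3 x 2 matrix of baseline-age decade weights (rows
#'   60-69 / 70-79 / 80+, columns male / female); each column sums to 1.
#' @param age_top Upper bound of the open 80+ band (uniform within bands).
#' @param bmi_category_probs 4 x 2 matrix of probabilities over
#'   underweight / normal / overweight / obese, columns male / female.
#' @param wave_offsets_years Follow-up interview offsets from baseline.
#' @param wave_jitter_years Half-width of the per-subject uniform jitter
#'   on each wave offset.
#' @param admin_censor_years Registry cut-off, years from baseline; must
#'   be at least the last wave offset plus the jitter.
#' @param wave_nonresponse_prob Per-wave probability that an alive subject
#'   is not interviewed (recycled to the number of waves).
#' @param burn_in_years Trajectories start healthy this many years before
#'   baseline, so baseline disability prevalence rises with age
#'   endogenously; subjects dying during burn-in are redrawn.
#' @param micro_step Piecewise-constant approximation step (years) for the
#'   age-dependent intensities during simulation.
#' @param true_params Generating parameter vector
#'   (\code{\link{ground_truth}}).
#' @param seed Integer seed; subjects get independent RNG substreams, so
#'   enlarging the cohort never perturbs existing subjects.
#' @return Object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_subjects = 1216,
                          sex_fraction_female = 806 / 1216,
                          age_weights = cbind(
                            male = c(0.566, 0.329, 0.105),
                            female = c(0.493, 0.332, 0.175)),
                          age_top = 96,
                          bmi_category_probs = cbind(
                            male = c(0.015, 0.305, 0.451, 0.229),
                            female = c(0.017, 0.253, 0.393, 0.337)),
                          wave_offsets_years = c(4.5, 9.5),
                          wave_jitter_years = 0.5,
                          admin_censor_years = 10.5,
                          wave_nonresponse_prob = c(0.42, 0.53),
                          burn_in_years = 5,
                          micro_step = 0.1,
                          true_params = ground_truth(),
                          seed = 20100101) {
  stopifnot(n_subjects >= 1,
            sex_fraction_female >= 0, sex_fraction_female <= 1,
            nrow(age_weights) == 3, ncol(age_weights) == 2,
            all(age_weights >= 0),
            nrow(bmi_category_probs) == 4, ncol(bmi_category_probs) == 2,
            all(bmi_category_probs >= 0),
            all(diff(wave_offsets_years) > 0), wave_jitter_years >= 0,
            micro_step > 0, burn_in_years >= 0, age_top > 80)
  if (any(abs(colSums(bmi_category_probs) - 1) > 1e-6))
    stop("bmi_category_probs columns must sum to 1")
  age_weights <- sweep(age_weights, 2, colSums(age_weights), "/")
  if (admin_censor_years <
      max(wave_offsets_years) + wave_jitter_years)
    stop("admin_censor_years must cover the last wave offset plus jitter")
  par_matrix(true_params, msm_spec())   # validates length/finiteness
  structure(list(n_subjects = as.integer(n_subjects),
                 sex_fraction_female = sex_fraction_female,
                 age_weights = age_weights, age_top = age_top,
                 bmi_category_probs = bmi_category_probs,
                 wave_offsets_years = wave_offsets_years,
                 wave_jitter_years = wave_jitter_years,
                 admin_censor_years = admin_censor_years,
                 wave_nonresponse_prob =
                   rep_len(wave_nonresponse_prob,
                           length(wave_offsets_years)),
                 burn_in_years = burn_in_years, micro_step = micro_step,
                 true_params = true_params, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one trajectory of the three-state process
#'
#' Forward simulation under the age-dependent generator, approximated as
#' piecewise constant over \code{micro_step}-year segments: within each
#' segment the sojourn is exponential with the competing-risks exit rates
#' frozen at the segment-start age. Uses the current RNG state.
#'
#' @param covariates Named list of covariate values (excluding age).
#' @param start_age Age at the start of simulation.
#' @param start_state Initial state, 1 or 2.
#' @param truth Generating parameter vector (\code{\link{ground_truth}}).
#' @param horizon Years to simulate.
#' @param micro_step Piecewise-constant step in years (default 0.1).
#' @param spec An \code{\link{msm_spec}}.
#' @return Object of class \code{"ms_trajectory"}: \code{start_age},
#'   \code{start_state}, \code{event_ages}, \code{event_states} (state
#'   entered at each change, strictly increasing ages, alternating living
#'   states until an optional terminal 3) and \code{death_age} (NA if
#'   alive at the horizon).
#' @export
simulate_trajectory <- function(covariates, start_age, start_state, truth,
                                horizon, micro_step = 0.1,
                                spec = msm_spec()) {
  stopifnot(start_state %in% 1:2, horizon > 0, micro_step > 0)
  B <- par_matrix(truth, spec)
  covs <- setdiff(spec$covariates, "age")
  z <- vapply(covs, function(k) as.numeric(covariates[[k]]), numeric(1))
  lp_fix <- B[1, ] + if (length(covs))
    as.numeric(z %*% B[covs, , drop = FALSE]) else 0
  bage <- if ("age" %in% spec$covariates) B["age", ] else numeric(4)

  state <- as.integer(start_state)
  t <- 0
  ev_age <- numeric(0)
  ev_state <- integer(0)
  death_age <- NA_real_
  while (t < horizon - 1e-12 && state != 3L) {
    q <- exp(lp_fix + bage * (start_age + t - spec$age_center))
    if (!all(is.finite(q))) stop("non-finite intensities during simulation")
    # exit rates from the current state: (destination, rate)
    if (state == 1L) {
      dest <- c(2L, 3L); r <- c(q[1], q[3])
    } else {
      dest <- c(1L, 3L); r <- c(q[2], q[4])
    }
    R <- r[1] + r[2]
    seg <- min(micro_step, horizon - t)
    if (R <= 0) { t <- t + seg; next }
    w <- stats::rexp(1, R)
    if (w >= seg) { t <- t + seg; next }
    t <- t + w
    state <- if (stats::runif(1) * R < r[1]) dest[1] else dest[2]
    ev_age <- c(ev_age, start_age + t)
    ev_state <- c(ev_state, state)
    if (state == 3L) death_age <- start_age + t
  }
  structure(list(start_age = start_age, start_state = as.integer(start_state),
                 event_ages = ev_age, event_states = ev_state,
                 death_age = death_age),
            class = "ms_trajectory")
}

#' State of a trajectory at a given age
#'
#' @param traj An \code{\link{simulate_trajectory}} result.
#' @param age Age at which to read the state.
#' @return Integer state 1, 2 or 3.
#' @export
state_at <- function(traj, age) {
  if (age < traj$start_age) stop("age precedes the trajectory start")
  k <- sum(traj$event_ages <= age)
  if (k == 0L) traj$start_state else traj$event_states[k]
}

# Draw ADL/IADL/MF item counts consistent with the current state: a
# limited subject satisfies at least one of the three criteria (>=1 ADL,
# >=2 IADL, >=3 MF); a healthy subject satisfies none.
draw_limitation_counts <- function(limited) {
  if (!limited) {
    c(adl = 0L,
      iadl = sample.int(2L, 1L, prob = c(0.85, 0.15)) - 1L,
      mf = sample.int(3L, 1L, prob = c(0.60, 0.25, 0.15)) - 1L)
  } else {
    repeat {
      hit <- stats::runif(3) < c(0.55, 0.40, 0.70)
      if (any(hit)) break
    }
    c(adl = if (hit[1])
        sample.int(6L, 1L, prob = c(0.45, 0.25, 0.12, 0.08, 0.06, 0.04))
      else 0L,
      iadl = if (hit[2]) 1L + sample.int(4L, 1L, prob = c(0.5, 0.25, 0.15,
                                                          0.1))
      else sample.int(2L, 1L, prob = c(0.7, 0.3)) - 1L,
      mf = if (hit[3]) 2L + sample.int(9L, 1L,
                                       prob = c(0.22, 0.18, 0.15, 0.12,
                                                0.1, 0.09, 0.06, 0.05, 0.03))
      else sample.int(3L, 1L, prob = c(0.5, 0.3, 0.2)) - 1L)
  }
}

.BMI_RANGES <- list(underweight = c(16, 18.5), normal = c(18.5, 25),
                    overweight = c(25, 30), obese = c(30, 40))

#' Generate an observed synthetic cohort
#'
#' Simulates each subject's ground-truth trajectory (from a healthy state
#' \code{burn_in_years} before baseline, conditioned on being alive at
#' baseline) and applies the observation scheme: a baseline interview, a
#' per-wave interview when alive and responding, an exact death record at
#' the death age when death occurs before the administrative cut-off, and
#' a right-censored "alive, state unknown" record at the cut-off for alive
#' subjects who missed the final wave. Each subject uses an independent
#' L'Ecuyer RNG substream derived from \code{config$seed}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List with \code{data} (long-format data frame: \code{id, age,
#'   state, obstype, sex, bmi_cat, weight_kg, height_m, adl_count,
#'   iadl_count, mf_count}), \code{trajectories} (ground truth per
#'   subject) and \code{config}.
#' @export
observe_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())

  nw <- length(config$wave_offsets_years)
  rows <- vector("list", config$n_subjects)
  trajs <- vector("list", config$n_subjects)
  horizon <- config$burn_in_years + config$admin_censor_years + 1
  bands <- rbind(c(60, 70), c(70, 80), c(80, config$age_top))

  for (i in seq_len(config$n_subjects)) {
    next_stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, globalenv())

    female <- stats::runif(1) < config$sex_fraction_female
    sexcol <- if (female) 2L else 1L
    band <- sample.int(3L, 1L, prob = config$age_weights[, sexcol])
    age0 <- stats::runif(1, bands[band, 1], bands[band, 2])
    bmi_cat <- .BMI_LEVELS[sample.int(4L, 1L,
                                      prob = config$bmi_category_probs[, sexcol])]
    height <- stats::rnorm(1, if (female) 1.52 else 1.66,
                           if (female) 0.065 else 0.07)
    height <- max(height, 1.30)
    rng <- .BMI_RANGES[[bmi_cat]]
    bmi <- stats::runif(1, rng[1], rng[2])
    weight <- bmi * height^2
    prof <- list(female = as.numeric(female),
                 overweight = as.numeric(bmi_cat == "overweight"),
                 obese = as.numeric(bmi_cat == "obese"))

    for (try in 1:100) {
      traj <- simulate_trajectory(prof, age0 - config$burn_in_years, 1L,
                                  config$true_params, horizon,
                                  config$micro_step)
      if (is.na(traj$death_age) || traj$death_age > age0) break
    }
    if (!is.na(traj$death_age) && traj$death_age <= age0)
      stop("could not obtain a subject alive at baseline; ",
           "check the generating intensities")
    trajs[[i]] <- traj

    jit <- stats::runif(nw, -config$wave_jitter_years,
                        config$wave_jitter_years)
    responds <- stats::runif(nw) >= config$wave_nonresponse_prob
    wave_age <- age0 + config$wave_offsets_years + jit
    censor_age <- age0 + config$admin_censor_years
    dead_by <- function(a) !is.na(traj$death_age) && traj$death_age <= a

    st0 <- state_at(traj, age0)
    cnt <- draw_limitation_counts(st0 == 2L)
    r_age <- age0; r_state <- st0; r_type <- "panel"
    r_cnt <- matrix(cnt, nrow = 1)
    last_wave_seen <- FALSE
    for (w in seq_len(nw)) {
      if (dead_by(wave_age[w])) break
      if (responds[w]) {
        stw <- state_at(traj, wave_age[w])
        cw <- draw_limitation_counts(stw == 2L)
        r_age <- c(r_age, wave_age[w])
        r_state <- c(r_state, stw)
        r_type <- c(r_type, "panel")
        r_cnt <- rbind(r_cnt, cw)
        if (w == nw) last_wave_seen <- TRUE
      }
    }
    if (dead_by(censor_age)) {
      r_age <- c(r_age, traj$death_age)
      r_state <- c(r_state, 3L)
      r_type <- c(r_type, "death")
      r_cnt <- rbind(r_cnt, c(NA, NA, NA))
    } else if (!last_wave_seen) {
      r_age <- c(r_age, censor_age)
      r_state <- c(r_state, NA)
      r_type <- c(r_type, "censored")
      r_cnt <- rbind(r_cnt, c(NA, NA, NA))
    }
    k <- length(r_age)
    rows[[i]] <- data.frame(
      id = rep.int(i, k), age = r_age, state = as.integer(r_state),
      obstype = r_type,
      sex = rep.int(if (female) "female" else "male", k),
      bmi_cat = rep.int(bmi_cat, k),
      weight_kg = rep.int(weight, k),
      height_m = rep.int(height, k),
      adl_count = as.integer(r_cnt[, 1]),
      iadl_count = as.integer(r_cnt[, 2]),
      mf_count = as.integer(r_cnt[, 3]),
      stringsAsFactors = FALSE)

    stream <- next_stream
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data, trajectories = trajs, config = config)
}

#' Write a synthetic cohort to CSV with a JSON sidecar
#'
#' @param cohort Result of \code{\link{observe_cohort}}.
#' @param path CSV path; the generating configuration (including the seed
#'   and true parameters) is stored next to it as \code{<path>.json}.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  cfg_list <- lapply(unclass(cfg), function(x)
    if (is.matrix(x)) as.data.frame(x) else x)
  jsonlite::write_json(cfg_list, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort CSV written by \code{\link{write_cohort}}
#'
#' @param path CSV path.
#' @return Long-format data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
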