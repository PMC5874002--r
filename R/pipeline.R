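# End-to-end orchestration: descriptives, model fit, hazard-ratio table,
# life-expectancy tables by gender and by BMI x gender, figure-ready
# output, all deterministic given the configuration and seeds.

#' Baseline descriptive summary by sex
#'
#' Per sex: mean (sd) baseline age, age-band percentages, BMI-category
#' percentages, the three limitation-criterion percentages (>=1 ADL,
#' >=2 IADL, >=3 MF) and the composite functional-limitation percentage.
#'
#' @param data Long-format dataset with baseline records carrying
#'   \code{adl_count}, \code{iadl_count}, \code{mf_count} and
#'   anthropometry.
#' @return Data frame of statistics (rows) by sex (columns).
#' @export
run_descriptives <- function(data) {
  data <- data[order(data$id, data$age), , drop = FALSE]
  base <- data[!duplicated(data$id), , drop = FALSE]
  if (is.null(base$bmi_cat))
    base$bmi_cat <- as.character(classify_bmi(base$weight_kg, base$height_m))
  lim <- derive_functional_limitation(base$adl_count, base$iadl_count,
                                      base$mf_count)
  one_sex <- function(s) {
    b <- base[base$sex == s, , drop = FALSE]
    l <- lim[base$sex == s]
    pct <- function(x) 100 * mean(x, na.rm = TRUE)
    c(n = nrow(b),
      age_mean = mean(b$age), age_sd = stats::sd(b$age),
      pct_60_69 = pct(b$age < 70),
      pct_70_79 = pct(b$age >= 70 & b$age < 80),
      pct_80_plus = pct(b$age >= 80),
      pct_underweight = pct(b$bmi_cat == "underweight"),
      pct_normal = pct(b$bmi_cat == "normal"),
      pct_overweight = pct(b$bmi_cat == "overweight"),
      pct_obese = pct(b$bmi_cat == "obese"),
      pct_adl1 = pct(b$adl_count >= 1),
      pct_iadl2 = pct(b$iadl_count >= 2),
      pct_mf3 = pct(b$mf_count >= 3),
      pct_functional_limitation = pct(l))
  }
  sexes <- sort(unique(base$sex))
  out <- vapply(sexes, one_sex, numeric(14))
  data.frame(statistic = rownames(out), out, row.names = NULL,
             check.names = FALSE)
}

#' Analysis configuration
#'
#' @param cohort A \code{\link{cohort_config}} used to generate synthetic
#'   data when \code{data} is NULL.
#' @param data Optional long-format dataset (data frame or CSV path);
#'   overrides \code{cohort}.
#' @param ages Ages at which life expectancies are reported.
#' @param n_sim Parameter draws for the confidence intervals; 0 disables
#'   CI columns.
#' @param seed Seed for the CI draws.
#' @param grid_step,max_age Occupancy-integration settings.
#' @param stratified Also fit separate models per BMI category (sex and
#'   age remain covariates) for comparison with the single adjusted fit.
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @return Object of class \code{"analysis_config"}.
#' @export
analysis_config <- function(cohort = cohort_config(), data = NULL,
                            ages = c(60, 70, 80, 90), n_sim = 1000,
                            seed = 20100101, grid_step = 0.25,
                            max_age = 115, stratified = FALSE,
                            out_dir = NULL) {
  stopifnot(!is.unsorted(ages), n_sim >= 0)
  structure(list(cohort = cohort, data = data, ages = ages, n_sim = n_sim,
                 seed = as.integer(seed), grid_step = grid_step,
                 max_age = max_age, stratified = stratified,
                 out_dir = out_dir),
            class = "analysis_config")
}

.profile_grid <- function() {
  g <- expand.grid(sex = c("male", "female"),
                   bmi_cat = c("normal", "overweight", "obese"),
                   stringsAsFactors = FALSE)
  profs <- lapply(seq_len(nrow(g)), function(i)
    list(female = as.numeric(g$sex[i] == "female"),
         overweight = as.numeric(g$bmi_cat[i] == "overweight"),
         obese = as.numeric(g$bmi_cat[i] == "obese")))
  names(profs) <- paste(g$sex, g$bmi_cat, sep = ".")
  list(grid = g, profiles = profs)
}

# tidy rows (age, quantity, estimate[, lower, upper]) from the draw engine
# for one column of weights over profiles
.le_rows <- function(en, ages, weights, with_ci) {
  qn <- en$quantities
  pt <- en$point   # quantity x age x profile
  out <- expand.grid(age = ages, quantity = qn, stringsAsFactors = FALSE)
  comb <- function(arr) {  # quantity x age, weighting profiles; recompute pct
    yrs <- arr[1:3, , , drop = FALSE]   # total_le, dfle, dle
    m <- apply(yrs, c(1, 2), function(v) sum(v * weights))
    rbind(m, 100 * m[3, ] / m[1, ])
  }
  m <- comb(pt)
  out$estimate <- as.numeric(t(m))
  if (with_ci) {
    nd <- dim(en$draws)[1]
    dm <- vapply(seq_len(nd), function(b) {
      arr <- aperm(en$draws[b, , , , drop = FALSE], c(4, 3, 2, 1))
      dim(arr) <- dim(arr)[1:3]
      comb(arr)
    }, matrix(0, 4, length(ages)))
    out$lower <- as.numeric(t(apply(dm, c(1, 2), stats::quantile,
                                    probs = 0.025, names = FALSE)))
    out$upper <- as.numeric(t(apply(dm, c(1, 2), stats::quantile,
                                    probs = 0.975, names = FALSE)))
  }
  out
}

#' Run the full multistate life-table analysis
#'
#' Generates (or loads) the panel dataset, derives the analysis variables
#' and applies the exclusion rules, fits the three-state model, and
#' produces the hazard-ratio table, life-expectancy tables by gender and
#' by BMI x gender, and figure-ready LE/DFLE/DLE-versus-age data. The
#' gender table averages the covariate-adjusted profiles over the sex-
#' specific baseline BMI distribution (per draw for the intervals); the
#' BMI table evaluates the single adjusted fit at each profile.
#' Deterministic given the configuration and seeds.
#'
#' @param config An \code{\link{analysis_config}}.
#' @return List with \code{descriptives}, \code{exclusion_log}, \code{fit},
#'   \code{hr_table}, \code{gender_le}, \code{bmi_le}, \code{figure_data},
#'   \code{provenance} (and \code{stratified_fits} when requested);
#'   written as CSV/JSON under \code{out_dir} when set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  raw <- if (is.null(config$data)) {
    observe_cohort(config$cohort)$data
  } else if (is.character(config$data)) {
    read_cohort(config$data)
  } else as.data.frame(config$data)

  # re-derive the disability state from the item counts on interview rows
  pan <- raw$obstype == "panel"
  raw$state[pan] <- 1L + as.integer(derive_functional_limitation(
    raw$adl_count[pan], raw$iadl_count[pan], raw$mf_count[pan]))
  excl <- apply_exclusions(raw)
  dat <- excl$data

  obs_rng <- range(dat$age)
  if (any(config$ages < obs_rng[1] | config$ages > obs_rng[2]))
    warning(sprintf(paste0("requested ages extend beyond the observed age ",
                           "range (%.1f-%.1f); those expectancies are ",
                           "extrapolations"), obs_rng[1], obs_rng[2]))

  spec <- msm_spec()
  fit <- msm_fit(dat, spec)
  hr <- hazard_ratios(fit)
  prev <- fit_prevalence(dat, spec)

  pg <- .profile_grid()
  en <- le_draw_engine(fit, prev, pg$profiles, config$ages, config$n_sim,
                       config$seed, config$grid_step, config$max_age)
  with_ci <- config$n_sim > 0

  base <- dat[order(dat$id, dat$age), ]
  base <- base[!duplicated(base$id), ]
  gender_le <- do.call(rbind, lapply(c("male", "female"), function(s) {
    tab <- table(factor(base$bmi_cat[base$sex == s],
                        levels = c("normal", "overweight", "obese")))
    w <- as.numeric(tab) / sum(tab)
    wfull <- ifelse(pg$grid$sex == s,
                    w[match(pg$grid$bmi_cat,
                            c("normal", "overweight", "obese"))], 0)
    cbind(sex = s, .le_rows(en, config$ages, wfull, with_ci))
  }))

  bmi_le <- do.call(rbind, lapply(seq_len(nrow(pg$grid)), function(i) {
    w <- as.numeric(seq_len(nrow(pg$grid)) == i)
    cbind(pg$grid[i, , drop = FALSE],
          .le_rows(en, config$ages, w, with_ci), row.names = NULL)
  }))

  fig_ages <- seq(min(config$ages), max(config$ages) + 5, by = 1)
  enf <- le_draw_engine(fit, prev, pg$profiles, fig_ages, 0, config$seed,
                        config$grid_step, config$max_age)
  fig <- do.call(rbind, lapply(c("male", "female"), function(s) {
    tab <- table(factor(base$bmi_cat[base$sex == s],
                        levels = c("normal", "overweight", "obese")))
    w <- as.numeric(tab) / sum(tab)
    wfull <- ifelse(pg$grid$sex == s,
                    w[match(pg$grid$bmi_cat,
                            c("normal", "overweight", "obese"))], 0)
    cbind(sex = s, .le_rows(enf, fig_ages, wfull, FALSE))
  }))

  strat <- NULL
  if (isTRUE(config$stratified)) {
    sspec <- msm_spec(covariates = c("age", "female"))
    strat <- lapply(c("normal", "overweight", "obese"), function(bc) {
      msm_fit(dat[dat$bmi_cat == bc, , drop = FALSE], sspec)
    })
    names(strat) <- c("normal", "overweight", "obese")
  }

  # hash the scientific configuration only (not the output location)
  hcfg <- .serialisable(config)
  hcfg$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(hcfg, auto_unbox = TRUE, digits = NA)
  prov <- list(package_version =
                 as.character(utils::packageVersion("mslife")),
               config_md5 = .md5_string(cfg_json),
               seed_analysis = config$seed,
               seed_cohort = if (is.null(config$data))
                 config$cohort$seed else NULL,
               n_subjects_model = excl$log$n_subjects_retained)

  out <- list(descriptives = run_descriptives(dat),
              exclusion_log = excl$log, fit = fit, hr_table = hr,
              gender_le = gender_le, bmi_le = bmi_le, figure_data = fig,
              stratified_fits = strat, provenance = prov)
  if (!is.null(config$out_dir)) .write_bundle(out, config)
  out
}

.serialisable <- function(x) {
  lapply(unclass(x), function(v) {
    if (inherits(v, "cohort_config")) .serialisable(v)
    else if (is.matrix(v)) as.data.frame(v)
    else if (is.data.frame(v) || is.function(v)) NULL
    else v
  })
}

.md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

.write_bundle <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, nm)
    utils::write.csv(df, file.path(config$out_dir, nm), row.names = FALSE)
  wcsv(out$descriptives, "descriptives.csv")
  wcsv(out$hr_table, "hazard_ratios.csv")
  wcsv(out$gender_le, "le_by_gender.csv")
  wcsv(out$bmi_le, "le_by_bmi.csv")
  wcsv(out$figure_data, "figure_le_by_age.csv")
  write_msm_fit(out$fit, file.path(config$out_dir, "fitted_model.json"))
  jsonlite::write_json(out$exclusion_log,
                       file.path(config$out_dir, "exclusion_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(out$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

#' Round a life-expectancy table for display
#'
#' Years and percentages to one decimal (the convention of the published
#' tables); full precision is retained in the CSV outputs.
#'
#' @param le_table A table from \code{\link{run_full_analysis}}.
#' @return The table with numeric columns rounded.
#' @export
format_le_table <- function(le_table) {
  num <- intersect(c("estimate", "lower", "upper"), names(le_table))
  le_table[num] <- lapply(le_table[num], round, digits = 1)
  le_table
}
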