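# Independent likelihood oracle: discrete-time forward algorithm over the
# living states {1, 2}, stepping each observation interval on a fine grid
# with a truncated-Taylor per-step matrix (second order), the generator
# frozen at the interval-start age as in the model's convention.
oracle_loglik <- function(params, data, spec = msm_spec(), dt = 0.01) {
  data <- data[order(data$id, data$age), , drop = FALSE]
  if (is.null(data$female) && !is.null(data$sex))
    data$female <- as.numeric(data$sex == "female")
  if (is.null(data$overweight) && !is.null(data$bmi_cat))
    data$overweight <- as.numeric(data$bmi_cat == "overweight")
  if (is.null(data$obese) && !is.null(data$bmi_cat))
    data$obese <- as.numeric(data$bmi_cat == "obese")
  out <- vapply(split(data, data$id), function(d) {
    ll <- 0
    for (i in seq_len(nrow(d) - 1L)) {
      prof <- list(female = d$female[i], overweight = d$overweight[i],
                   obese = d$obese[i])
      Q <- intensity_matrix(params, prof, d$age[i], spec)
      A <- Q[1:2, 1:2]
      step_mat <- function(h) diag(2) + A * h + (A %*% A) * h^2 / 2
      Tlen <- d$age[i + 1L] - d$age[i]
      nfull <- floor(Tlen / dt)
      M <- step_mat(dt)
      alpha <- as.numeric(d$state[i] == 1:2)
      for (s in seq_len(nfull)) alpha <- alpha %*% M
      alpha <- alpha %*% step_mat(Tlen - nfull * dt)
      contrib <- switch(d$obstype[i + 1L],
                        panel = if (d$state[i + 1L] == 3L)
                          1 - sum(alpha) else alpha[d$state[i + 1L]],
                        death = sum(alpha * c(Q[1, 3], Q[2, 3])),
                        censored = sum(alpha))
      ll <- ll + log(contrib)
    }
    ll
  }, numeric(1))
  out
}
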