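# Analysis-variable derivation: WHO BMI categories, the composite
# functional-limitation state, and the sample exclusion rules.

.BMI_LEVELS <- c("underweight", "normal", "overweight", "obese")

#' Classify body mass index into WHO categories
#'
#' BMI = weight / height^2 (kg/m^2). Half-open intervals with inclusive
#' lower bounds: [0, 18.5) underweight, [18.5, 25) normal, [25, 30)
#' overweight, [30, Inf) obese, so e.g. 24.95 is normal and 30.0 is obese.
#' Missing weight or height yields \code{NA} (such subjects are removed
#' later by \code{\link{apply_exclusions}}).
#'
#' @param weight_kg Measured weight in kilograms (positive).
#' @param height_m Measured height in metres (positive).
#' @return Factor with levels underweight < normal < overweight < obese.
#' @examples
#' classify_bmi(c(60, 80), c(1.65, 1.60))
#' @export
classify_bmi <- function(weight_kg, height_m) {
  if (length(weight_kg) != length(height_m))
    stop("weight_kg and height_m must have the same length")
  bad <- (!is.na(weight_kg) & weight_kg <= 0) |
    (!is.na(height_m) & height_m <= 0)
  if (any(bad)) stop("weight and height must be positive")
  bmi <- weight_kg / height_m^2
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), labels = .BMI_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' Composite functional-limitation indicator
#'
#' A subject is functionally limited (state 2) when they report difficulty
#' in at least one activity of daily living (ADL, 6 items), or at least two
#' instrumental activities of daily living (IADL, 5 items), or at least
#' three mobility-function items (MF, 11 items).
#'
#' @param adl,iadl,mf Item difficulty counts (0-6, 0-5, 0-11).
#' @return Logical vector: \code{TRUE} = functionally limited.
#' @examples
#' derive_functional_limitation(0, 1, 2)  # below all thresholds -> FALSE
#' derive_functional_limitation(1, 0, 0)  # one ADL limitation   -> TRUE
#' @export
derive_functional_limitation <- function(adl, iadl, mf) {
  if (any(adl < 0 | iadl < 0 | mf < 0, na.rm = TRUE))
    stop("limitation counts must be non-negative")
  if (any(adl > 6 | iadl > 5 | mf > 11, na.rm = TRUE))
    stop("limitation counts exceed the number of items (6 ADL, 5 IADL, 11 MF)")
  adl >= 1 | iadl >= 2 | mf >= 3
}

#' Apply the sample exclusion rules
#'
#' Two sequential exclusions on a long-format panel dataset: (1) subjects
#' with missing baseline weight or height (no BMI) are dropped; (2)
#' underweight subjects are dropped from the modelling dataset, since the
#' underweight category is too sparse to support estimation. Both apply to
#' model fitting, so the fitted n matches the reported hazard-ratio tables.
#'
#' @param data Long-format panel data with columns \code{id}, \code{age},
#'   and baseline anthropometry (\code{weight_kg}, \code{height_m}); a
#'   \code{bmi_cat} column is (re)derived from the baseline record.
#' @return List with \code{data} (the modelling dataset, with a
#'   \code{bmi_cat} column) and \code{log}, a named list of counts removed
#'   at each step. The operation is idempotent.
#' @export
apply_exclusions <- function(data) {
  stopifnot(all(c("id", "age", "weight_kg", "height_m") %in% names(data)))
  data <- data[order(data$id, data$age), , drop = FALSE]
  base_idx <- !duplicated(data$id)
  base <- data[base_idx, , drop = FALSE]
  n_input <- nrow(base)

  miss <- is.na(base$weight_kg) | is.na(base$height_m)
  keep1 <- base$id[!miss]
  base1 <- base[!miss, , drop = FALSE]
  cat1 <- classify_bmi(base1$weight_kg, base1$height_m)
  under <- cat1 == "underweight"
  keep2 <- keep1[!under]

  out <- data[data$id %in% keep2, , drop = FALSE]
  if (nrow(out) == 0L) stop("no subjects remain after exclusions")
  map <- cat1[match(out$id, keep1)]
  out$bmi_cat <- as.character(map)
  rownames(out) <- NULL

  list(data = out,
       log = list(n_subjects_input = n_input,
                  n_missing_anthropometry = sum(miss),
                  n_underweight = sum(under),
                  n_subjects_retained = length(keep2)))
}

#' Write an exclusion log as JSON
#'
#' @param log The \code{log} element returned by
#'   \code{\link{apply_exclusions}}.
#' @param path Output file path.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
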