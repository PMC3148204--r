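# Synthetic inputs for simulation and testing: logistic risk cohorts
# emulating a Framingham-style study, binary-test datasets with specified
# operating characteristics, and case-control subsamples of a generated
# population.  All generators take an explicit seed and use the
# Mersenne-Twister generator locally, leaving the global RNG state alone.

default_covariates <- function() {
  list(
    sex  = list(type = "binary", freq = 0.5),
    age  = list(type = "normal"),
    bmi  = list(type = "normal"),
    chol = list(type = "normal"),
    dbp  = list(type = "normal"),
    sbp  = list(type = "normal")
  )
}

# Intercept solved numerically (Gaussian quadrature over the linear
# predictor) so that the default coefficients give a marginal event
# probability of 0.30.
default_intercept <- -1.4455961

default_coefficients <- c(sex = 0.7, age = 0.9, bmi = 0.25,
                          chol = 0.45, dbp = 0.3, sbp = 0.5)

#' Specification of a synthetic risk cohort
#'
#' Describes a cohort whose binary outcome follows a logistic model over a
#' set of covariates.  The default emulates a Framingham-style 30-year
#' coronary event cohort in shape only: six covariates (a binary one for
#' sex, five standardized continuous ones for age, BMI, serum cholesterol
#' and diastolic/systolic blood pressure), with the intercept tuned so the
#' marginal event probability is 0.30.  No attempt is made to match real
#' Framingham coefficients.
#'
#' @param n number of subjects.
#' @param intercept logistic intercept.
#' @param coefficients named numeric vector, one coefficient per covariate.
#' @param covariates named list of per-covariate distributions, each either
#'   `list(type = "normal")` (standard normal) or
#'   `list(type = "binary", freq = f)` (Bernoulli with frequency `f`).
#' @param seed integer seed; required, generators never read global RNG
#'   state.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n = 1000, seed = 1)
#' pop <- generate_risk_cohort(spec)
#' pop$realized_prevalence
cohort_spec <- function(n, intercept = default_intercept,
                        coefficients = default_coefficients,
                        covariates = default_covariates(), seed) {
  if (missing(seed)) stop_config("'seed' is required")
  if (!is.numeric(n) || n < 1) stop_config("'n' must be a positive integer")
  if (length(coefficients) != length(covariates)) {
    stop_config("need exactly one coefficient per covariate")
  }
  for (cv in covariates) {
    if (!is.list(cv) || !cv$type %in% c("normal", "binary")) {
      stop_config("covariate distributions must be 'normal' or 'binary'")
    }
    if (cv$type == "binary" &&
        (is.null(cv$freq) || cv$freq <= 0 || cv$freq >= 1)) {
      stop_config("binary covariates need a frequency strictly inside (0, 1)")
    }
  }
  structure(
    list(n = as.integer(n), intercept = intercept,
         coefficients = coefficients, covariates = covariates,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic risk cohort
#'
#' Draws covariates from the distributions in the spec, computes each
#' subject's true event probability from the logistic model, and draws the
#' binary outcome.  Fully reproducible: the same spec (including seed)
#' yields the same sample.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `population_sample`: a list with elements
#'   `covariates` (n x k matrix), `outcomes`, `true_probabilities`,
#'   `realized_prevalence`, and the generating `spec`.
#' @export
generate_risk_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, .rng_kind = "Mersenne-Twister", {
    n <- spec$n
    k <- length(spec$covariates)
    X <- matrix(0, nrow = n, ncol = k,
                dimnames = list(NULL, names(spec$covariates)))
    for (j in seq_len(k)) {
      cv <- spec$covariates[[j]]
      X[, j] <- if (cv$type == "normal") stats::rnorm(n)
                else stats::rbinom(n, 1L, cv$freq)
    }
    eta <- spec$intercept + drop(X %*% spec$coefficients)
    p <- stats::plogis(eta)
    y <- stats::rbinom(n, 1L, p)
    structure(
      list(covariates = X, outcomes = y, true_probabilities = p,
           realized_prevalence = mean(y), spec = spec),
      class = "population_sample"
    )
  })
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("Synthetic population: n = %d, %d covariates, realized prevalence = %.4g\n",
              length(x$outcomes), ncol(x$covariates), x$realized_prevalence))
  invisible(x)
}

#' Generate binary-test data
#'
#' Builds a dataset in which the predicted probabilities are exactly 0 or 1
#' (the degenerate-model representation of a binary test).  In exact mode
#' the four cell counts n(a, b, c, d) are produced with no randomness,
#' which requires `n * prevalence * sensitivity` and the analogous products
#' to be whole numbers; otherwise outcomes and test results are drawn with
#' the given rates.
#'
#' @param n number of subjects.
#' @param sensitivity,specificity test operating characteristics in
#'   \eqn{[0, 1]}.
#' @param prevalence disease prevalence, strictly inside (0, 1).
#' @param seed integer seed; required unless `exact = TRUE`.
#' @param exact logical; if `TRUE`, produce the exact cell counts
#'   deterministically.
#' @param label character label for the resulting prediction set.
#' @return A [prediction_set()] with 0/1 probabilities.
#' @export
#' @examples
#' ps <- generate_binary_test_data(1000, 0.9, 0.9, 0.5, exact = TRUE)
#' classify(ps, 0.5)  # a = d = 0.45, b = c = 0.05
generate_binary_test_data <- function(n, sensitivity, specificity, prevalence,
                                      seed = NULL, exact = FALSE,
                                      label = "binary test") {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop_domain("sensitivity and specificity must lie in [0, 1]")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop_domain("'prevalence' must lie strictly inside (0, 1)")
  }
  if (exact) {
    cells <- n * c(a = prevalence * sensitivity,
                   b = (1 - prevalence) * (1 - specificity),
                   c = prevalence * (1 - sensitivity),
                   d = (1 - prevalence) * specificity)
    if (any(abs(cells - round(cells)) > 1e-9)) {
      stop_input("exact mode requires n * prevalence * sensitivity (and the ",
                 "other three cells) to be whole numbers; got (",
                 paste(format(cells), collapse = ", "), ")")
    }
    cells <- round(cells)
    y <- rep(c(1, 1, 0, 0), times = cells[c("a", "c", "b", "d")])
    p <- rep(c(1, 0, 1, 0), times = cells[c("a", "c", "b", "d")])
    return(prediction_set(y, p, label))
  }
  if (is.null(seed)) stop_config("'seed' is required in stochastic mode")
  withr::with_seed(as.integer(seed), .rng_kind = "Mersenne-Twister", {
    y <- stats::rbinom(n, 1L, prevalence)
    p <- ifelse(y == 1,
                stats::rbinom(n, 1L, sensitivity),
                stats::rbinom(n, 1L, 1 - specificity))
    prediction_set(y, p, label)
  })
}

#' Draw a case-control sample from a synthetic population
#'
#' Samples the requested numbers of cases and controls uniformly without
#' replacement within each outcome class, then refits the logistic model on
#' the subsample.  The refitted probabilities therefore carry the
#' case-control distortion (their mean tracks the design prevalence
#' `n_cases / (n_cases + n_controls)`, not the population's), which is
#' exactly the inconsistency [adjust_probabilities()] corrects.
#'
#' @param population a `population_sample` from [generate_risk_cohort()].
#' @param n_cases,n_controls subsample sizes per outcome class.
#' @param seed integer seed.
#' @param label character label for the refitted prediction set.
#' @return A [prediction_set()] with refitted probabilities; the selected
#'   row indices of the population are kept in the `"indices"` attribute.
#' @export
sample_case_control <- function(population, n_cases, n_controls, seed,
                                label = "case-control refit") {
  stopifnot(inherits(population, "population_sample"))
  if (missing(seed)) stop_config("'seed' is required")
  case_idx <- which(population$outcomes == 1)
  ctrl_idx <- which(population$outcomes == 0)
  if (length(case_idx) < n_cases || length(ctrl_idx) < n_controls) {
    stop_input(sprintf(
      "population has %d cases and %d controls; requested %d + %d",
      length(case_idx), length(ctrl_idx), n_cases, n_controls))
  }
  idx <- withr::with_seed(as.integer(seed), .rng_kind = "Mersenne-Twister", {
    c(sample(case_idx, n_cases), sample(ctrl_idx, n_controls))
  })
  ps <- fit_logistic_model(population$covariates[idx, , drop = FALSE],
                           population$outcomes[idx], label)
  attr(ps, "indices") <- idx
  ps
}

#' Write or read a generated dataset as CSV
#'
#' The on-disk dialect is comma-separated with a header row: columns `id`,
#' `outcome`, one column per covariate, and `probability`.
#'
#' @param population a `population_sample`.
#' @param probabilities optional probabilities to store (defaults to the
#'   true generating probabilities).
#' @param path output file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a data frame in the same dialect.
#' @export
write_cohort_csv <- function(population, path, probabilities = NULL) {
  stopifnot(inherits(population, "population_sample"))
  if (is.null(probabilities)) probabilities <- population$true_probabilities
  df <- data.frame(id = seq_along(population$outcomes),
                   outcome = population$outcomes,
                   population$covariates,
                   probability = probabilities)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  utils::read.csv(path)
}
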