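# Decision curve analysis when the sample prevalence is by design not the
# population prevalence: odds-rescaled probabilities and net-benefit
# estimators built from sensitivity and specificity with an assumed true
# prevalence.

#' Prevalence-adjust predicted probabilities
#'
#' In a case-control sample the empirical prevalence \eqn{\pi} does not
#' estimate the population prevalence \eqn{\pi_0}, and probabilities fitted
#' on such a sample are inflated accordingly.  Given an assumed true
#' prevalence, each probability is adjusted on the odds scale:
#' \deqn{odds(\tilde p_i) = odds(p_i)\,
#'   \frac{\pi_0/(1-\pi_0)}{\pi/(1-\pi)},}
#' which is equivalent to shifting the logistic intercept by the log of the
#' prevalence-odds ratio.  The boundary probabilities 0 and 1 are fixed
#' points, and the map is strictly increasing, so the ranking of subjects
#' (hence the ROC curve) is unchanged.
#'
#' @param preds a [prediction_set()] whose empirical prevalence is strictly
#'   inside (0, 1).
#' @param pi0 assumed true (population) prevalence, strictly inside (0, 1).
#' @return A `prediction_set` with adjusted probabilities; when
#'   `pi0` equals the empirical prevalence the input is returned unchanged
#'   (the adjustment is the identity map).
#' @export
#' @examples
#' ps <- prediction_set(c(1, 0), c(0.5, 0.5))
#' adjust_probabilities(ps, 0.2)$probabilities  # both 0.2
adjust_probabilities <- function(preds, pi0) {
  pi <- both_classes_or_stop(preds)
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 >= 1) {
    stop_domain("'pi0' must be a single value strictly inside (0, 1)")
  }
  if (pi0 == pi) {
    return(preds)
  }
  f <- (pi0 / (1 - pi0)) * ((1 - pi) / pi)
  p <- preds$probabilities
  adj <- (p * f) / (p * f + (1 - p))
  prediction_set(preds$outcomes, adj, preds$label)
}

cc_sens_spec <- function(props) {
  sens <- if (props$a + props$c > 0) props$a / (props$a + props$c) else NA_real_
  spec <- if (props$b + props$d > 0) props$d / (props$b + props$d) else NA_real_
  list(sensitivity = sens, specificity = spec)
}

#' Case-control decision curve
#'
#' Decision curve for data from a case-control design, given an assumed
#' true prevalence `pi0`.  At each grid threshold the adjusted
#' probabilities are classified, sensitivity and specificity are estimated
#' from the resulting proportions (they remain consistent under
#' case-control sampling), and the net benefit is computed from
#' [sens_spec_net_benefit()] with `pi0` in place of the sample prevalence.
#' A grid point where the sample has no cases or no controls leaves
#' sensitivity or specificity undefined; such points are reported as `NA`
#' with a warning rather than silently substituted, since a fabricated 0
#' would be a fabricated net benefit.  With `pi0` equal to the empirical
#' prevalence the curve reduces exactly to [decision_curve()].
#'
#' @param preds a [prediction_set()] from the case-control sample.
#' @param pi0 assumed true prevalence, strictly inside (0, 1).
#' @param grid a [threshold_grid()].
#' @param kind benefit kind, see [net_benefit()].
#' @return A `decision_curve` data frame with an extra `pi0` column.
#' @export
case_control_curve <- function(preds, pi0, grid = threshold_grid(),
                               kind = c("treated", "untreated", "overall")) {
  kind <- match.arg(kind)
  grid <- as_threshold_grid(grid)
  adj <- adjust_probabilities(preds, pi0)
  nb <- vapply(as.numeric(grid), function(p_t) {
    ss <- cc_sens_spec(classify(adj, p_t))
    sens_spec_net_benefit(ss$sensitivity, ss$specificity, pi0, p_t, kind)
  }, numeric(1))
  if (anyNA(nb)) {
    warning(sprintf(
      "%d grid point(s) have undefined sensitivity or specificity; reported as NA",
      sum(is.na(nb))), call. = FALSE)
  }
  new_decision_curve(preds$label, kind, grid, nb,
                     extra = data.frame(pi0 = pi0))
}

#' Net benefit as a function of the assumed true prevalence
#'
#' Holds the threshold probability fixed and sweeps the assumed true
#' prevalence over a grid, recomputing the case-control net-benefit
#' estimate at each value.  Useful when the population prevalence is
#' uncertain and must be postulated from external sources.
#'
#' @param preds a [prediction_set()] from the case-control sample.
#' @param p_t threshold probability in (0, 1).
#' @param pi0_grid increasing numeric vector of assumed prevalences in
#'   (0, 1).
#' @param kind benefit kind, see [net_benefit()].
#' @return A data frame with columns `pi0`, `p_t`, `kind`, `net_benefit`.
#' @export
prevalence_sweep <- function(preds, p_t, pi0_grid,
                             kind = c("treated", "untreated", "overall")) {
  kind <- match.arg(kind)
  check_threshold(p_t)
  stopifnot(length(p_t) == 1L)
  pi0_grid <- as.numeric(pi0_grid)
  if (length(pi0_grid) < 1L || any(pi0_grid <= 0) || any(pi0_grid >= 1)) {
    stop_domain("'pi0_grid' values must lie strictly inside (0, 1)")
  }
  if (length(pi0_grid) > 1L && any(diff(pi0_grid) <= 0)) {
    stop_domain("'pi0_grid' must be strictly increasing")
  }
  nb <- vapply(pi0_grid, function(pi0) {
    adj <- adjust_probabilities(preds, pi0)
    ss <- cc_sens_spec(classify(adj, p_t))
    sens_spec_net_benefit(ss$sensitivity, ss$specificity, pi0, p_t, kind)
  }, numeric(1))
  data.frame(pi0 = pi0_grid, p_t = p_t, kind = kind, net_benefit = nb,
             stringsAsFactors = FALSE)
}
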