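# The bridge between decision curve analysis and ROC analysis: empirical
# ROC points, the Youden-optimal cutoff, the net-benefit-optimal operating
# point, sensitivity/specificity forms of the net benefit, and the decision
# curve of a dichotomized model.

both_classes_or_stop <- function(preds) {
  if (!inherits(preds, "prediction_set")) {
    stop_input("'preds' must be a prediction_set")
  }
  pi <- mean(preds$outcomes)
  if (pi <= 0 || pi >= 1) {
    stop_input("both outcome classes must be present: sensitivity or ",
               "specificity is undefined otherwise")
  }
  invisible(pi)
}

#' Empirical ROC curve
#'
#' All operating points (1 - specificity, sensitivity) attainable by
#' varying the classification cutoff, using the empirical step-function
#' convention: one point per distinct probability value plus the two
#' trivial endpoints (0, 0) and (1, 1).  A subject is classified positive
#' when its probability strictly exceeds the cutoff, so the cutoff equal to
#' the largest probability yields (0, 0) and the sentinel `-Inf` yields
#' (1, 1).  Points are ordered by cutoff, descending.
#'
#' @param preds a [prediction_set()] containing both outcome classes.
#' @return A data frame of class `roc_curve` with columns `cutoff`,
#'   `one_minus_specificity`, `sensitivity`.
#' @export
#' @examples
#' ps <- prediction_set(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
#' roc_points(ps)
roc_points <- function(preds) {
  both_classes_or_stop(preds)
  p <- preds$probabilities
  y <- preds$outcomes
  n_case <- sum(y == 1)
  n_ctrl <- sum(y == 0)
  cuts <- c(sort(unique(p), decreasing = TRUE), -Inf)
  sens <- vapply(cuts, function(ct) sum(p > ct & y == 1), numeric(1)) / n_case
  fpr <- vapply(cuts, function(ct) sum(p > ct & y == 0), numeric(1)) / n_ctrl
  structure(
    data.frame(cutoff = cuts, one_minus_specificity = fpr,
               sensitivity = sens),
    class = c("roc_curve", "data.frame")
  )
}

new_operating_point <- function(cutoff, sensitivity, specificity,
                                criterion, criterion_value, ...) {
  structure(
    c(list(cutoff = cutoff, sensitivity = sensitivity,
           specificity = specificity, criterion = criterion,
           criterion_value = criterion_value), list(...)),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point (criterion: %s)\n", x$criterion))
  cat(sprintf("  cutoff = %.6g, sensitivity = %.4g, specificity = %.4g\n",
              x$cutoff, x$sensitivity, x$specificity))
  cat(sprintf("  criterion value = %.6g\n", x$criterion_value))
  if (!is.null(x$slope_target)) {
    cat(sprintf("  target ROC slope (1-pi)/pi * p_t/(1-p_t) = %.6g\n",
                x$slope_target))
  }
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' The operating point maximizing the Youden index,
#' sensitivity + specificity - 1; geometrically, the highest point of the
#' ROC curve above the chance diagonal.  Ties are broken in favour of the
#' highest specificity (fewest positives).
#'
#' @param roc a `roc_curve` from [roc_points()].
#' @return An `operating_point` whose `criterion_value` is the maximal
#'   Youden index.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  youden <- roc$sensitivity - roc$one_minus_specificity
  best <- which(youden >= max(youden) - 1e-15)
  best <- best[which.min(roc$one_minus_specificity[best])]
  new_operating_point(
    cutoff = roc$cutoff[best],
    sensitivity = roc$sensitivity[best],
    specificity = 1 - roc$one_minus_specificity[best],
    criterion = "youden",
    criterion_value = youden[best]
  )
}

candidate_cutoffs <- function(p) {
  v <- sort(unique(p))
  mids <- if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

#' Net-benefit-optimal operating point
#'
#' For a fixed threshold probability `p_t`, the cutoff whose induced
#' classification maximizes the net benefit for the treated.  Candidate
#' cutoffs are midpoints between consecutive distinct probabilities plus
#' sentinels below the minimum (everyone positive) and above the maximum
#' (no one positive), which together cover every achievable classification.
#' Ties are broken in favour of the highest specificity.  In theory the
#' optimum is the point where the ROC slope equals
#' \eqn{[(1-\pi)/\pi]\,[p_t/(1-p_t)]}; that target slope is reported as a
#' diagnostic rather than obtained by differentiating the empirical step
#' function.  At `p_t` equal to the sample prevalence the optimum
#' coincides with the Youden-optimal operating point.
#'
#' @param preds a [prediction_set()] containing both outcome classes.
#' @param p_t threshold probability in (0, 1).
#' @return An `operating_point` with `criterion_value` the maximized net
#'   benefit for the treated and extra fields `p_t` and `slope_target`.
#' @export
netbenefit_cutoff <- function(preds, p_t) {
  pi <- both_classes_or_stop(preds)
  check_threshold(p_t)
  stopifnot(length(p_t) == 1L)
  p <- preds$probabilities
  y <- preds$outcomes
  n <- length(y)
  w <- p_t / (1 - p_t)
  cuts <- candidate_cutoffs(p)
  a <- vapply(cuts, function(ct) sum(p > ct & y == 1), numeric(1)) / n
  b <- vapply(cuts, function(ct) sum(p > ct & y == 0), numeric(1)) / n
  u <- a - b * w
  best <- which(u >= max(u) - 1e-15)
  best <- best[which.min(b[best])]
  new_operating_point(
    cutoff = cuts[best],
    sensitivity = a[best] / pi,
    specificity = ((1 - pi) - b[best]) / (1 - pi),
    criterion = "net_benefit",
    criterion_value = u[best],
    p_t = p_t,
    slope_target = (1 - pi) / pi * w
  )
}

#' Net benefit from sensitivity, specificity and prevalence
#'
#' The net benefit rewritten in terms of the test characteristics, using
#' \eqn{a = se\,\pi}, \eqn{b = (1-sp)(1-\pi)}, \eqn{c = (1-se)\pi},
#' \eqn{d = sp(1-\pi)}: for the treated,
#' \eqn{se\,\pi - (1-sp)(1-\pi)\,p_t/(1-p_t)}; for the untreated,
#' \eqn{sp(1-\pi) - (1-se)\pi\,(1-p_t)/p_t}; the overall form is their
#' sum.  Algebraically identical to [net_benefit()] on the induced
#' proportions; this parameterization is what makes the case-control
#' estimators possible, since sensitivity and specificity remain
#' consistently estimable when the sample prevalence does not reflect the
#' population's.
#'
#' @param sensitivity,specificity rates in \eqn{[0, 1]}; may be `NA`, in
#'   which case `NA` is returned.
#' @param prevalence disease prevalence, strictly inside (0, 1).
#' @param p_t threshold probability in (0, 1); may be a vector.
#' @param kind benefit kind, see [net_benefit()].
#' @return Numeric net benefit, one value per element of `p_t`.
#' @export
sens_spec_net_benefit <- function(sensitivity, specificity, prevalence, p_t,
                                  kind = c("treated", "untreated", "overall")) {
  kind <- match.arg(kind)
  if (prevalence <= 0 || prevalence >= 1) {
    stop_domain("'prevalence' must lie strictly inside (0, 1)")
  }
  check_threshold(p_t)
  if (is.na(sensitivity) || is.na(specificity)) {
    return(rep(NA_real_, length(p_t)))
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop_domain("sensitivity and specificity must lie in [0, 1]")
  }
  pi <- prevalence
  w <- p_t / (1 - p_t)
  treated <- sensitivity * pi - (1 - specificity) * (1 - pi) * w
  untreated <- specificity * (1 - pi) - (1 - sensitivity) * pi / w
  switch(kind,
    treated = treated,
    untreated = untreated,
    overall = treated + untreated
  )
}

#' Decision curve of a dichotomized model
#'
#' Fixes a single classification cutoff (for instance the Youden-optimal
#' one) and shows the net benefit of that fixed dichotomization as the
#' threshold probability varies.  Sensitivity and specificity are constant
#' across the grid; only the net-benefit weights change, producing the
#' characteristic arc that falls below both the treat-none and treat-all
#' strategies once the threshold moves away from the cutoff.  At the grid
#' point equal to the cutoff the value coincides with the continuous
#' model's decision curve.
#'
#' @param preds a [prediction_set()] containing both outcome classes.
#' @param cutoff classification cutoff in (0, 1).
#' @param grid a [threshold_grid()].
#' @param kind benefit kind, see [net_benefit()].
#' @return A `decision_curve` data frame.
#' @export
dichotomized_curve <- function(preds, cutoff, grid = threshold_grid(),
                               kind = c("treated", "untreated", "overall")) {
  pi <- both_classes_or_stop(preds)
  kind <- match.arg(kind)
  if (cutoff <= 0 || cutoff >= 1) {
    stop_domain("'cutoff' must lie strictly inside (0, 1)")
  }
  grid <- as_threshold_grid(grid)
  pos <- preds$probabilities > cutoff
  case <- preds$outcomes == 1
  sens <- sum(pos & case) / sum(case)
  spec <- sum(!pos & !case) / sum(!case)
  nb <- sens_spec_net_benefit(sens, spec, pi, as.numeric(grid), kind)
  new_decision_curve(
    sprintf("%s (cutoff %.4g)", preds$label, cutoff), kind, grid, nb
  )
}
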