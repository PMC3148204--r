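# Core algebra of decision curve analysis: classification proportions at a
# threshold probability and the three net-benefit functionals.

#' Construct a prediction set
#'
#' A prediction set pairs a binary outcome (1 = disease / event, 0 = none)
#' with a predicted probability for each subject, plus a label naming the
#' model or strategy that produced the probabilities.
#'
#' @param outcomes integer or numeric vector of 0/1 outcomes.
#' @param probabilities numeric vector of predicted probabilities in
#'   \eqn{[0, 1]}, same length as `outcomes`.
#' @param label character scalar naming the model.
#'
#' @return An object of class `prediction_set`: a list with elements
#'   `outcomes`, `probabilities` and `label`.
#' @export
#' @examples
#' ps <- prediction_set(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1), "toy")
#' classify(ps, 0.5)
prediction_set <- function(outcomes, probabilities, label = "model") {
  if (length(outcomes) < 1L || length(outcomes) != length(probabilities)) {
    stop_input("'outcomes' and 'probabilities' must have equal length >= 1")
  }
  outcomes <- as.numeric(outcomes)
  probabilities <- as.numeric(probabilities)
  if (anyNA(outcomes) || anyNA(probabilities)) {
    stop_input("missing values are not allowed in a prediction set")
  }
  if (!all(outcomes %in% c(0, 1))) {
    bad <- unique(outcomes[!outcomes %in% c(0, 1)])
    stop_input("outcomes must be 0 or 1; offending values: ",
               paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop_input("probabilities must lie in [0, 1]")
  }
  structure(
    list(outcomes = outcomes, probabilities = probabilities,
         label = as.character(label)[1L]),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("Prediction set '%s': n = %d, prevalence = %.4g\n",
              x$label, length(x$outcomes), mean(x$outcomes)))
  invisible(x)
}

#' Sample prevalence of a prediction set
#'
#' @param preds a [prediction_set()].
#' @return The proportion of subjects with outcome 1.
#' @export
prevalence <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  mean(preds$outcomes)
}

#' Construct classification proportions
#'
#' The four joint proportions of a binary classification at a threshold:
#' `a` true positives, `b` false positives, `c` false negatives, `d` true
#' negatives.  They must be non-negative and sum to 1; the disease
#' prevalence is `a + c`.
#'
#' @param a,b,c,d proportions in \eqn{[0, 1]} summing to 1.
#' @return An object of class `class_proportions`.
#' @export
#' @examples
#' class_proportions(0.3, 0.2, 0.2, 0.3)
class_proportions <- function(a, b, c, d) {
  p <- c(a = a, b = b, c = c, d = d)
  if (anyNA(p) || any(p < -1e-12)) {
    stop_input("proportions must be non-negative")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop_input("proportions must sum to 1 (got ", format(sum(p), digits = 15), ")")
  }
  structure(as.list(pmax(p, 0)), class = "class_proportions")
}

#' @export
print.class_proportions <- function(x, ...) {
  cat(sprintf("Classification proportions: a = %.4g, b = %.4g, c = %.4g, d = %.4g (prevalence %.4g)\n",
              x$a, x$b, x$c, x$d, x$a + x$c))
  invisible(x)
}

benefit_kinds <- c("treated", "untreated", "overall")

check_threshold <- function(p_t, arg = "p_t") {
  if (!is.numeric(p_t) || anyNA(p_t) || any(p_t <= 0) || any(p_t >= 1)) {
    stop_domain("'", arg, "' must lie strictly inside (0, 1)")
  }
  invisible(p_t)
}

#' Classify a prediction set at a threshold probability
#'
#' A subject is treated when its predicted probability strictly exceeds the
#' threshold; subjects with probability exactly equal to the threshold are
#' counted as not treated.  Returns the four joint proportions as exact
#' counts over n.
#'
#' @param preds a [prediction_set()].
#' @param p_t threshold probability, strictly inside (0, 1).
#' @return A [class_proportions()] object.
#' @export
#' @examples
#' ps <- prediction_set(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
#' classify(ps, 0.5)  # a = b = c = d = 0.25
classify <- function(preds, p_t) {
  if (!inherits(preds, "prediction_set")) {
    stop_input("'preds' must be a prediction_set")
  }
  check_threshold(p_t)
  stopifnot(length(p_t) == 1L)
  n <- length(preds$outcomes)
  treated <- preds$probabilities > p_t
  case <- preds$outcomes == 1
  class_proportions(
    a = sum(treated & case) / n,
    b = sum(treated & !case) / n,
    c = sum(!treated & case) / n,
    d = sum(!treated & !case) / n
  )
}

#' Net benefit of a classification
#'
#' The three net-benefit functionals at threshold probability `p_t`,
#' with odds weight \eqn{w = p_t / (1 - p_t)}:
#' \describe{
#'   \item{treated}{\eqn{u = a - b\,w}: profit among the treated, per
#'     subject, in units of the profit of treating a true case.}
#'   \item{untreated}{\eqn{u = d - c / w}: profit among the untreated, in
#'     units of the loss avoided by not treating a non-case.}
#'   \item{overall}{\eqn{u = (a + d) - b\,w - c / w}: the sum of the two,
#'     invariant under recoding of the outcome; its maximum is 1, attained
#'     only when \eqn{b = c = 0}.}
#' }
#'
#' @param props a [class_proportions()] object.
#' @param p_t threshold probability in (0, 1); may be a vector.
#' @param kind one of `"treated"`, `"untreated"`, `"overall"`.
#' @return Numeric net benefit, one value per element of `p_t`.
#' @export
#' @examples
#' pr <- class_proportions(0.3, 0.2, 0.2, 0.3)
#' net_benefit(pr, 0.5, "overall")  # 0.6 - 0.4 = 0.2
net_benefit <- function(props, p_t, kind = c("treated", "untreated", "overall")) {
  if (!inherits(props, "class_proportions")) {
    stop_input("'props' must be a class_proportions object")
  }
  kind <- match.arg(kind)
  check_threshold(p_t)
  w <- p_t / (1 - p_t)
  switch(kind,
    treated   = props$a - props$b * w,
    untreated = props$d - props$c / w,
    overall   = (props$a + props$d) - props$b * w - props$c / w
  )
}

#' Absolute (unnormalized) benefit
#'
#' The benefit in utility units before normalization: `U_treated = aP - bL`
#' for the treated and `U_untreated = dL - cP` for the untreated, where `P`
#' is the profit of treating a case and `L` the loss of treating a
#' non-case.  For any two models compared at the same threshold, the
#' difference in `U_treated` equals the difference in `U_untreated`.
#'
#' @param props a [class_proportions()] object.
#' @param P profit per treated case, positive.
#' @param L loss per treated non-case, positive, same units as `P`.
#' @return A list of class `absolute_benefit` with elements `P`, `L`,
#'   `U_treated`, `U_untreated` and the implied threshold `p_t = L/(L+P)`.
#' @export
absolute_benefit <- function(props, P, L) {
  if (!inherits(props, "class_proportions")) {
    stop_input("'props' must be a class_proportions object")
  }
  if (!is.numeric(P) || !is.numeric(L) || P <= 0 || L <= 0) {
    stop_domain("'P' and 'L' must be positive")
  }
  structure(
    list(P = P, L = L,
         U_treated = props$a * P - props$b * L,
         U_untreated = props$d * L - props$c * P,
         p_t = L / (L + P)),
    class = "absolute_benefit"
  )
}

#' @export
print.absolute_benefit <- function(x, ...) {
  cat(sprintf("Absolute benefit (P = %g, L = %g, implied p_t = %.4g):\n",
              x$P, x$L, x$p_t))
  cat(sprintf("  U_treated = %.6g, U_untreated = %.6g\n",
              x$U_treated, x$U_untreated))
  invisible(x)
}

#' Reference decision curves
#'
#' Decision curves of the three reference strategies at a given disease
#' prevalence: treating none, treating all, and a hypothetical perfect
#' prediction model.  Closed forms, for prevalence \eqn{\pi} and odds
#' weight \eqn{w = p_t/(1 - p_t)}:
#' treat-all/treated \eqn{\pi - (1-\pi) w}; treat-none/untreated
#' \eqn{(1-\pi) - \pi / w}; treat-none/treated and treat-all/untreated are
#' identically 0; the perfect model gives \eqn{\pi}, \eqn{1-\pi} and 1 for
#' the treated, untreated and overall kinds.
#'
#' @param prevalence disease prevalence, strictly inside (0, 1).
#' @param grid a [threshold_grid()] or increasing numeric vector in (0, 1).
#' @param strategy one of `"treat_none"`, `"treat_all"`, `"perfect"`.
#' @param kind benefit kind, see [net_benefit()].
#' @return A `decision_curve` data frame, see [decision_curve()].
#' @export
#' @examples
#' reference_curve(0.3, threshold_grid(), "treat_all", "treated")
reference_curve <- function(prevalence, grid = threshold_grid(),
                            strategy = c("treat_none", "treat_all", "perfect"),
                            kind = c("treated", "untreated", "overall")) {
  strategy <- match.arg(strategy)
  kind <- match.arg(kind)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_domain("'prevalence' must lie strictly inside (0, 1)")
  }
  grid <- as_threshold_grid(grid)
  pi <- prevalence
  w <- grid / (1 - grid)
  nb <- switch(strategy,
    treat_none = switch(kind,
      treated = rep(0, length(grid)),
      untreated = (1 - pi) - pi / w,
      overall = (1 - pi) - pi / w),
    treat_all = switch(kind,
      treated = pi - (1 - pi) * w,
      untreated = rep(0, length(grid)),
      overall = pi - (1 - pi) * w),
    perfect = switch(kind,
      treated = rep(pi, length(grid)),
      untreated = rep(1 - pi, length(grid)),
      overall = rep(1, length(grid)))
  )
  new_decision_curve(strategy, kind, grid, nb)
}
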