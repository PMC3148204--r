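# Decision curves over a threshold grid: continuous prediction models,
# binary tests, and the convenience logistic fit.

#' Threshold probability grid
#'
#' A strictly increasing sequence of threshold probabilities, kept away
#' from 0 and 1 because the untreated (and overall) net benefit diverges as
#' \eqn{p_t \to 0} and the treated net benefit as \eqn{p_t \to 1}.  The
#' default runs from 0.01 to 0.99 in steps of 0.01.
#'
#' @param min,max grid endpoints, inside (0, 1).
#' @param step grid spacing.
#' @return A numeric vector of class `threshold_grid`.
#' @export
threshold_grid <- function(min = 0.01, max = 0.99, step = 0.01) {
  if (min <= 0 || max >= 1 || min > max || step <= 0) {
    stop_domain("grid must satisfy 0 < min <= max < 1 with positive step")
  }
  as_threshold_grid(seq(min, max, by = step))
}

#' @rdname threshold_grid
#' @param values numeric vector to validate as a threshold grid.
#' @export
as_threshold_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) ||
      any(values <= 0) || any(values >= 1)) {
    stop_domain("threshold grid values must lie strictly inside (0, 1)")
  }
  if (length(values) > 1L && any(diff(values) <= 0)) {
    stop_domain("threshold grid must be strictly increasing")
  }
  structure(values, class = c("threshold_grid", "numeric"))
}

new_decision_curve <- function(label, kind, grid, nb, extra = NULL) {
  df <- data.frame(
    strategy_label = label,
    kind = kind,
    p_t = as.numeric(grid),
    net_benefit = as.numeric(nb),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  class(df) <- c("decision_curve", "data.frame")
  df
}

#' Decision curve of a prediction model
#'
#' Evaluates the net benefit of the treat-if-probability-exceeds-threshold
#' policy at every grid value.  Each point is computed exactly from the
#' empirical classification proportions at that threshold; no smoothing or
#' interpolation is applied.
#'
#' @param preds a [prediction_set()].
#' @param grid a [threshold_grid()].
#' @param kind benefit kind, see [net_benefit()].
#' @return A data frame of class `decision_curve` with columns
#'   `strategy_label`, `kind`, `p_t`, `net_benefit`.
#' @export
#' @examples
#' ps <- prediction_set(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
#' dc <- decision_curve(ps, threshold_grid(), "treated")
#' dc[dc$p_t == 0.5, ]
decision_curve <- function(preds, grid = threshold_grid(),
                           kind = c("treated", "untreated", "overall")) {
  kind <- match.arg(kind)
  grid <- as_threshold_grid(grid)
  nb <- vapply(as.numeric(grid), function(p_t) {
    net_benefit(classify(preds, p_t), p_t, kind)
  }, numeric(1))
  new_decision_curve(preds$label, kind, grid, nb)
}

#' Binary diagnostic or prognostic test
#'
#' A binary test is the degenerate prediction model that assigns
#' probability 1 to test-positive and 0 to test-negative subjects, so the
#' positives are treated at every threshold.  Its decision curve is fully
#' determined by sensitivity, specificity and prevalence.
#'
#' @param sensitivity,specificity rates in \eqn{[0, 1]}.
#' @param prevalence disease prevalence, strictly inside (0, 1).
#' @param label character scalar naming the test.
#' @return An object of class `binary_test`.
#' @export
binary_test <- function(sensitivity, specificity, prevalence, label = "test") {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop_domain("sensitivity and specificity must lie in [0, 1]")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop_domain("'prevalence' must lie strictly inside (0, 1)")
  }
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         prevalence = prevalence, label = as.character(label)[1L]),
    class = "binary_test"
  )
}

#' Decision curve of a binary test
#'
#' At every threshold the classification of a binary test is fixed:
#' \eqn{a = se\,\pi}, \eqn{b = (1-sp)(1-\pi)}, \eqn{c = (1-se)\pi},
#' \eqn{d = sp(1-\pi)}.  Only the net-benefit weights vary with the
#' threshold.
#'
#' @param test a [binary_test()].
#' @param grid a [threshold_grid()].
#' @param kind benefit kind, see [net_benefit()].
#' @return A `decision_curve` data frame.
#' @export
#' @examples
#' simple <- binary_test(0.9, 0.9, 0.5, "simple")
#' binary_test_curve(simple, as_threshold_grid(0.5), "treated")  # 0.40
binary_test_curve <- function(test, grid = threshold_grid(),
                              kind = c("treated", "untreated", "overall")) {
  stopifnot(inherits(test, "binary_test"))
  kind <- match.arg(kind)
  grid <- as_threshold_grid(grid)
  pi <- test$prevalence
  props <- class_proportions(
    a = test$sensitivity * pi,
    b = (1 - test$specificity) * (1 - pi),
    c = (1 - test$sensitivity) * pi,
    d = test$specificity * (1 - pi)
  )
  nb <- net_benefit(props, as.numeric(grid), kind)
  new_decision_curve(test$label, kind, grid, nb)
}

#' Fit a logistic risk model
#'
#' Convenience wrapper around maximum-likelihood logistic regression with
#' an intercept (iteratively reweighted least squares, convergence
#' tolerance 1e-8, at most 100 iterations).  Returns the fitted in-sample
#' event probabilities as a [prediction_set()]; the underlying fit is kept
#' in the `"fit"` attribute.
#'
#' @param covariates numeric matrix or data frame (n rows, k columns), or
#'   `NULL` for an intercept-only model.
#' @param outcomes binary 0/1 vector of length n, containing both classes.
#' @param label character scalar naming the model.
#' @return A `prediction_set` with attribute `"fit"` (the `glm` object).
#' @export
fit_logistic_model <- function(covariates, outcomes, label = "logistic") {
  outcomes <- as.numeric(outcomes)
  if (!all(outcomes %in% c(0, 1))) stop_input("outcomes must be 0 or 1")
  if (length(unique(outcomes)) < 2L) {
    stop_input("outcomes must contain both classes to fit a logistic model")
  }
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.matrix(covariates) && ncol(covariates) == 0L)) {
    df <- data.frame(y = outcomes)
    fml <- y ~ 1
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(outcomes)) {
      stop_input("covariate rows must match the number of outcomes")
    }
    if (length(outcomes) <= ncol(covariates)) {
      stop_input("need more observations than covariates")
    }
    df <- data.frame(y = outcomes, covariates)
    fml <- y ~ .
  }
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu < 1e-6) || any(mu > 1 - 1e-6)) {
    warning("possible perfect separation: fitted probabilities at 0 or 1 ",
            "(iterations capped at 100)", call. = FALSE)
  }
  ps <- prediction_set(outcomes, pmin(pmax(stats::fitted(fit), 0), 1), label)
  attr(ps, "fit") <- fit
  ps
}

#' Plot decision curves
#'
#' Draws one panel of decision curves (all rows must share one benefit
#' kind), one line per strategy, clipping the y-axis to `ylim` so that the
#' reference curves that diverge to minus infinity are drawn only where
#' they exceed the clip.
#'
#' @param x a `decision_curve` data frame (rows from several curves may be
#'   combined with `rbind`).
#' @param ylim y-axis limits; defaults to `c(-0.05, 1.05)`.
#' @param col line colours, recycled across strategies.
#' @param lty line types, recycled across strategies.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.decision_curve <- function(x, ylim = c(-0.05, 1.05), col = NULL,
                                lty = NULL, ...) {
  kinds <- unique(x$kind)
  if (length(kinds) != 1L) {
    stop_input("plot one benefit kind at a time; got: ",
               paste(kinds, collapse = ", "))
  }
  labs <- unique(x$strategy_label)
  if (is.null(col)) col <- grDevices::hcl.colors(max(length(labs), 2L), "Dark 2")
  col <- rep_len(col, length(labs))
  lty <- rep_len(if (is.null(lty)) 1L else lty, length(labs))
  graphics::plot(NA, xlim = range(x$p_t), ylim = ylim,
                 xlab = "threshold probability", ylab = paste("net benefit,", kinds),
                 ...)
  graphics::abline(h = 0, col = "grey80")
  for (i in seq_along(labs)) {
    sub <- x[x$strategy_label == labs[i], ]
    keep <- sub$net_benefit >= ylim[1]
    graphics::lines(sub$p_t[keep], sub$net_benefit[keep],
                    col = col[i], lty = lty[i])
  }
  graphics::legend("topright", legend = labs, col = col, lty = lty,
                   bty = "n", cex = 0.8)
  invisible(x)
}
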