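# Random fixtures; probabilities drawn from a continuous distribution are
# tie-free almost surely.

random_preds <- function(n, label = "rand", both_classes = TRUE) {
  repeat {
    p <- stats::runif(n)
    y <- stats::rbinom(n, 1L, p)
    if (!both_classes || (any(y == 1) && any(y == 0))) break
  }
  prediction_set(y, p, label)
}

random_props <- function() {
  x <- stats::rexp(4)
  x <- x / sum(x)
  class_proportions(x[1], x[2], x[3], x[4])
}

expand_binary_test <- function(n, sens, spec, prev, label = "expanded") {
  generate_binary_test_data(n, sens, spec, prev, exact = TRUE, label = label)
}
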