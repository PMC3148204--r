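test_that("empirical ROC points follow the step-function convention", {
  ps <- prediction_set(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
  roc <- roc_points(ps)
  expect_equal(roc$one_minus_specificity, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$sensitivity, c(0, 0.5, 0.5, 1, 1))
  # endpoints and monotonicity
  expect_equal(roc$one_minus_specificity[c(1, nrow(roc))], c(0, 1))
  expect_equal(roc$sensitivity[c(1, nrow(roc))], c(0, 1))
  expect_true(all(diff(roc$one_minus_specificity) >= 0))
  expect_true(all(diff(roc$sensitivity) >= 0))

  # perfect predictions pass through (0, 1)
  perfect <- roc_points(prediction_set(c(1, 1, 0), c(1, 1, 0)))
  expect_true(any(perfect$one_minus_specificity == 0 &
                    perfect$sensitivity == 1))

  # uninformative constant predictions: only the endpoints
  const <- roc_points(prediction_set(c(1, 0, 1), c(0.4, 0.4, 0.4)))
  expect_equal(nrow(const), 2L)

  expect_error(roc_points(prediction_set(c(1, 1), c(0.2, 0.9))),
               class = "nb_input_error")
})

test_that("ROC points agree with brute force and with pROC", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (rep in 1:20) {
    ps <- random_preds(sample(5:500, 1))
    roc <- as.data.frame(roc_points(ps))
    expect_equal(roc[, c("one_minus_specificity", "sensitivity")],
                 oracle_roc(ps$outcomes,
                            ps$probabilities)[, c("one_minus_specificity",
                                                  "sensitivity")])
    ref <- pROC::roc(ps$outcomes, ps$probabilities, quiet = TRUE,
                     direction = "<")
    ours <- unique(roc[, c("one_minus_specificity", "sensitivity")])
    theirs <- unique(data.frame(one_minus_specificity = 1 - ref$specificities,
                                sensitivity = ref$sensitivities))
    o <- ours[order(ours[[1]], ours[[2]]), ]
    t <- theirs[order(theirs[[1]], theirs[[2]]), ]
    expect_equal(unname(as.matrix(o)), unname(as.matrix(t)))
  }
})

test_that("the Youden-optimal cutoff maximizes sensitivity + specificity - 1", {
  expanded <- expand_binary_test(1000, 0.9, 0.9, 0.5)
  op <- youden_cutoff(roc_points(expanded))
  expect_equal(op$criterion_value, 0.8)

  perfect <- youden_cutoff(roc_points(prediction_set(c(1, 1, 0), c(1, 1, 0))))
  expect_equal(perfect$criterion_value, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  const <- youden_cutoff(roc_points(prediction_set(c(1, 0), c(0.4, 0.4))))
  expect_equal(const$criterion_value, 0)

  # brute-force agreement
  set.seed(32)
  for (rep in 1:25) {
    ps <- random_preds(sample(5:500, 1))
    op <- youden_cutoff(roc_points(ps))
    oracle <- oracle_youden_best(ps$outcomes, ps$probabilities)
    expect_equal(op$criterion_value, oracle$value)
    expect_equal(c(op$sensitivity, op$specificity),
                 c(oracle$sens, oracle$spec))
  }
})

test_that("the net-benefit-optimal operating point matches brute force", {
  set.seed(33)
  for (rep in 1:25) {
    ps <- random_preds(sample(5:500, 1))
    p_t <- runif(1, 0.05, 0.95)
    op <- netbenefit_cutoff(ps, p_t)
    oracle <- oracle_netbenefit_best(ps$outcomes, ps$probabilities, p_t)
    expect_equal(op$criterion_value, oracle$value)
    expect_equal(c(op$sensitivity, op$specificity),
                 c(oracle$sens, oracle$spec))
  }

  # perfect predictions: maximal attainable value is the prevalence
  perfect <- prediction_set(c(1, 1, 0), c(1, 1, 0))
  op <- netbenefit_cutoff(perfect, 0.3)
  expect_equal(op$criterion_value, 2 / 3)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  # analytic target slope diagnostic
  ps <- expand_binary_test(20, 0.5, 0.5, 0.3)  # prevalence exactly 0.3
  expect_equal(netbenefit_cutoff(ps, 0.2)$slope_target, 7 / 12)
})

test_that("at p_t equal to the prevalence the optimum is the Youden point", {
  set.seed(34)
  for (rep in 1:50) {
    ps <- random_preds(sample(10:100, 1))
    pi <- mean(ps$outcomes)
    op_nb <- netbenefit_cutoff(ps, pi)
    op_y <- youden_cutoff(roc_points(ps))
    expect_equal(c(op_nb$sensitivity, op_nb$specificity),
                 c(op_y$sensitivity, op_y$specificity))
    # exact identity: u_treated at p_t = pi is pi * Youden at every cutoff
    for (cl in oracle_classifications(ps$outcomes, ps$probabilities)) {
      expect_equal(cl$a - cl$b * pi / (1 - pi),
                   pi * (cl$sens + cl$spec - 1), tolerance = 1e-12)
    }
  }
})

test_that("sensitivity/specificity form equals the proportion form", {
  expect_equal(sens_spec_net_benefit(0.9, 0.9, 0.5, 0.5, "treated"), 0.40)
  for (pi in c(0.2, 0.7)) {
    expect_equal(sens_spec_net_benefit(1, 1, pi, 0.4, "overall"), 1)
  }
  set.seed(35)
  for (rep in 1:100) {
    sens <- runif(1); spec <- runif(1)
    pi <- runif(1, 0.05, 0.95)
    p_t <- runif(1, 0.05, 0.95)
    props <- class_proportions(sens * pi, (1 - spec) * (1 - pi),
                               (1 - sens) * pi, spec * (1 - pi))
    for (kind in c("treated", "untreated", "overall")) {
      expect_equal(sens_spec_net_benefit(sens, spec, pi, p_t, kind),
                   net_benefit(props, p_t, kind), tolerance = 1e-12)
    }
  }
  expect_error(sens_spec_net_benefit(0.9, 0.9, 0.5, 0, "treated"),
               class = "nb_domain_error")
})

test_that("dichotomized curves are arcs anchored at the cutoff", {
  # fixed dichotomization of a 90/90 test at prevalence 0.5
  expanded <- expand_binary_test(1000, 0.9, 0.9, 0.5)
  dc <- dichotomized_curve(expanded, 0.5, as_threshold_grid(0.25), "treated")
  expect_equal(dc$net_benefit, 0.45 - 0.05 * (1 / 3))

  set.seed(36)
  ps <- random_preds(300)
  g <- threshold_grid()
  cutoff <- 0.4
  dcv <- dichotomized_curve(ps, cutoff, g, "treated")
  cont <- decision_curve(ps, g, "treated")
  # at the grid point equal to the cutoff the two curves coincide
  expect_equal(dcv$net_benefit[dcv$p_t == cutoff],
               cont$net_benefit[cont$p_t == cutoff], tolerance = 1e-12)

  # well-separated data: the arc falls below BOTH reference strategies far
  # from the cutoff (for a 90/90 test at prevalence 0.5, treat-all wins
  # below p_t = 0.1 and treat-none above 0.9, analytically)
  sep <- expand_binary_test(1000, 0.9, 0.9, 0.5)
  pi <- 0.5
  for (kind in c("treated", "untreated", "overall")) {
    arc <- dichotomized_curve(sep, 0.5, g, kind)$net_benefit
    tn <- reference_curve(pi, g, "treat_none", kind)$net_benefit
    ta <- reference_curve(pi, g, "treat_all", kind)$net_benefit
    # strictly inside the dominance regions (equality holds at 0.1 and 0.9)
    low <- g < 0.095
    high <- g > 0.905
    expect_true(all(arc[low] < pmax(tn[low], ta[low])))
    expect_true(all(arc[high] < pmax(tn[high], ta[high])))
  }
})
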