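test_that("classify counts strict exceedances of the threshold", {
  ps <- prediction_set(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
  pr <- classify(ps, 0.5)
  expect_equal(unlist(pr[c("a", "b", "c", "d")]),
               c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))

  # everyone predicted certain: a = prevalence, b = 1 - prevalence
  all_one <- prediction_set(c(1, 1, 0, 0, 0), rep(1, 5))
  pr1 <- classify(all_one, 0.3)
  expect_equal(pr1$a, 0.4)
  expect_equal(pr1$b, 0.6)
  expect_equal(pr1$c + pr1$d, 0)

  # nobody predicted at risk: nobody treated
  none <- prediction_set(c(1, 0), c(0, 0))
  pr0 <- classify(none, 0.7)
  expect_equal(pr0$a + pr0$b, 0)

  # ties with the threshold are NOT treated
  tie <- prediction_set(c(1, 1), c(0.5, 0.6))
  expect_equal(classify(tie, 0.5)$a, 0.5)

  expect_error(prediction_set(numeric(0), numeric(0)), class = "nb_input_error")
  expect_error(classify(ps, 0), class = "nb_domain_error")
  expect_error(classify(ps, 1), class = "nb_domain_error")
})

test_that("classify matches a brute-force loop on random instances", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(1:1000, 1)
    ps <- random_preds(n, both_classes = FALSE)
    p_t <- runif(1, 0.05, 0.95)
    expect_equal(unlist(classify(ps, p_t)[c("a", "b", "c", "d")]),
                 oracle_classify(ps$outcomes, ps$probabilities, p_t))
  }
})

test_that("net benefit reproduces the three closed forms", {
  # 60% correctly classified, 40% not, at p_t = 0.5: 0.6 - 0.4 = 0.2
  expect_equal(net_benefit(class_proportions(0.3, 0.2, 0.2, 0.3), 0.5,
                           "overall"), 0.2)
  expect_equal(net_benefit(class_proportions(0.45, 0.05, 0.05, 0.45), 0.5,
                           "treated"), 0.40)
  # treat-all classification: untreated net benefit is identically zero
  treat_all <- class_proportions(0.3, 0.7, 0, 0)
  for (p_t in c(0.1, 0.5, 0.9)) {
    expect_equal(net_benefit(treat_all, p_t, "untreated"), 0)
  }
  # perfect model: treated net benefit equals the prevalence
  perfect <- class_proportions(0.3, 0, 0, 0.7)
  for (p_t in c(0.2, 0.8)) {
    expect_equal(net_benefit(perfect, p_t, "treated"), 0.3)
  }
  expect_error(net_benefit(perfect, 1, "treated"), class = "nb_domain_error")
})

test_that("overall net benefit is the sum of treated and untreated", {
  set.seed(7)
  for (rep in 1:200) {
    pr <- random_props()
    p_t <- runif(1, 0.02, 0.98)
    expect_equal(net_benefit(pr, p_t, "overall"),
                 net_benefit(pr, p_t, "treated") +
                   net_benefit(pr, p_t, "untreated"),
                 tolerance = 1e-12)
  }
})

test_that("net benefits are bounded with equality only for perfect models", {
  set.seed(8)
  for (rep in 1:200) {
    pr <- random_props()
    p_t <- runif(1, 0.02, 0.98)
    pi <- pr$a + pr$c
    expect_lt(net_benefit(pr, p_t, "treated"), pi + 1e-12)
    expect_lt(net_benefit(pr, p_t, "untreated"), 1 - pi + 1e-12)
    expect_lt(net_benefit(pr, p_t, "overall"), 1 + 1e-12)
  }
  perfect <- class_proportions(0.4, 0, 0, 0.6)
  expect_equal(net_benefit(perfect, 0.37, "overall"), 1)
})

test_that("absolute benefit differences agree between treated and untreated", {
  ab <- absolute_benefit(class_proportions(0.45, 0.05, 0.05, 0.45), P = 2, L = 1)
  expect_equal(ab$U_treated, 0.85)
  expect_equal(ab$U_untreated, 0.35)
  expect_equal(ab$p_t, 1 / 3)

  none <- absolute_benefit(class_proportions(0, 0, 0.3, 0.7), P = 5, L = 2)
  expect_equal(none$U_treated, 0)

  # same-threshold comparison of two models: identical differences
  set.seed(9)
  for (rep in 1:100) {
    pi <- runif(1, 0.1, 0.9)
    split1 <- runif(2)
    m1 <- class_proportions(pi * split1[1], (1 - pi) * split1[2],
                            pi * (1 - split1[1]), (1 - pi) * (1 - split1[2]))
    split2 <- runif(2)
    m2 <- class_proportions(pi * split2[1], (1 - pi) * split2[2],
                            pi * (1 - split2[1]), (1 - pi) * (1 - split2[2]))
    P <- rexp(1) + 0.1
    L <- rexp(1) + 0.1
    a1 <- absolute_benefit(m1, P, L)
    a2 <- absolute_benefit(m2, P, L)
    expect_equal(a1$U_treated - a2$U_treated,
                 a1$U_untreated - a2$U_untreated, tolerance = 1e-12)
  }
  expect_error(absolute_benefit(class_proportions(0.5, 0, 0, 0.5),
                                P = 0, L = 1), class = "nb_domain_error")
})

test_that("recoding the outcome swaps treated and untreated net benefits", {
  set.seed(10)
  for (rep in 1:100) {
    ps <- random_preds(sample(5:60, 1), both_classes = FALSE)
    p_t <- runif(1, 0.05, 0.95)
    flipped <- prediction_set(1 - ps$outcomes, 1 - ps$probabilities)
    nb <- function(x, t, kind) net_benefit(classify(x, t), t, kind)
    expect_equal(nb(flipped, 1 - p_t, "treated"), nb(ps, p_t, "untreated"))
    expect_equal(nb(flipped, 1 - p_t, "untreated"), nb(ps, p_t, "treated"))
    expect_equal(nb(flipped, 1 - p_t, "overall"), nb(ps, p_t, "overall"))
  }
})

test_that("reference curves follow their closed forms", {
  g <- threshold_grid()
  expect_equal(reference_curve(0.3, as_threshold_grid(0.2), "treat_all",
                               "treated")$net_benefit, 0.125)
  expect_equal(reference_curve(0.3, g, "treat_none", "treated")$net_benefit,
               rep(0, length(g)))
  for (pi in c(0.2, 0.5, 0.8)) {
    expect_equal(reference_curve(pi, g, "perfect", "overall")$net_benefit,
                 rep(1, length(g)))
  }
  # monotonicity of the diverging references
  ta <- reference_curve(0.3, g, "treat_all", "treated")$net_benefit
  expect_true(all(diff(ta) < 0))
  tn <- reference_curve(0.3, g, "treat_none", "untreated")$net_benefit
  expect_true(all(diff(tn) > 0))
  expect_error(reference_curve(0, g, "treat_all", "treated"),
               class = "nb_domain_error")
  expect_error(reference_curve(1, g, "perfect", "overall"),
               class = "nb_domain_error")
})
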