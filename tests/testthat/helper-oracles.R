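# Brute-force oracles, written independently of the package internals:
# plain loops over subjects and over every achievable classification.

oracle_classify <- function(y, p, p_t) {
  n <- length(y)
  a <- b <- c <- d <- 0L
  for (i in seq_len(n)) {
    treated <- p[i] > p_t
    if (treated && y[i] == 1) a <- a + 1L
    else if (treated && y[i] == 0) b <- b + 1L
    else if (!treated && y[i] == 1) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a / n, b = b / n, c = c / n, d = d / n)
}

# every achievable classification: one per distinct probability value used
# as a strict-> cutoff, plus "treat everyone"
oracle_classifications <- function(y, p) {
  cuts <- c(sort(unique(p), decreasing = TRUE), -Inf)
  lapply(cuts, function(ct) {
    treated <- p > ct
    list(cutoff = ct,
         sens = sum(treated & y == 1) / sum(y == 1),
         spec = sum(!treated & y == 0) / sum(y == 0),
         a = mean(treated & y == 1),
         b = mean(treated & y == 0))
  })
}

oracle_roc <- function(y, p) {
  cls <- oracle_classifications(y, p)
  data.frame(cutoff = vapply(cls, `[[`, numeric(1), "cutoff"),
             one_minus_specificity = 1 - vapply(cls, `[[`, numeric(1), "spec"),
             sensitivity = vapply(cls, `[[`, numeric(1), "sens"))
}

# maximizer over all classifications; crit takes (sens, spec, a, b)
oracle_best <- function(y, p, crit) {
  cls <- oracle_classifications(y, p)
  vals <- vapply(cls, function(cl) crit(cl$sens, cl$spec, cl$a, cl$b),
                 numeric(1))
  best <- which(vals >= max(vals) - 1e-15)
  best <- best[which.max(vapply(cls[best], `[[`, numeric(1), "spec"))]
  list(sens = cls[[best]]$sens, spec = cls[[best]]$spec,
       value = vals[best])
}

oracle_youden_best <- function(y, p) {
  oracle_best(y, p, function(sens, spec, a, b) sens + spec - 1)
}

oracle_netbenefit_best <- function(y, p, p_t) {
  oracle_best(y, p, function(sens, spec, a, b) a - b * p_t / (1 - p_t))
}
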