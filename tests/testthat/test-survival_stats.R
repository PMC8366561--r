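test_that("median dichotomization follows the documented tie rule", {
  d <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(d$threshold, 2.5)
  expect_equal(as.character(d$group), c("below", "below", "above", "above"))
  d2 <- dichotomize_at_median(c(1, 2, 2, 5))
  expect_equal(d2$threshold, 2)
  expect_equal(sum(d2$group == "above"), 1)      # only the 5
  expect_equal(sum(d2$group == "below"), 3)      # ties go below
  d3 <- dichotomize_at_median(c(4, 4, 4))
  expect_true(d3$degenerate)
  d4 <- dichotomize_at_median(c(1, NA, 3))
  expect_equal(d4$n_missing, 1)
  expect_error(dichotomize_at_median(c(1, NA)), "non-missing")
})

test_that("product-limit estimate matches the hand-computed censored fixture", {
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  s_at <- function(t) km$surv[max(which(km$time <= t))]
  expect_equal(s_at(1), 0.8)
  expect_equal(s_at(3), 0.8 * (2 / 3), tolerance = 1e-12)
  expect_equal(s_at(5), 0)
  expect_equal(km$median, 5)
  expect_equal(km_estimate(1:5, rep(1, 5))$median, 3)     # S(3)=0.4 <= 0.5
  expect_true(is.na(km_estimate(1:4, rep(0, 4))$median))  # all censored
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("uncensored KM reproduces the empirical survival function", {
  set.seed(15)
  t <- rexp(40, 0.1)
  km <- km_estimate(t, rep(1, 40))
  for (i in seq_along(km$time))
    expect_equal(km$surv[i], mean(t > km$time[i]), tolerance = 1e-12)
})

test_that("log-rank is null on duplicated groups and matches a hand O/E table", {
  lr <- logrank_test(c(3, 5, 7), c(1, 1, 0), c(3, 5, 7), c(1, 1, 0))
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p, 1)
  # 6-subject fixture, hand computation:
  # A: 1(e), 3(e), 5(c); B: 2(e), 4(e), 6(e)
  # t=1: O_A=1 E_A=3/6; t=2: O_A=0 E_A=2/5; t=3: O_A=1 E_A=2/4;
  # t=4: O_A=0 E_A=1/3; t=6: O_A=0 E_A=0 (A exhausted)
  # O_A=2, E_A=0.5+0.4+0.5+1/3=1.7333; V = sum of hypergeometric variances
  v <- (3 * 3) / (6^2) + (2 * 3) / (5^2) + (2 * 2) / (4^2) + (1 * 2) / (3^2)
  chisq_hand <- (2 - 26 / 15)^2 / v
  lr2 <- logrank_test(c(1, 3, 5), c(1, 1, 0), c(2, 4, 6), c(1, 1, 1))
  expect_equal(lr2$obs[1], 2)
  expect_equal(lr2$exp[1], 26 / 15, tolerance = 1e-12)
  expect_equal(lr2$chisq, chisq_hand, tolerance = 1e-12)
  expect_error(logrank_test(1:3, rep(0, 3), 4:6, rep(0, 3)), "no events")
})

test_that("log-rank is invariant under monotone time rescaling", {
  set.seed(8)
  ta <- rexp(30); tb <- rexp(30, 1.7)
  ea <- rbinom(30, 1, 0.8); eb <- rbinom(30, 1, 0.8)
  l1 <- logrank_test(ta, ea, tb, eb)
  l2 <- logrank_test(ta^3 * 12, ea, tb^3 * 12, eb)
  expect_equal(l1$chisq, l2$chisq, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-by-step hand computation", {
  bh <- bh_adjust(c(0.01, 0.02, 0.04), q = 0.3)
  expect_equal(bh$adjusted, c(0.03, 0.03, 0.04))
  expect_true(all(bh$significant))
  expect_equal(bh_adjust(0.2)$adjusted, 0.2)           # m = 1 identity
  expect_equal(bh_adjust(rep(0.1, 3))$adjusted, rep(0.1, 3))
  # adjusted p's never fall below raw and are monotone in rank
  set.seed(2)
  p <- runif(20)
  adj <- bh_adjust(p)$adjusted
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Cox fit agrees with a 1-D partial-likelihood scan on a small fixture", {
  x <- c(0, 1, 0, 1, 0, 1, 0, 1)
  t <- c(2, 1, 5, 3, 8, 4, 9, 7)
  e <- c(1, 1, 1, 1, 1, 1, 0, 1)
  fit <- fit_cox(data.frame(x = x), t, e, ties = "breslow")
  expect_equal(fit$coef, breslow_scan(x, t, e), tolerance = 1e-4)
  expect_equal(fit$hr, exp(fit$coef))
  expect_equal(fit$ci_lo, exp(fit$coef - 1.96 * fit$se))
  expect_equal(fit$p, pchisq((fit$coef / fit$se)^2, 1, lower.tail = FALSE))
})

test_that("Cox on identical survival in both arms gives HR near 1", {
  t <- rep(c(1, 2, 3, 4, 6, 9), 2)
  e <- rep(c(1, 1, 0, 1, 1, 1), 2)
  x <- rep(c(0, 1), each = 6)
  fit <- fit_cox(data.frame(x = x), t, e)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_error(fit_cox(data.frame(x = rep(1, 12)), t, e), "constant")
})

test_that("Cox sign matches the log-rank direction on the same data", {
  set.seed(77)
  for (r in 1:10) {
    x <- rbinom(60, 1, 0.5)
    t <- rexp(60, 0.05 * exp(runif(1, -1, 1) * x))
    e <- rbinom(60, 1, 0.85)
    if (sum(e) < 5 || length(unique(x)) < 2) next
    fit <- suppressWarnings(fit_cox(data.frame(x = x), t, e))
    lr <- logrank_test(t[x == 1], e[x == 1], t[x == 0], e[x == 0])
    worse_in_x1 <- lr$obs[1] > lr$exp[1]  # group A = x == 1
    expect_equal(fit$coef > 0, worse_in_x1)
  }
})

test_that("forward-Wald selection keeps one of two collinear markers", {
  set.seed(31)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(log(3) * x))
  e <- rbinom(n, 1, 0.8)
  sel <- forward_wald_select(data.frame(m1 = x, m2 = x, junk = rbinom(n, 1, 0.5)),
                             t, e)
  expect_equal(sel$selected, "m1")  # duplicate adds nothing, largest Wald first
  expect_gt(sel$model$hr[1], 1)
  # an exact duplicate makes the conditional fit singular: no information,
  # conditional Wald p effectively 1 (reported NA), so it never enters
  dup_row <- sel$trace[sel$trace$step == 2 & sel$trace$candidate == "m2", ]
  expect_true(is.na(dup_row$p) || dup_row$p > 0.9)
  expect_false("m2" %in% sel$selected)
})

test_that("forward selection with no candidates returns an empty model", {
  sel <- forward_wald_select(data.frame()[1:10, , drop = FALSE],
                             rexp(10), rep(1, 10))
  expect_length(sel$selected, 0)
  expect_null(sel$model)
})

test_that("univariate screen recovers a constructed prognostic marker", {
  set.seed(55)
  n <- 120
  z <- rnorm(n)
  tbl <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    os_months = rexp(n, 0.03 * exp(log(3) * z)),
    os_event = rbinom(n, 1, 0.85),
    pfs_months = rexp(n, 0.05), pfs_event = rbinom(n, 1, 0.8),
    marker_hot = z + rnorm(n, 0, 0.2),   # tracks hazard: high = poor
    marker_null = rnorm(n),
    marker_flat = 1)
  sc <- run_univariate_screen(tbl, "os",
                              c("marker_hot", "marker_null", "marker_flat"))
  res <- sc$results
  expect_true(res$significant[res$marker == "marker_hot"])
  expect_equal(res$direction[res$marker == "marker_hot"], "above")
  expect_false("marker_flat" %in% res$marker)
  expect_match(sc$skipped$reason[sc$skipped$marker == "marker_flat"],
               "degenerate")
  expect_true(all(res$p_adj >= res$p))
  expect_equal(res$n_below + res$n_above, rep(n, nrow(res)))
})

test_that("screens are deterministic for a fixed table", {
  set.seed(4)
  tbl <- data.frame(patient_id = sprintf("P%02d", 1:30),
                    os_months = rexp(30, 0.05), os_event = rbinom(30, 1, 0.8),
                    pfs_months = rexp(30, 0.08), pfs_event = rbinom(30, 1, 0.8),
                    m1 = rnorm(30), m2 = rnorm(30))
  s1 <- run_univariate_screen(tbl, "pfs", c("m1", "m2"))
  s2 <- run_univariate_screen(tbl, "pfs", c("m1", "m2"))
  expect_identical(s1$results, s2$results)
})
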