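# Statistics pipeline: normalisation, screening, multivariate stage, ADR
# analyses and Hardy-Weinberg testing against hand-computed oracles.

test_that("dose/weight correction follows its definition and is linear", {
  ds <- tibble::tibble(auc_inf = 166.6, cmax = 39.0, dose = 80, weight = 67.7)
  out <- normalize_exposure(ds)
  expect_equal(out$auc_dw, 166.6 * 67.7 / 80)
  expect_equal(out$auc_dw, 141.0, tolerance = 1e-3)
  expect_equal(out$log_auc_dw, log(out$auc_dw))
  # dose = weight numerically -> AUC/DW equals AUC
  same <- normalize_exposure(tibble::tibble(auc_inf = 100, cmax = 10,
                                            dose = 70, weight = 70))
  expect_equal(same$auc_dw, 100)
  # halving the dose at fixed AUC doubles AUC/DW
  half <- normalize_exposure(tibble::tibble(auc_inf = 166.6, cmax = 39,
                                            dose = 40, weight = 67.7))
  expect_equal(half$auc_dw, 2 * out$auc_dw)
  expect_error(normalize_exposure(tibble::tibble(auc_inf = 1, cmax = 1,
                                                 dose = 0, weight = 70)),
               "positive")
})

test_that("univariate screen handles two-group, multi-group and degenerate data", {
  # identical values in both groups: t = 0, p = 1
  ds <- tibble::tibble(y = rep(5, 10), g = rep(c("a", "b"), each = 5))
  res <- univariate_screen(ds, "y", "g")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_match(res$flags, "constant_outcome")

  # pooled t test equals stats::t.test on the log scale
  set.seed(11)
  ds2 <- tibble::tibble(y = exp(rnorm(40)), g = rep(c("a", "b"), 20))
  res2 <- univariate_screen(ds2, "y", "g")
  ref <- t.test(log(ds2$y[ds2$g == "a"]), log(ds2$y[ds2$g == "b"]),
                var.equal = TRUE)
  expect_equal(res2$p, ref$p.value)
  expect_equal(res2$test, "t")

  # three groups, one shifted far beyond the SD: ANOVA flags it and only the
  # shifted pairs are significant post-hoc
  set.seed(12)
  ds3 <- tibble::tibble(
    y = exp(c(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1), rnorm(20, 3, 0.1))),
    g = rep(c("a", "b", "c"), each = 20)
  )
  res3 <- univariate_screen(ds3, "y", "g")
  expect_equal(res3$test, "anova")
  expect_lt(res3$p, 0.05)
  ph <- res3$posthoc[[1]]
  expect_lt(ph["c", "a"], 0.05)
  expect_lt(ph["c", "b"], 0.05)
  expect_gt(ph["b", "a"], 0.05)

  # a singleton level is reported descriptively and excluded from the test
  ds4 <- tibble::tibble(y = exp(rnorm(21)), g = c(rep(c("a", "b"), 10), "c"))
  res4 <- univariate_screen(ds4, "y", "g")
  expect_equal(res4$test, "t")
  expect_match(res4$flags, "sparse_levels_descriptive_only")
  expect_true("c" %in% res4$groups[[1]]$level)
})

test_that("group descriptives report n, arithmetic mean and CV%", {
  ds <- tibble::tibble(y = c(1, 2, 3, 10, 20, 30),
                       g = rep(c("a", "b"), each = 3))
  res <- univariate_screen(ds, "y", "g")
  desc <- res$groups[[1]]
  expect_equal(desc$n, c(3L, 3L))
  expect_equal(desc$mean[desc$level == "b"], 20)
  expect_equal(desc$cv[desc$level == "b"], 100 * sd(c(10, 20, 30)) / 20)
})

test_that("the Bonferroni threshold is 0.05 over the screened count", {
  expect_identical(bonferroni_alpha(8), 0.00625)
  expect_identical(bonferroni_alpha(1), 0.05)
  expect_identical(bonferroni_alpha(5), 0.01)
  expect_error(bonferroni_alpha(0))
})

test_that("multivariate OLS agrees with the normal equations to 10 digits", {
  set.seed(21)
  n <- 60
  ds <- tibble::tibble(
    x1 = rnorm(n),
    x2 = rep(c("u", "v", "w"), each = 20)
  )
  ds$y <- exp(0.5 + 0.3 * ds$x1 + 0.8 * (ds$x2 == "w") + rnorm(n, 0, 0.2))
  fit <- multivariate_model(ds, "y", c("x1", "x2"))
  X <- stats::model.matrix(~ x1 + x2, data = ds)
  beta <- solve(crossprod(X), crossprod(X, log(ds$y)))
  expect_equal(unname(fit$coefficients$estimate), unname(beta[, 1]),
               tolerance = 1e-10)
  expect_equal(fit$alpha_star, 0.05 / 2)
  expect_equal(fit$k, 2)
})

test_that("a perfectly predictive binary term is recovered with R^2 = 1", {
  ds <- tibble::tibble(g = rep(c("a", "b"), each = 10))
  ds$y <- exp(ifelse(ds$g == "b", 2, 1))
  fit <- suppressWarnings(multivariate_model(ds, "y", "g"))  # perfect fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$coefficients$estimate[2], 1)
})

test_that("rank deficiency names the aliased columns", {
  ds <- tibble::tibble(g = rep(c("a", "b"), each = 10))
  ds$g2 <- ds$g
  ds$y <- exp(rnorm(20))
  expect_error(multivariate_model(ds, "y", c("g", "g2")), "aliased.*g2")
})

test_that("ADR incidence chi-square reproduces case shares and degenerate zero", {
  ds <- tibble::tibble(
    arm = rep(c("E", "D", "B"), times = c(36, 37, 30)),
    adr_gi = c(rep(1, 10), rep(0, 26), rep(1, 2), rep(0, 35), 1, rep(0, 29))
  )
  res <- adr_incidence_test(ds, "adr_gi", "arm")
  expect_equal(unname(res$case_share[c("E", "D", "B")]),
               c(10, 2, 1) / 13)
  expect_equal(unname(100 * res$case_share["E"]), 76.9, tolerance = 0.05)
  expect_lt(res$p, 0.05)
  # identical incidence in all groups -> statistic 0
  flat <- tibble::tibble(arm = rep(c("a", "b"), each = 10),
                         adr = rep(c(1, 0, 1, 0), 5))
  expect_equal(adr_incidence_test(flat, "adr", "arm")$statistic, 0)
  # all events in one group of a large balanced design
  big <- tibble::tibble(arm = rep(c("a", "b"), each = 100),
                        adr = c(rep(1, 40), rep(0, 160)))
  expect_lt(adr_incidence_test(big, "adr", "arm")$p, 0.001)
})

test_that("quasi-separation is flagged and the penalised fallback is finite", {
  set.seed(31)
  ds <- tibble::tibble(
    sex = rep(c("F", "M"), each = 40),
    x = rnorm(80)
  )
  ds$event <- ifelse(ds$sex == "F", rbinom(40, 1, 0.3), 0L)
  res <- adr_logistic(ds, "event", c("sex", "x"))
  expect_true(res$separation)
  pen <- res$penalized_coefficients
  expect_false(is.null(pen))
  expect_true(all(is.finite(pen$estimate)))
  expect_true(all(abs(pen$estimate) < 15))

  # a well-behaved fit is not flagged
  ds$event2 <- rbinom(80, 1, stats::plogis(-0.5 + ds$x))
  res2 <- adr_logistic(ds, "event2", "x")
  expect_false(res2$separation)
})

test_that("Hardy-Weinberg chi-square matches hand-computed expected counts", {
  # exact Hardy-Weinberg proportions: statistic 0
  perfect <- hwe_test(c(25, 50, 25))
  expect_equal(perfect$chisq, 0)
  expect_false(perfect$deviating)

  # hand-computed: q = 270/312, expected (2.8269, 36.3462, 116.8269)
  res <- hwe_test(c(5, 32, 119))
  q <- (2 * 119 + 32) / 312
  e <- 156 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  expect_equal(res$chisq, sum((c(5, 32, 119) - e)^2 / e))
  expect_equal(res$chisq, 2.2306, tolerance = 1e-3)
  expect_gt(res$p_chisq, 0.05)
  expect_false(res$deviating)

  # no heterozygotes at intermediate frequency: extreme deviation
  split <- hwe_test(c(50, 0, 50))
  expect_lt(split$p_chisq, 1e-10)
  expect_lt(split$p_exact, 1e-10)
  expect_true(split$deviating)

  # monomorphic variants are flagged, not tested
  mono <- hwe_test(c(120, 0, 0))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$p_chisq))
})

test_that("exact and chi-square HWE tests agree where decisions are made", {
  # the two p values use different tail definitions (discrete enumeration vs
  # an asymptotic chi-square), so they coincide near the rejection region but
  # can differ substantially in the bulk; the deviation calls must agree away
  # from the 0.05 boundary
  set.seed(41)
  for (q in c(0.2, 0.35, 0.5)) {
    for (i in 1:20) {
      g <- table(factor(rbinom(150, 2, q), levels = 0:2))
      res <- hwe_test(as.numeric(g))
      if (res$monomorphic) next
      if (res$p_chisq < 0.1) {
        expect_lt(abs(res$p_chisq - res$p_exact), 0.06)
      }
      if (abs(res$p_chisq - 0.05) > 0.03) {
        expect_equal(res$p_chisq < 0.05, res$p_exact < 0.05)
      }
    }
  }
})

test_that("exact HWE p is a proper tail probability", {
  expect_equal(hwe_exact_p(c(25, 50, 25)), 1, tolerance = 0.05)
  expect_lte(hwe_exact_p(c(5, 32, 119)), 1)
  expect_gte(hwe_exact_p(c(5, 32, 119)), 0)
})

test_that("DW correction removes a pure dose/weight artifact between sexes", {
  set.seed(51)
  n <- 400
  sex <- rep(c("F", "M"), each = n / 2)
  weight <- ifelse(sex == "F", 60, 80)
  cl_per_kg <- 8 * exp(rnorm(n, 0, 0.3))  # identical CL/kg distribution
  auc <- 80e6 / (cl_per_kg * weight) / 1000
  ds <- tibble::tibble(sex = sex, weight = weight, dose = 80,
                       auc_inf = auc, cmax = auc / 10)
  ds <- normalize_exposure(ds)
  raw <- univariate_screen(ds, "auc_inf", "sex")
  corrected <- univariate_screen(ds, "auc_dw", "sex")
  expect_lt(raw$p, 0.05)
  expect_gt(corrected$p, 0.05)
})

test_that("combine_levels pools factor levels under one label", {
  x <- c("NF", "DF", "PF", "NF")
  expect_equal(combine_levels(x, c("DF", "PF")),
               c("NF", "DF+PF", "DF+PF", "NF"))
})
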