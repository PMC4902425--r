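test_that("Egger regression reproduces the closed-form three-point fit", {
  eff <- make_effects(c(0, 0.2, 0.4), c(0.1, 0.2, 0.4))
  eg <- egger_test(eff)
  expect_equal(eg$intercept, 1.5, tolerance = 1e-10)
  expect_equal(eg$slope, -1 / 7, tolerance = 1e-10)
  expect_equal(eg$p_value, 2 * pt(-abs(eg$statistic), df = 1))
})

test_that("Egger fit agrees with explicit normal equations on k <= 6", {
  set.seed(17)
  for (k in 3:6) {
    theta <- rnorm(k, 0.1, 0.4)
    se <- runif(k, 0.05, 0.5)
    eg <- egger_test(make_effects(theta, se))
    o <- ols_normal_equations(1 / se, theta / se)
    expect_equal(eg$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(eg$slope, o$slope, tolerance = 1e-10)
    expect_equal(eg$intercept_se, o$intercept_se, tolerance = 1e-10)
    expect_equal(eg$statistic, o$t, tolerance = 1e-10)
    expect_equal(eg$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("Egger test agrees with metafor's classical weighted regression", {
  skip_if_not_installed("metafor")
  set.seed(23)
  theta <- rnorm(10, 0.2, 0.3)
  se <- runif(10, 0.1, 0.4)
  eg <- egger_test(make_effects(theta, se))
  rt <- metafor::regtest(metafor::rma(yi = theta, sei = se, method = "DL"),
                         model = "lm", predictor = "sei")
  expect_equal(eg$statistic, as.numeric(rt$zval), tolerance = 1e-8)
  expect_equal(eg$p_value, as.numeric(rt$pval), tolerance = 1e-8)
})

test_that("degenerate Egger inputs are reported, not crashed on", {
  expect_error(egger_test(make_effects(c(0, 1), c(1, 1))),
               class = "hcymr_usage_error")
  expect_warning(deg <- egger_test(make_effects(c(0.2, 0.2, 0.2),
                                                c(0.3, 0.3, 0.3))),
                 "degenerate")
  expect_equal(deg$p_value, 1)
  # standardized effects exactly proportional to precision: zero intercept
  expect_warning(prop <- egger_test(make_effects(c(0.2, 0.2, 0.2, 0.2),
                                                 c(0.1, 0.2, 0.3, 0.4))),
                 "degenerate")
  expect_equal(prop$intercept, 0, tolerance = 1e-10)
  expect_equal(prop$p_value, 1)
})

test_that("Begg's tau equals brute-force pair enumeration for k <= 8", {
  # the Kendall core itself, on the documented rank example
  ks <- hcymr:::kendall_stat(c(1, 3, 2), c(1, 2, 3))
  expect_equal(ks$tau, 1 / 3)
  expect_equal(ks$S, 1)

  set.seed(41)
  for (k in c(3, 5, 8)) {
    for (r in 1:10) {
      theta <- rnorm(k, 0, 0.5)
      se <- runif(k, 0.1, 0.5)
      bg <- begg_test(make_effects(theta, se))
      w <- 1 / se^2
      tf <- sum(w * theta) / sum(w)
      u <- (theta - tf) / sqrt(se^2 - 1 / sum(w))
      o <- kendall_oracle(u, se^2)
      expect_equal(bg$tau, o$tau, tolerance = 1e-12)
      expect_equal(bg$S, o$S)
    }
  }
})

test_that("Begg's tau matches metafor's rank correlation test", {
  skip_if_not_installed("metafor")
  set.seed(43)
  theta <- rnorm(12, 0.1, 0.4)
  se <- runif(12, 0.08, 0.45)
  bg <- begg_test(make_effects(theta, se))
  rk <- metafor::ranktest(theta, sei = se, exact = FALSE)
  expect_equal(bg$tau, as.numeric(rk$tau), tolerance = 1e-10)
})

test_that("perfectly concordant deviates give maximal rank correlation", {
  # u increasing with the variances by construction
  theta <- c(0, 0.5, 1.2, 2.2, 3.5)
  se <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  bg <- begg_test(make_effects(theta, se))
  expect_equal(bg$tau, 1)
  expect_error(begg_test(make_effects(c(0, 1), c(1, 2))),
               class = "hcymr_usage_error")
})

test_that("both bias tests are invariant under study relabeling", {
  set.seed(47)
  theta <- rnorm(9, 0.2, 0.4)
  se <- runif(9, 0.1, 0.4)
  eff <- make_effects(theta, se)
  perm <- sample(9)
  eg1 <- egger_test(eff); eg2 <- egger_test(eff[perm, ])
  bg1 <- begg_test(eff); bg2 <- begg_test(eff[perm, ])
  expect_equal(eg1$statistic, eg2$statistic, tolerance = 1e-12)
  expect_equal(eg1$p_value, eg2$p_value, tolerance = 1e-12)
  expect_equal(bg1$S, bg2$S)
  expect_equal(bg1$p_value, bg2$p_value, tolerance = 1e-12)
})

test_that("funnel data carries points, ranks and pseudo-95% boundaries", {
  single <- funnel_data(make_effects(0.3, 0.2))
  expect_equal(nrow(single$points), 1L)
  expect_equal(single$pooled, 0.3)
  expect_equal(single$boundary$lower, single$pooled - 1.96 * single$boundary$se)

  theta <- c(-0.4, -0.2, 0, 0.2, 0.4)
  fd <- funnel_data(make_effects(theta, rep(0.25, 5)))
  expect_equal(sum(fd$points$log_or > fd$pooled),
               sum(fd$points$log_or < fd$pooled))
  expect_setequal(fd$points$rank, 1:5)
})

test_that("small-study censoring produces funnel asymmetry Egger can see", {
  unbiased <- simulate_studies(sim_config(k = 30, seed = 90, true_log_or = 0,
                                          tau = 0))
  biased <- simulate_studies(sim_config(k = 30, seed = 90, true_log_or = 0,
                                        tau = 0, small_study_bias = TRUE))
  e0 <- egger_test(study_effects(unbiased, "allele"))
  e1 <- egger_test(study_effects(biased, "allele"))
  expect_lt(e1$p_value, e0$p_value)
  expect_lt(e1$p_value, 0.05)
})
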