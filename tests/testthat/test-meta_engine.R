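test_that("fixed-effect pooling matches hand computation and degenerate cases", {
  one <- pool_fixed(make_effects(0.5, 0.2))
  expect_equal(one$pooled_log_or, 0.5)
  expect_equal(one$se, 0.2)
  expect_equal(one$Q, 0)
  expect_equal(one$q_p, 1)
  expect_equal(one$i_squared, 0)

  eq <- pool_fixed(make_effects(c(0, 1), c(1, 1)))
  expect_equal(eq$pooled_log_or, 0.5)
  expect_equal(eq$se, 1 / sqrt(2))

  same <- pool_fixed(make_effects(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(same$pooled_log_or, 0.3)
  expect_equal(same$Q, 0)

  expect_error(pool_fixed(data.frame(log_or = numeric(0), se = numeric(0))),
               class = "hcymr_usage_error")
})

test_that("heterogeneity statistics match hand computation", {
  h1 <- heterogeneity(make_effects(c(0, 1), c(1, 1)))
  expect_equal(h1$Q, 0.5)
  expect_equal(h1$i_squared, 0)  # truncated: Q < k-1

  h2 <- heterogeneity(make_effects(c(0, 2), c(1, 1)))
  expect_equal(h2$Q, 2)
  expect_equal(h2$i_squared, 50)
  expect_equal(h2$q_p, pchisq(2, 1, lower.tail = FALSE))
})

test_that("DerSimonian-Laird pooling matches hand computation and truncation", {
  r <- pool_random(make_effects(c(0, 2), c(1, 1)))
  expect_equal(r$tau_squared, 1)  # (2-1)/(2 - 2/2)
  expect_equal(r$pooled_log_or, 1)
  expect_equal(r$se, 1)

  # Q <= k-1: tau^2 truncates to zero and random equals fixed exactly
  eff <- make_effects(c(0.1, 0.12, 0.11), c(0.3, 0.3, 0.3))
  f <- pool_fixed(eff); rr <- pool_random(eff)
  expect_identical(rr$tau_squared, 0)
  expect_identical(rr$pooled_log_or, f$pooled_log_or)
  expect_identical(rr$se, f$se)

  single <- pool_random(make_effects(0.4, 0.15))
  expect_equal(single$tau_squared, 0)
  expect_equal(single$pooled_log_or, 0.4)
  expect_equal(single$se, 0.15)
})

test_that("pooling agrees with closed-form WLS normal equations on k <= 6", {
  set.seed(77)
  for (k in 2:6) {
    theta <- rnorm(k, 0.2, 0.4)
    se <- runif(k, 0.05, 0.5)
    f <- pool_fixed(make_effects(theta, se))
    o <- wls_constant(theta, se)
    expect_equal(f$pooled_log_or, o$pooled, tolerance = 1e-10)
    expect_equal(f$se, o$se, tolerance = 1e-10)
    r <- pool_random(make_effects(theta, se))
    t2 <- dl_tau2_oracle(theta, se)
    expect_equal(r$tau_squared, t2, tolerance = 1e-10)
    o2 <- wls_constant(theta, sqrt(se^2 + t2))
    expect_equal(r$pooled_log_or, o2$pooled, tolerance = 1e-10)
    expect_equal(r$se, o2$se, tolerance = 1e-10)
  }
})

test_that("pooling agrees with metafor's FE and DL fits", {
  skip_if_not_installed("metafor")
  set.seed(13)
  theta <- rnorm(9, 0.1, 0.5)
  se <- runif(9, 0.08, 0.45)
  f <- pool_fixed(make_effects(theta, se))
  r <- pool_random(make_effects(theta, se))
  mf <- metafor::rma(yi = theta, sei = se, method = "FE")
  md <- metafor::rma(yi = theta, sei = se, method = "DL")
  expect_equal(f$pooled_log_or, as.numeric(mf$b), tolerance = 1e-10)
  expect_equal(f$se, mf$se, tolerance = 1e-10)
  expect_equal(f$Q, mf$QE, tolerance = 1e-10)
  expect_equal(r$tau_squared, md$tau2, tolerance = 1e-10)
  expect_equal(r$pooled_log_or, as.numeric(md$b), tolerance = 1e-10)
  expect_equal(r$se, md$se, tolerance = 1e-10)
})

test_that("model selection follows the heterogeneity thresholds", {
  expect_equal(select_model(list(q_p = 0.5, i_squared = 10)), "fixed")
  expect_equal(select_model(list(q_p = 0.05, i_squared = 30)), "random")
  expect_equal(select_model(list(q_p = 0.5, i_squared = 60)), "random")
  expect_equal(select_model(list(q_p = 0.09, i_squared = 10),
                            p_threshold = 0.05), "fixed")
  expect_error(select_model(list(q_p = 0.5, i_squared = 10),
                            p_threshold = 0), class = "hcymr_usage_error")
})

test_that("normalized weights sum to one and CI brackets the estimate", {
  studies <- simulate_studies(sim_config(k = 10, seed = 8))
  for (m in GENETIC_MODELS) {
    fit <- pool_studies(studies, model = m)
    for (p in list(fit$fixed, fit$random)) {
      expect_equal(sum(p$weights), 1, tolerance = 1e-9)
      expect_lte(p$ci_low, exp(p$pooled_log_or))
      expect_gte(p$ci_high, exp(p$pooled_log_or))
    }
  }
})

test_that("I-squared is invariant when effects and SEs rescale together", {
  theta <- c(-0.2, 0.1, 0.4, 0.7)
  se <- c(0.2, 0.3, 0.15, 0.25)
  base <- heterogeneity(make_effects(theta, se))
  for (cc in c(0.1, 2, 10)) {
    scaled <- heterogeneity(make_effects(theta * cc, se * cc))
    expect_equal(scaled$i_squared, base$i_squared, tolerance = 1e-10)
    expect_equal(scaled$Q, base$Q, tolerance = 1e-10)
  }
})

test_that("subgroup analysis reduces to overall pooling for one stratum", {
  studies <- simulate_studies(sim_config(
    k = 8, seed = 4, ethnicity_probs = c(Asian = 1, Caucasian = 0, Mixed = 0)))
  sub <- subgroup_analysis(studies, "allele", by = "ethnicity")
  expect_equal(names(sub), "Asian")
  overall <- pool_studies(studies, "allele")
  expect_equal(sub$Asian$pooled$pooled_log_or,
               overall$pooled$pooled_log_or)

  # two strata carrying identical data give identical pooled results
  a <- toy_studies(4); a$ethnicity <- "Asian"
  b <- a; b$ethnicity <- "Caucasian"; b$study_id <- paste0(b$study_id, "b")
  sub2 <- subgroup_analysis(rbind(a, b), "allele", by = "ethnicity")
  expect_equal(sub2$Asian$pooled$pooled_log_or,
               sub2$Caucasian$pooled$pooled_log_or)
  expect_equal(sub2$Asian$pooled$se, sub2$Caucasian$pooled$se)
})

test_that("subgroups with distinct true ORs bracket their truths at large n", {
  big <- function(or, eth, seed) simulate_studies(sim_config(
    k = 6, seed = seed, true_log_or = log(or), tau = 0,
    n_cases_range = c(4000L, 5000L), n_controls_range = c(4000L, 5000L),
    ethnicity_probs = setNames(as.numeric(
      c("Asian", "Caucasian", "Mixed") == eth),
      c("Asian", "Caucasian", "Mixed"))))
  a <- big(1.0, "Asian", 61)
  b <- big(2.0, "Caucasian", 62)
  b$study_id <- paste0(b$study_id, "b")
  sub <- subgroup_analysis(rbind(a, b), "allele", by = "ethnicity")
  expect_gt(sub$Asian$pooled$ci_high, 1.0)
  expect_lt(sub$Asian$pooled$ci_low, 1.0)
  expect_gt(sub$Caucasian$pooled$ci_high, 2.0)
  expect_lt(sub$Caucasian$pooled$ci_low, 2.0)
})

test_that("leave-one-out isolates an outlier and handles degeneracies", {
  expect_error(leave_one_out(toy_studies(1)), class = "hcymr_usage_error")

  # two identical studies: each row equals the single-study estimate
  a <- one_study_table(id = "a"); b <- one_study_table(id = "b")
  loo <- leave_one_out(rbind(a, b), "allele")
  single <- pool_studies(a, "allele")
  expect_equal(nrow(loo), 2L)
  expect_equal(loo$or, rep(exp(single$pooled$pooled_log_or), 2))

  # one strong outlier among nulls: omitting it moves the pool closest to 1
  set.seed(55)
  nulls <- simulate_studies(sim_config(k = 10, seed = 50, true_log_or = 0,
                                       tau = 0))
  out <- one_study_table(case = c(20, 100, 200), ctrl = c(200, 100, 20),
                         id = "outlier")
  tab <- rbind(nulls[, names(out)], out)
  loo2 <- leave_one_out(tab, "allele", method = "fixed")
  closest <- loo2$omitted[which.min(abs(log(loo2$or)))]
  expect_equal(closest, "outlier")
})

test_that("HWE-exclusion sensitivity pools only compliant studies", {
  studies <- simulate_studies(mthfr_gc_config(seed = 14))
  studies <- add_hwe(studies)
  fit <- hwe_exclusion(studies, "allele", alpha = 0.05)
  n_dev <- sum(studies$hwe_p < 0.05)
  expect_equal(attr(fit, "n_excluded"), n_dev)
  expect_equal(fit$pooled$k, 27 - n_dev)

  # all compliant: identical to overall pooling
  clean <- simulate_studies(sim_config(k = 8, seed = 70))
  clean <- add_hwe(clean)
  clean <- clean[clean$hwe_p >= 0.05, ]
  expect_equal(hwe_exclusion(clean, "allele")$pooled$pooled_log_or,
               pool_studies(clean, "allele")$pooled$pooled_log_or)

  # empty subset errors
  forced <- clean
  forced$hwe_p <- 0
  expect_error(hwe_exclusion(forced, "allele"),
               class = "hcymr_usage_error")
})

test_that("removing HWE-violating studies shifts tau^2 down in simulation", {
  # inbreeding distortion perturbs control genotype splits and inflates
  # apparent between-study variance in genotype-based contrasts
  t2_all <- t2_kept <- numeric(40)
  for (r in 1:40) {
    st <- add_hwe(simulate_studies(sim_config(
      k = 20, seed = 300 + r, tau = 0, hwe_violation_fraction = 0.5,
      inbreeding_f = 0.3)))
    t2_all[r] <- pool_studies(st, "recessive")$random$tau_squared
    kept <- st[!st$hwe_violating, ]
    t2_kept[r] <- pool_studies(kept, "recessive")$random$tau_squared
  }
  expect_lt(mean(t2_kept), mean(t2_all))
})
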