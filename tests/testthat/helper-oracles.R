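# Independent oracles and small fixtures used across the test files.
# Every oracle here is a from-first-principles computation, deliberately
# not sharing code with the package internals it checks.

# two-parameter OLS by explicit normal equations
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - 2
  sigma2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(sigma2 * xtx_inv)))
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       intercept_se = se[1], t = unname(beta[1]) / se[1],
       p = unname(2 * pt(-abs(beta[1] / se[1]), df = df)))
}

# weighted least squares of theta on a constant (the fixed-effect pooled
# estimate) via explicit normal equations
wls_constant <- function(theta, se) {
  W <- diag(1 / se^2, nrow = length(theta))
  X <- matrix(1, length(theta), 1)
  xtwx <- t(X) %*% W %*% X
  b <- solve(xtwx) %*% t(X) %*% W %*% theta
  list(pooled = as.numeric(b), se = sqrt(as.numeric(solve(xtwx))))
}

# DerSimonian-Laird tau^2 written out directly
dl_tau2_oracle <- function(theta, se) {
  w <- 1 / se^2
  tf <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - tf)^2)
  max(0, (Q - (length(theta) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Pearson HWE chi-square upper tail by explicit enumeration of the three
# genotype cells
hwe_oracle <- function(cc, ct, tt) {
  n <- cc + ct + tt
  p <- (2 * cc + ct) / (2 * n)
  if (p == 0 || p == 1) return(1)
  obs <- c(cc, ct, tt)
  exp_cells <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- 0
  for (j in 1:3) chisq <- chisq + (obs[j] - exp_cells[j])^2 / exp_cells[j]
  pchisq(chisq, 1, lower.tail = FALSE)
}

# Kendall S and tau by brute-force enumeration of all pairs
kendall_oracle <- function(u, v) {
  n <- length(u)
  S <- 0; tu <- 0; tv <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    S <- S + sign(u[i] - u[j]) * sign(v[i] - v[j])
    if (u[i] == u[j]) tu <- tu + 1
    if (v[i] == v[j]) tv <- tv + 1
  }
  n0 <- n * (n - 1) / 2
  list(S = S, tau = S / sqrt((n0 - tu) * (n0 - tv)))
}

make_effects <- function(theta, se, ids = paste0("s", seq_along(theta))) {
  data.frame(study_id = ids, model = rep("allele", length(theta)),
             log_or = theta, se = se,
             corrected = rep(FALSE, length(theta)),
             estimable = rep(TRUE, length(theta)),
             stringsAsFactors = FALSE)
}

one_study_table <- function(case = c(10, 20, 10), ctrl = c(20, 20, 10),
                            id = "s1", ethnicity = "Asian",
                            source = "population") {
  data.frame(study_id = id, year = 2010, ethnicity = ethnicity,
             control_source = source,
             case_cc = case[1], case_ct = case[2], case_tt = case[3],
             ctrl_cc = ctrl[1], ctrl_ct = ctrl[2], ctrl_tt = ctrl[3],
             stringsAsFactors = FALSE)
}

# a small deterministic multi-study table with both strata represented
toy_studies <- function(k = 6) {
  set.seed(99)
  do.call(rbind, lapply(seq_len(k), function(i) {
    one_study_table(case = as.integer(c(40, 60, 30) + rpois(3, 10)),
                    ctrl = as.integer(c(60, 70, 25) + rpois(3, 10)),
                    id = sprintf("t%02d", i),
                    ethnicity = c("Asian", "Caucasian")[1 + i %% 2],
                    source = c("population", "hospital")[1 + i %% 2])
  }))
}
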