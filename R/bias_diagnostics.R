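## Small-study / publication-bias diagnostics: Egger's regression test,
## Begg and Mazumdar's rank-correlation test, and funnel-plot data.

#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `y_i = theta_i/se_i`
#' on precision `x_i = 1/se_i`; under no small-study bias the intercept is
#' zero. The test statistic is `intercept / se(intercept)` referred to a t
#' distribution with k-2 df, two-sided. The fit itself is delegated to
#' [stats::lm()].
#'
#' @param effects Per-study effects (`log_or`, `se`), k >= 3.
#' @return A list of class `bias_test` with `method = "egger"`,
#'   `statistic` (t), `p_value`, `intercept`, `intercept_se`, `slope`, `k`.
#' @examples
#' eff <- data.frame(log_or = c(0, 0.2, 0.4), se = c(0.1, 0.2, 0.4))
#' egger_test(eff)
#' @export
egger_test <- function(effects) {
  effects <- as_effects_frame(effects)
  k <- nrow(effects)
  if (k < 3L) stop_usage("Egger's test needs at least 3 studies")
  x <- 1 / effects$se
  y <- effects$log_or / effects$se
  if (stats::var(x) < 1e-14) {
    warning("degenerate Egger fit: all standard errors equal", call. = FALSE)
    return(structure(list(method = "egger", statistic = NA_real_,
                          p_value = 1, intercept = NA_real_,
                          intercept_se = NA_real_, slope = NA_real_, k = k),
                     class = "bias_test"))
  }
  fit <- stats::lm(y ~ x)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-12) {
    ## exact linear relation: no residual scale to test against
    warning("degenerate Egger fit: standardized effects exactly linear in precision",
            call. = FALSE)
    pval <- if (abs(b0) < 1e-10) 1 else 0
    return(structure(list(method = "egger",
                          statistic = if (abs(b0) < 1e-10) 0 else Inf,
                          p_value = pval, intercept = b0,
                          intercept_se = 0, slope = b1, k = k),
                     class = "bias_test"))
  }
  se0 <- unname(sqrt(diag(stats::vcov(fit)))[1])
  tval <- b0 / se0
  structure(list(method = "egger", statistic = tval,
                 p_value = 2 * stats::pt(-abs(tval), df = k - 2),
                 intercept = b0, intercept_se = unname(se0),
                 slope = b1, k = k),
            class = "bias_test")
}

## Kendall S statistic and its tie-corrected null variance
kendall_stat <- function(u, v) {
  n <- length(u)
  du <- sign(outer(u, u, "-"))
  dv <- sign(outer(v, v, "-"))
  S <- sum(du[lower.tri(du)] * dv[lower.tri(dv)])
  tie_counts <- function(z) as.numeric(table(z)[table(z) > 1])
  t_u <- tie_counts(u); t_v <- tie_counts(v)
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(t_u * (t_u - 1) * (2 * t_u + 5)) -
              sum(t_v * (t_v - 1) * (2 * t_v + 5))) / 18
  if (n > 2) {
    var_s <- var_s +
      sum(t_u * (t_u - 1) * (t_u - 2)) * sum(t_v * (t_v - 1) * (t_v - 2)) /
        (9 * n * (n - 1) * (n - 2)) +
      sum(t_u * (t_u - 1)) * sum(t_v * (t_v - 1)) / (2 * n * (n - 1))
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - sum(t_u * (t_u - 1) / 2)) *
                  (n0 - sum(t_v * (t_v - 1) / 2)))
  list(S = S, var_s = var_s, tau = if (denom > 0) S / denom else NA_real_)
}

#' Begg and Mazumdar's rank-correlation test
#'
#' Correlates the variance-standardized deviates
#' `u_i = (theta_i - theta_F) / sqrt(se_i^2 - 1/sum(w))` (with the
#' fixed-effect pooled value `theta_F` and weights `w = 1/se^2`) with the
#' study variances `se_i^2` using Kendall's tau. The two-sided p-value
#' uses the normal approximation to the Kendall S statistic with the
#' standard tie-corrected variance and a continuity correction.
#'
#' @param effects Per-study effects (`log_or`, `se`), k >= 3.
#' @return A `bias_test` with `method = "begg"`, `statistic` (the
#'   continuity-corrected z), `p_value`, `tau`, `S`, `k`.
#' @export
begg_test <- function(effects) {
  effects <- as_effects_frame(effects)
  k <- nrow(effects)
  if (k < 3L) stop_usage("Begg's test needs at least 3 studies")
  w <- 1 / effects$se^2
  theta_f <- sum(w * effects$log_or) / sum(w)
  v_star <- effects$se^2 - 1 / sum(w)
  v_star <- pmax(v_star, .Machine$double.eps)
  u <- (effects$log_or - theta_f) / sqrt(v_star)
  ks <- kendall_stat(u, effects$se^2)
  z <- if (ks$var_s > 0 && abs(ks$S) > 0)
    sign(ks$S) * (abs(ks$S) - 1) / sqrt(ks$var_s) else 0
  structure(list(method = "begg", statistic = z,
                 p_value = min(1, 2 * stats::pnorm(-abs(z))),
                 tau = ks$tau, S = ks$S, k = k),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  if (identical(x$method, "egger")) {
    cat(sprintf(
      "Egger's regression test (k = %d): intercept %.4f (SE %.4f), t = %.3f, p = %.4g\n",
      x$k, x$intercept, x$intercept_se, x$statistic, x$p_value))
  } else {
    cat(sprintf(
      "Begg's rank-correlation test (k = %d): tau = %.4f, z = %.3f, p = %.4g\n",
      x$k, x$tau, x$statistic, x$p_value))
  }
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-study points (log OR vs standard error, with the inverted-axis
#' precision rank) plus pseudo-95% funnel boundaries around the
#' fixed-effect pooled value over an SE grid.
#'
#' @param effects Per-study effects (`log_or`, `se`).
#' @param grid_n Number of points in the boundary SE grid.
#' @return List of class `funnel_data`: `points` (data frame `study_id`,
#'   `log_or`, `se`, `rank` where rank 1 is the most precise study),
#'   `boundary` (data frame `se`, `lower`, `upper`), and `pooled` (the
#'   fixed-effect pooled log OR).
#' @export
funnel_data <- function(effects, grid_n = 50L) {
  effects <- as_effects_frame(effects)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  se_grid <- seq(0, max(effects$se) * 1.05, length.out = grid_n)
  structure(list(
    points = data.frame(study_id = effects$study_id,
                        log_or = effects$log_or, se = effects$se,
                        rank = rank(effects$se, ties.method = "first"),
                        stringsAsFactors = FALSE),
    boundary = data.frame(se = se_grid,
                          lower = pooled - Z95 * se_grid,
                          upper = pooled + Z95 * se_grid),
    pooled = pooled
  ), class = "funnel_data")
}

#' @export
plot.funnel_data <- function(x, ...) {
  graphics::plot(x$points$log_or, x$points$se,
                 ylim = rev(range(c(0, x$points$se))),
                 xlim = range(c(x$points$log_or, x$boundary$lower,
                                x$boundary$upper)),
                 xlab = "log OR", ylab = "standard error", ...)
  graphics::lines(x$boundary$lower, x$boundary$se, lty = 2)
  graphics::lines(x$boundary$upper, x$boundary$se, lty = 2)
  graphics::abline(v = x$pooled, lty = 3)
  invisible(x)
}
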