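## Inverse-variance pooling: fixed effect and DerSimonian-Laird random
## effects, Cochran's Q / I-squared heterogeneity, the model-selection rule,
## subgroup analysis, and the two sensitivity analyses.

Z95 <- 1.96  # normal quantile used for all 95% intervals

as_effects_frame <- function(effects, drop_inestimable = TRUE) {
  if (inherits(effects, "effect_estimate"))
    effects <- data.frame(study_id = effects$study_id, model = effects$model,
                          log_or = effects$log_or, se = effects$se,
                          corrected = effects$corrected,
                          estimable = effects$estimable,
                          stringsAsFactors = FALSE)
  effects <- as.data.frame(effects, stringsAsFactors = FALSE)
  if (!all(c("log_or", "se") %in% names(effects)))
    stop_usage("effects must have log_or and se columns")
  if (nrow(effects) == 0L)
    stop_usage("no estimable effects to pool")
  if (is.null(effects$study_id))
    effects$study_id <- paste0("study_", seq_len(nrow(effects)))
  if (is.null(effects$model)) effects$model <- NA_character_
  if (!is.null(effects$estimable) && drop_inestimable &&
      any(!effects$estimable)) {
    warning(sprintf("excluding %d non-estimable effect(s) from pooling: %s",
                    sum(!effects$estimable),
                    paste(effects$study_id[!effects$estimable],
                          collapse = ", ")), call. = FALSE)
    effects <- effects[effects$estimable, , drop = FALSE]
  }
  if (nrow(effects) == 0L)
    stop_usage("no estimable effects to pool")
  if (any(!is.finite(effects$log_or)) || any(effects$se <= 0))
    stop_usage("effects must have finite log_or and positive se")
  effects
}

#' Cochran's Q and I-squared heterogeneity statistics
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-study effects from the fixed-effect pooled value; its reference
#' distribution under homogeneity is chi-square with k-1 df.
#' `I^2 = max(0, (Q - (k-1))/Q) * 100` is the percentage of total variation
#' attributable to between-study heterogeneity. For a single study the
#' conventions Q = 0, p = 1, I^2 = 0 apply.
#'
#' @param effects Data frame of per-study effects (`log_or`, `se`), e.g.
#'   from [study_effects()].
#' @return List with `Q`, `q_p`, `i_squared`, `df`.
#' @export
heterogeneity <- function(effects) {
  effects <- as_effects_frame(effects)
  k <- nrow(effects)
  if (k == 1L)
    return(list(Q = 0, q_p = 1, i_squared = 0, df = 0L))
  w <- 1 / effects$se^2
  theta_f <- sum(w * effects$log_or) / sum(w)
  Q <- sum(w * (effects$log_or - theta_f)^2)
  q_p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(Q = Q, q_p = q_p, i_squared = i2, df = k - 1L)
}

make_pooled <- function(model, effects, pooled, se, het, tau2, effects_model,
                        w) {
  p <- 2 * stats::pnorm(-abs(pooled / se))
  structure(list(
    model = model, k = nrow(effects),
    pooled_log_or = pooled, se = se,
    ci_low = exp(pooled - Z95 * se), ci_high = exp(pooled + Z95 * se),
    p_value = p,
    Q = het$Q, q_p = het$q_p, i_squared = het$i_squared,
    tau_squared = tau2,
    effects_model = effects_model,
    weights = stats::setNames(w / sum(w), effects$study_id),
    study_id = effects$study_id,
    effects = effects
  ), class = "pooled_result")
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each study by the reciprocal of its squared standard error:
#' the pooled log OR is `sum(w * theta) / sum(w)` with standard error
#' `1/sqrt(sum(w))`; the 95% CI is `exp(pooled +/- 1.96 * se)` and the
#' p-value is two-sided normal.
#'
#' @param effects Per-study effects (`log_or`, `se`).
#' @return A `pooled_result` (see [pool_studies()] for the fields).
#' @export
pool_fixed <- function(effects) {
  effects <- as_effects_frame(effects)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- heterogeneity(effects)
  tau2 <- dl_tau_squared(effects, het)
  make_pooled(effects$model[1], effects, pooled, se, het, tau2, "fixed", w)
}

dl_tau_squared <- function(effects, het = heterogeneity(effects)) {
  k <- nrow(effects)
  if (k < 2L) return(0)
  w <- 1 / effects$se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (het$Q - (k - 1)) / denom)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w`, then inverse-variance pooling with random
#' weights `1/(se^2 + tau^2)`. When `Q <= k-1` the estimate truncates to
#' zero and the result coincides exactly with [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result` with `effects_model = "random"`.
#' @export
pool_random <- function(effects) {
  effects <- as_effects_frame(effects)
  het <- heterogeneity(effects)
  tau2 <- dl_tau_squared(effects, het)
  w_star <- 1 / (effects$se^2 + tau2)
  pooled <- sum(w_star * effects$log_or) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  make_pooled(effects$model[1], effects, pooled, se, het, tau2, "random",
              w_star)
}

#' Heterogeneity-driven choice between fixed and random effects
#'
#' Returns `"random"` when the Q test is significant at the `p_threshold`
#' level or I-squared exceeds `i2_threshold` percent, otherwise `"fixed"`.
#' Defaults follow the usual meta-analytic rule (p < 0.1 or I^2 > 50).
#'
#' @param het Heterogeneity triple from [heterogeneity()].
#' @param p_threshold Q-test significance threshold, in (0, 1).
#' @param i2_threshold I-squared threshold, in (0, 100).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, p_threshold = 0.1, i2_threshold = 50) {
  if (p_threshold <= 0 || p_threshold >= 1 ||
      i2_threshold <= 0 || i2_threshold >= 100)
    stop_usage("heterogeneity thresholds out of range")
  if (het$q_p < p_threshold || het$i_squared > i2_threshold)
    "random" else "fixed"
}

#' Pool a study collection under one genetic model
#'
#' The central fitting function: computes per-study effects under the
#' requested genetic-model contrast, both the fixed-effect and the
#' DerSimonian-Laird random-effects pooled estimates, the heterogeneity
#' statistics, and applies the selection rule of [select_model()] (unless
#' `method` forces one model). Both pooled results are always retained.
#'
#' @param studies A study data frame (or a per-study effects frame with
#'   `log_or` and `se` columns, in which case `model` and `correction`
#'   are ignored).
#' @param model Genetic model, one of
#'   `r paste(GENETIC_MODELS, collapse = ", ")`.
#' @param method `"auto"` (heterogeneity rule), `"fixed"` or `"random"`.
#' @param correction Continuity-correction switch for zero cells.
#' @param p_threshold,i2_threshold Thresholds for [select_model()].
#' @return An object of class `meta_pool`: a list with `model`, `effects`
#'   (per-study frame), `het`, `fixed` and `random` (`pooled_result`
#'   objects), `selected` (`"fixed"` or `"random"`) and `pooled` (the
#'   selected result). A `pooled_result` carries the pooled log OR, its
#'   SE, the OR-scale 95% CI, two-sided p, Q, Q p-value, I^2, tau^2 and
#'   normalized weights.
#' @examples
#' studies <- simulate_studies(sim_config(k = 8, seed = 42))
#' fit <- pool_studies(studies, model = "allele")
#' print(fit)
#' coef(fit)
#' @export
pool_studies <- function(studies, model = "allele",
                         method = c("auto", "fixed", "random"),
                         correction = TRUE,
                         p_threshold = 0.1, i2_threshold = 50) {
  method <- match.arg(method)
  effects <- if (is.data.frame(studies) && "log_or" %in% names(studies))
    as_effects_frame(studies)
  else
    as_effects_frame(study_effects(studies, model, correction))
  fixed <- pool_fixed(effects)
  random <- pool_random(effects)
  het <- heterogeneity(effects)
  selected <- if (method == "auto")
    select_model(het, p_threshold, i2_threshold) else method
  structure(list(model = model, effects = effects, het = het,
                 fixed = fixed, random = random, selected = selected,
                 pooled = if (selected == "fixed") fixed else random),
            class = "meta_pool")
}

## Subgroup and sensitivity analyses ------------------------------------------

#' Subgroup meta-analysis by a stratification variable
#'
#' Runs the full pooling pipeline (including model selection) separately
#' within each level of a stratifier; strata with no studies are omitted.
#'
#' @param studies Study data frame.
#' @param model Genetic model.
#' @param by `"ethnicity"` or `"control_source"`.
#' @param ... Passed to [pool_studies()].
#' @return Named list of `meta_pool` objects, one per observed stratum,
#'   of class `subgroup_result`.
#' @export
subgroup_analysis <- function(studies, model = "allele",
                              by = c("ethnicity", "control_source"), ...) {
  by <- match.arg(by)
  studies <- validate_studies(studies)
  split_tab <- split(studies, studies[[by]], drop = TRUE)
  out <- lapply(split_tab, pool_studies, model = model, ...)
  structure(out, by = by, class = c("subgroup_result", class(out)))
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the full pooling (with the same model-selection rule) k times,
#' omitting each study in turn.
#'
#' @param studies Study data frame with at least two studies.
#' @param model Genetic model.
#' @param ... Passed to [pool_studies()].
#' @return Data frame of class `loo_result`, one row per omitted study:
#'   the pooled OR, CI, p-value, selected effects model and a
#'   `significant` flag (CI excludes 1) for the remaining k-1 studies.
#' @export
leave_one_out <- function(studies, model = "allele", ...) {
  studies <- validate_studies(studies)
  if (nrow(studies) < 2L)
    stop_usage("leave-one-out needs at least two studies")
  dots <- list(...)
  effects <- do.call(study_effects, c(
    list(studies, model),
    dots[intersect(names(dots), "correction")]))
  pool_args <- dots[intersect(names(dots), c("p_threshold", "i2_threshold",
                                             "method"))]
  rows <- lapply(seq_len(nrow(effects)), function(i) {
    fit <- do.call(pool_studies, c(
      list(effects[-i, , drop = FALSE], model = model), pool_args))
    p <- fit$pooled
    data.frame(omitted = effects$study_id[i], k = p$k,
               or = exp(p$pooled_log_or), ci_low = p$ci_low,
               ci_high = p$ci_high, p_value = p$p_value,
               effects_model = p$effects_model,
               significant = p$ci_low > 1 | p$ci_high < 1,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("loo_result", "data.frame"))
}

#' Sensitivity analysis excluding studies out of Hardy-Weinberg equilibrium
#'
#' Re-pools using only studies whose control genotypes are compatible with
#' HWE at the given significance level.
#'
#' @param studies Study data frame; `hwe_p` is computed if absent.
#' @param model Genetic model.
#' @param alpha HWE significance level (studies with `hwe_p < alpha` are
#'   excluded).
#' @param ... Passed to [pool_studies()].
#' @return A `meta_pool` fit on the retained subset, with attributes
#'   `n_excluded` and `excluded` (the study labels dropped).
#' @export
hwe_exclusion <- function(studies, model = "allele", alpha = 0.05, ...) {
  studies <- validate_studies(studies)
  if (is.null(studies$hwe_p)) studies <- add_hwe(studies)
  keep <- studies$hwe_p >= alpha
  if (!any(keep))
    stop_usage("no studies with controls in HWE at alpha = ", alpha)
  fit <- pool_studies(studies[keep, , drop = FALSE], model = model, ...)
  attr(fit, "n_excluded") <- sum(!keep)
  attr(fit, "excluded") <- studies$study_id[!keep]
  fit
}

## S3 methods ------------------------------------------------------------------

fmt_pooled_line <- function(p) {
  sprintf("%-8s k=%2d  OR %.3f [%.3f, %.3f]  p=%.4g",
          p$effects_model, p$k, exp(p$pooled_log_or), p$ci_low, p$ci_high,
          p$p_value)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled odds ratio (%s model, %s effects)\n",
              x$model, x$effects_model))
  cat(sprintf("  OR %.4f  95%% CI [%.4f, %.4f]  p = %.4g  (k = %d)\n",
              exp(x$pooled_log_or), x$ci_low, x$ci_high, x$p_value, x$k))
  cat(sprintf("  Q = %.3f (p = %.4g), I^2 = %.1f%%, tau^2 = %.4f\n",
              x$Q, x$q_p, x$i_squared, x$tau_squared))
  invisible(x)
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Genotype-count meta-analysis: %s model, k = %d studies\n",
              x$model, nrow(x$effects)))
  cat(" ", fmt_pooled_line(x$fixed), "\n")
  cat(" ", fmt_pooled_line(x$random), "\n")
  cat(sprintf("  heterogeneity: Q = %.3f (p = %.4g), I^2 = %.1f%% -> %s effects selected\n",
              x$het$Q, x$het$q_p, x$het$i_squared, x$selected))
  invisible(x)
}

#' @export
summary.meta_pool <- function(object, ...) {
  p <- object$pooled
  eff <- object$effects
  eff$or <- exp(eff$log_or)
  eff$weight <- p$weights[eff$study_id]
  structure(list(model = object$model, effects = eff, pooled = p,
                 het = object$het, selected = object$selected),
            class = "summary.meta_pool")
}

#' @export
print.summary.meta_pool <- function(x, ...) {
  cat(sprintf("Per-study effects (%s model):\n", x$model))
  print(x$effects[, c("study_id", "or", "se", "weight")], digits = 4)
  cat("\n")
  print(x$pooled)
  invisible(x)
}

#' @export
coef.meta_pool <- function(object, ...) {
  stats::setNames(object$pooled$pooled_log_or, "pooled_log_or")
}

#' @export
coef.pooled_result <- function(object, ...) {
  stats::setNames(object$pooled_log_or, "pooled_log_or")
}

#' Confidence interval of a pooled result (odds-ratio scale)
#' @param object A `meta_pool` or `pooled_result`.
#' @param ... Ignored.
#' @export
confint.meta_pool <- function(object, ...) confint(object$pooled, ...)

#' @export
confint.pooled_result <- function(object, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("or", c("2.5 %", "97.5 %")))
}

#' @export
weights.meta_pool <- function(object, ...) object$pooled$weights

#' Forest plot of a meta-analysis fit
#'
#' Base-graphics forest plot: per-study ORs with 95% CIs, marker size
#' proportional to pooling weight, and the pooled estimate as a diamond.
#'
#' @param x A `meta_pool` object.
#' @param xlim Optional x-axis limits (OR scale, plotted on log axis).
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.meta_pool <- function(x, xlim = NULL, ...) {
  eff <- x$effects
  or <- exp(eff$log_or)
  lo <- exp(eff$log_or - Z95 * eff$se)
  hi <- exp(eff$log_or + Z95 * eff$se)
  p <- x$pooled
  k <- nrow(eff)
  if (is.null(xlim)) xlim <- range(c(lo, hi, p$ci_low, p$ci_high, 1))
  graphics::plot(NA, xlim = xlim, ylim = c(0, k + 1), log = "x",
                 xlab = "Odds ratio (log scale)", ylab = "",
                 yaxt = "n", main = sprintf("%s model", x$model), ...)
  graphics::axis(2, at = k:1, labels = eff$study_id, las = 1, cex.axis = 0.7)
  graphics::segments(lo, k:1, hi, k:1)
  graphics::points(or, k:1, pch = 15,
                   cex = 0.5 + 2 * sqrt(p$weights[eff$study_id]))
  graphics::abline(v = 1, lty = 3)
  graphics::polygon(c(p$ci_low, exp(p$pooled_log_or), p$ci_high,
                      exp(p$pooled_log_or)),
                    c(0, 0.25, 0, -0.25), col = "grey40", border = NA)
  invisible(x)
}
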