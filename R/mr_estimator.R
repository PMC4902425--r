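## Wald-ratio (single-instrument) Mendelian randomization with a
## delta-method standard error.

#' Gene-exposure association
#'
#' The per-T-allele effect of the instrument on the exposure, in SD units
#' of natural-log plasma total homocysteine per allele. The default 0.158
#' SD/allele is the value reported by the GWAS meta-analysis of tHcy
#' concentrations (44,147 individuals) on which the analysis rests; it is
#' treated as a supplied constant, so its standard error defaults to zero
#' but can be set for full delta-method propagation.
#'
#' @param beta Per-allele effect, SD ln-tHcy per T allele; must be nonzero
#'   to serve as an instrument.
#' @param se_beta Non-negative standard error of `beta`.
#' @return A list of class `gene_exposure`.
#' @export
gene_exposure <- function(beta = 0.158, se_beta = 0) {
  if (!is.finite(beta))
    stop_usage("gene-exposure beta must be finite")
  if (!is.finite(se_beta) || se_beta < 0)
    stop_usage("se_beta must be non-negative")
  structure(list(beta = beta, se_beta = se_beta), class = "gene_exposure")
}

#' @export
print.gene_exposure <- function(x, ...) {
  cat(sprintf("gene-exposure effect: %.4f SD ln-tHcy per T allele (SE %.4f)\n",
              x$beta, x$se_beta))
  invisible(x)
}

#' Standard error of a log odds ratio from its published 95% CI
#'
#' Reconstructs `se(log OR) = (ln(high) - ln(low)) / (2 * 1.96)` from an
#' odds-ratio confidence interval, for use when only published summary
#' results are available.
#'
#' @param or_low,or_high Positive CI bounds with `or_low < or_high`.
#' @return The implied standard error of the log odds ratio.
#' @examples
#' se_from_ci(1.06, 1.27)
#' @export
se_from_ci <- function(or_low, or_high) {
  if (!is.finite(or_low) || !is.finite(or_high) ||
      or_low <= 0 || or_high <= or_low)
    stop_usage("need 0 < or_low < or_high")
  (log(or_high) - log(or_low)) / (2 * Z95)
}

#' Effect estimate from a published odds ratio and CI
#'
#' @param or Point estimate (odds-ratio scale).
#' @param ci_low,ci_high 95% CI bounds.
#' @param model Genetic model label carried along (default `"allele"`).
#' @param study_id Label.
#' @return An `effect_estimate` suitable for [wald_ratio()] or pooling.
#' @export
published_effect <- function(or, ci_low, ci_high, model = "allele",
                             study_id = "published") {
  if (!is.finite(or) || or <= 0) stop_usage("or must be positive")
  structure(list(study_id = study_id, model = model,
                 log_or = log(or), se = se_from_ci(ci_low, ci_high),
                 corrected = FALSE, estimable = TRUE),
            class = "effect_estimate")
}

extract_gene_disease <- function(x) {
  if (inherits(x, "meta_pool")) x <- x$pooled
  if (inherits(x, "pooled_result"))
    return(list(log_or = x$pooled_log_or, se = x$se, model = x$model))
  if (inherits(x, "effect_estimate") ||
      (is.list(x) && all(c("log_or", "se") %in% names(x))))
    return(list(log_or = x$log_or, se = x$se,
                model = if (is.null(x$model)) NA_character_ else x$model))
  stop_usage("gene_disease must be a pooled result or an effect estimate")
}

#' Wald-ratio Mendelian-randomization estimate
#'
#' Divides the gene-disease log odds ratio (per T allele) by the
#' gene-exposure effect (SD ln-tHcy per T allele) to obtain the causal
#' log odds ratio of disease per SD increase in ln-tHcy:
#' `log OR_per_SD = log OR_per_allele / beta`.
#'
#' Two delta-method standard errors are available:
#' \describe{
#'   \item{simplified}{`se / |beta|` — first-order propagation treating
#'     `beta` as a known constant (the default; appropriate when the
#'     gene-exposure effect comes from a much larger sample).}
#'   \item{full-delta}{`sqrt(se^2/beta^2 + log_or^2 * se_beta^2 / beta^4)`
#'     — also propagates the uncertainty in `beta`; recommended whenever a
#'     credible `se_beta` is available.}
#' }
#'
#' @param gene_disease The per-T-allele gene-disease association: a
#'   `meta_pool`/`pooled_result` from [pool_studies()] (the allele model),
#'   an `effect_estimate`, or any list with `log_or` and `se`.
#' @param exposure A [gene_exposure()] object (default: the 0.158
#'   SD/allele constant).
#' @param se_mode `"simplified"` or `"full-delta"`.
#' @param weak_floor Instruments with `|beta|` below this floor (default
#'   0.01 SD/allele) are flagged `weak_instrument`.
#' @return A list of class `mr_estimate`: `log_or_per_sd`, `se`,
#'   `or_per_sd`, OR-scale `ci_low`/`ci_high`, two-sided normal
#'   `p_value`, `se_mode`, `weak_instrument`, and the inputs.
#' @examples
#' gd <- published_effect(1.16, 1.06, 1.27)
#' wald_ratio(gd, gene_exposure(0.158))
#' @export
wald_ratio <- function(gene_disease, exposure = gene_exposure(),
                       se_mode = c("simplified", "full-delta"),
                       weak_floor = 0.01) {
  se_mode <- match.arg(se_mode)
  gd <- extract_gene_disease(gene_disease)
  if (!inherits(exposure, "gene_exposure"))
    exposure <- do.call(gene_exposure, as.list(exposure))
  beta <- exposure$beta
  if (beta == 0)
    stop_usage("instrument has no exposure effect (beta = 0)")
  if (!is.na(gd$model) && gd$model != "allele")
    warning("gene-disease estimate is not from the allele (per-T-allele) model",
            call. = FALSE)
  if (!is.finite(gd$log_or) || !is.finite(gd$se) || gd$se <= 0)
    stop_usage("gene_disease needs finite log_or and positive se")
  point <- gd$log_or / beta
  se <- switch(se_mode,
    simplified = gd$se / abs(beta),
    `full-delta` = sqrt(gd$se^2 / beta^2 +
                          gd$log_or^2 * exposure$se_beta^2 / beta^4))
  structure(list(
    log_or_per_sd = point, se = se, or_per_sd = exp(point),
    ci_low = exp(point - Z95 * se), ci_high = exp(point + Z95 * se),
    p_value = 2 * stats::pnorm(-abs(point / se)),
    se_mode = se_mode,
    weak_instrument = abs(beta) < weak_floor,
    beta = beta, se_beta = exposure$se_beta,
    gene_log_or = gd$log_or, gene_se = gd$se
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("Wald-ratio Mendelian-randomization estimate\n")
  cat(sprintf("  OR per SD ln-tHcy: %.4f  95%% CI [%.4f, %.4f]  p = %.4g\n",
              x$or_per_sd, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  log OR %.4f (SE %.4f, %s delta method)\n",
              x$log_or_per_sd, x$se, x$se_mode))
  if (isTRUE(x$weak_instrument))
    cat("  WARNING: weak instrument (|beta| below floor)\n")
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$log_or_per_sd, "log_or_per_sd")
}

#' @export
confint.mr_estimate <- function(object, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("or_per_sd", c("2.5 %", "97.5 %")))
}
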