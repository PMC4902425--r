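## End-to-end orchestration: read -> HWE screen -> per-model contrasts and
## pooling -> subgroups -> sensitivity analyses -> bias tests -> MR.

log_stage <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full two-stage analysis pipeline
#'
#' Executes, in order: study-table validation; the Hardy-Weinberg screen
#' of each study's controls; for every requested genetic model the
#' per-study odds ratios, heterogeneity assessment, fixed-effect and
#' DerSimonian-Laird random-effects pooling with the heterogeneity-driven
#' model choice, subgroup analyses by ethnicity and source of controls,
#' leave-one-out and HWE-exclusion sensitivity analyses, and the Begg and
#' Egger publication-bias tests; finally the Wald-ratio MR estimate of
#' disease risk per SD ln-tHcy from the allele-model pooled odds ratio.
#'
#' Stages that are undefined for the input degenerate gracefully with a
#' warning rather than aborting: bias tests need at least three studies,
#' leave-one-out at least two, and the HWE-exclusion analysis at least
#' one study in equilibrium.
#'
#' @param input Path to a study table (read with [read_studies()]) or a
#'   study data frame.
#' @param models Genetic models to run (default: all five).
#' @param p_threshold,i2_threshold Heterogeneity thresholds for
#'   [select_model()].
#' @param hwe_alpha Significance level of the HWE screen.
#' @param exposure A [gene_exposure()] for the MR stage, or `NULL` to
#'   skip MR.
#' @param se_mode Delta-method mode for [wald_ratio()].
#' @param correction Continuity-correction switch.
#' @param verbose Log each stage to standard error.
#' @return An object of class `gc_analysis`: `studies` (with `hwe_p`),
#'   `hwe` (screen summary), `models` (per genetic model: `pooled`
#'   [meta_pool], `bias` (egger/begg), `subgroups`, `leave_one_out`,
#'   `hwe_exclusion`), `mr` (an `mr_estimate` from the allele model,
#'   or `NULL`), and the configuration used.
#' @examples
#' studies <- simulate_studies(sim_config(k = 8, seed = 3))
#' fit <- run_pipeline(studies, models = "allele")
#' print(fit)
#' @export
run_pipeline <- function(input,
                         models = GENETIC_MODELS,
                         p_threshold = 0.1, i2_threshold = 50,
                         hwe_alpha = 0.05,
                         exposure = gene_exposure(),
                         se_mode = c("simplified", "full-delta"),
                         correction = TRUE,
                         verbose = FALSE) {
  se_mode <- match.arg(se_mode)
  if (!length(models) || !all(models %in% GENETIC_MODELS))
    stop_usage("models must be drawn from: ",
               paste(GENETIC_MODELS, collapse = ", "))
  if (hwe_alpha <= 0 || hwe_alpha >= 1)
    stop_usage("hwe_alpha must be in (0, 1)")

  studies <- if (is.character(input)) {
    log_stage(verbose, "read", "reading %s", input)
    read_studies(input)
  } else validate_studies(input)
  log_stage(verbose, "read", "%d studies", nrow(studies))

  studies <- add_hwe(studies)
  n_dev <- sum(studies$hwe_p < hwe_alpha)
  log_stage(verbose, "hwe", "%d of %d studies out of HWE at alpha = %g",
            n_dev, nrow(studies), hwe_alpha)
  hwe_summary <- list(alpha = hwe_alpha, n_deviating = n_dev,
                      deviating = studies$study_id[studies$hwe_p < hwe_alpha])

  k <- nrow(studies)
  model_blocks <- lapply(models, function(m) {
    log_stage(verbose, "pool", "%s model", m)
    fit <- pool_studies(studies, model = m, correction = correction,
                        p_threshold = p_threshold,
                        i2_threshold = i2_threshold)
    bias <- if (nrow(fit$effects) >= 3L) {
      list(egger = egger_test(fit$effects), begg = begg_test(fit$effects))
    } else {
      warning("fewer than 3 studies: bias tests skipped for the ",
              m, " model", call. = FALSE)
      list(egger = NULL, begg = NULL)
    }
    subgroups <- list(
      ethnicity = subgroup_analysis(studies, model = m, by = "ethnicity",
                                    correction = correction,
                                    p_threshold = p_threshold,
                                    i2_threshold = i2_threshold),
      control_source = subgroup_analysis(studies, model = m,
                                         by = "control_source",
                                         correction = correction,
                                         p_threshold = p_threshold,
                                         i2_threshold = i2_threshold))
    loo <- if (k >= 2L)
      leave_one_out(studies, model = m, correction = correction,
                    p_threshold = p_threshold, i2_threshold = i2_threshold)
    else {
      warning("single study: leave-one-out skipped", call. = FALSE)
      NULL
    }
    hwe_ex <- if (any(studies$hwe_p >= hwe_alpha))
      hwe_exclusion(studies, model = m, alpha = hwe_alpha,
                    correction = correction, p_threshold = p_threshold,
                    i2_threshold = i2_threshold)
    else {
      warning("all studies out of HWE: exclusion analysis skipped",
              call. = FALSE)
      NULL
    }
    list(pooled = fit, bias = bias, subgroups = subgroups,
         leave_one_out = loo, hwe_exclusion = hwe_ex, funnel =
           funnel_data(fit$effects))
  })
  names(model_blocks) <- models

  mr <- NULL
  if (!is.null(exposure) && "allele" %in% models) {
    log_stage(verbose, "mr", "Wald ratio from allele-model pooled OR")
    mr <- wald_ratio(model_blocks[["allele"]]$pooled, exposure,
                     se_mode = se_mode)
  }

  structure(list(studies = studies, hwe = hwe_summary,
                 models = model_blocks, mr = mr,
                 config = list(models = models, p_threshold = p_threshold,
                               i2_threshold = i2_threshold,
                               hwe_alpha = hwe_alpha, se_mode = se_mode,
                               correction = correction)),
            class = "gc_analysis")
}

#' Wald-ratio MR from a published pooled odds ratio
#'
#' Convenience wrapper for the published-summary input mode: the
#' gene-disease association is supplied as an odds ratio with its 95% CI
#' rather than as genotype counts.
#'
#' @param or,ci_low,ci_high Published per-T-allele pooled OR and CI.
#' @param beta,se_beta Gene-exposure effect (SD ln-tHcy per allele).
#' @param se_mode Passed to [wald_ratio()].
#' @return An `mr_estimate`.
#' @examples
#' mr_from_published(1.16, 1.06, 1.27, beta = 0.158)
#' @export
mr_from_published <- function(or, ci_low, ci_high, beta = 0.158,
                              se_beta = 0,
                              se_mode = c("simplified", "full-delta")) {
  wald_ratio(published_effect(or, ci_low, ci_high),
             gene_exposure(beta, se_beta), se_mode = match.arg(se_mode))
}

#' @export
print.gc_analysis <- function(x, ...) {
  cat(sprintf("Two-stage genotype meta-analysis + MR (%d studies)\n",
              nrow(x$studies)))
  cat(sprintf("HWE screen: %d studies deviating at alpha = %g\n",
              x$hwe$n_deviating, x$hwe$alpha))
  cat("\nPooled odds ratios:\n")
  tab <- model_summary_table(x)
  print(tab, digits = 4, row.names = FALSE)
  for (m in names(x$models)) {
    b <- x$models[[m]]$bias
    if (!is.null(b$egger))
      cat(sprintf("%s model bias: Egger t = %.2f (p = %.3g), Begg z = %.2f (p = %.3g)\n",
                  m, b$egger$statistic, b$egger$p_value,
                  b$begg$statistic, b$begg$p_value))
  }
  if (!is.null(x$mr)) {
    cat("\n")
    print(x$mr)
  }
  invisible(x)
}

#' @export
summary.gc_analysis <- function(object, ...) {
  structure(list(table = model_summary_table(object),
                 hwe = object$hwe, mr = object$mr,
                 n = nrow(object$studies)),
            class = "summary.gc_analysis")
}

#' @export
print.summary.gc_analysis <- function(x, ...) {
  cat(sprintf("%d studies; %d deviating from HWE\n", x$n,
              x$hwe$n_deviating))
  print(x$table, digits = 4, row.names = FALSE)
  if (!is.null(x$mr)) print(x$mr)
  invisible(x)
}

#' Forest-plot table for one genetic model of an analysis
#'
#' Per-study OR, CI and normalized pooling weight plus a pooled row,
#' suitable for export to any plotting layer.
#'
#' @param bundle A `gc_analysis`.
#' @param model Genetic model name.
#' @return Data frame with columns `study_id`, `or`, `ci_low`, `ci_high`,
#'   `weight`; the final row is the pooled estimate.
#' @export
forest_table <- function(bundle, model = "allele") {
  if (!model %in% names(bundle$models))
    stop_usage("model ", model, " was not run in this analysis")
  fit <- bundle$models[[model]]$pooled
  eff <- fit$effects
  p <- fit$pooled
  rbind(
    data.frame(study_id = eff$study_id, or = exp(eff$log_or),
               ci_low = exp(eff$log_or - Z95 * eff$se),
               ci_high = exp(eff$log_or + Z95 * eff$se),
               weight = unname(p$weights[eff$study_id]),
               stringsAsFactors = FALSE),
    data.frame(study_id = sprintf("pooled (%s)", p$effects_model),
               or = exp(p$pooled_log_or), ci_low = p$ci_low,
               ci_high = p$ci_high, weight = 1,
               stringsAsFactors = FALSE))
}
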