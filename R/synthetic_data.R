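## Seeded generator of case-control genotype studies with known truth.
## Every pipeline stage is testable against this generator without any
## external data.

#' Configuration for the synthetic-study generator
#'
#' Defines the conditions under which [simulate_studies()] draws a
#' collection of case-control genotype studies. Defaults emulate a
#' moderately heterogeneous literature on a common biallelic variant:
#' per-allele odds ratio 1.16, between-study SD of the log OR 0.15,
#' control T-allele frequencies 0.20-0.55, and study sizes of a few
#' hundred per arm.
#'
#' @param k Number of studies.
#' @param n_cases_range,n_controls_range Integer ranges (length-2) from
#'   which per-study arm sizes are drawn uniformly.
#' @param maf_range Range of the control-population T-allele frequency,
#'   inside (0, 1).
#' @param true_log_or True per-allele (multiplicative) log odds ratio.
#' @param tau Between-study SD of the per-study log OR (0 = homogeneous).
#' @param hwe_violation_fraction Fraction of studies whose control
#'   genotype frequencies are distorted away from Hardy-Weinberg
#'   proportions; the violating studies are chosen by a deterministic
#'   rule on the study index, so the set is stable when `k` grows.
#' @param inbreeding_f Inbreeding coefficient F applied to the control
#'   genotype frequencies of violating studies
#'   (`f_TT = q^2 + F q(1-q)`, `f_CT = 2q(1-q)(1-F)`).
#' @param small_study_bias If `TRUE`, small studies (case arm below the
#'   midpoint of `n_cases_range`) are redrawn until their observed allele
#'   log OR is at least the true value, emulating suppression of small
#'   null/negative studies.
#' @param true_beta,true_se_beta Gene-exposure truth for
#'   [simulate_gene_exposure()]: per-allele effect on SD ln-tHcy and its
#'   sampling SD.
#' @param ethnicity_probs,control_source_probs Named probability vectors
#'   from which each study's stratum labels are drawn.
#' @param seed Root seed; each study uses an index-derived substream, so
#'   increasing `k` appends studies without reshuffling earlier ones.
#' @return A validated list of class `sim_config`.
#' @seealso [mthfr_gc_config()] for the 27-study configuration emulating
#'   the published MTHFR C677T gastric-cancer literature.
#' @export
sim_config <- function(k = 27L,
                       n_cases_range = c(50L, 420L),
                       n_controls_range = c(60L, 550L),
                       maf_range = c(0.20, 0.55),
                       true_log_or = log(1.16),
                       tau = 0.15,
                       hwe_violation_fraction = 0,
                       inbreeding_f = 0.2,
                       small_study_bias = FALSE,
                       true_beta = 0.158,
                       true_se_beta = 0,
                       ethnicity_probs = c(Asian = 0.6, Caucasian = 0.3,
                                           Mixed = 0.1),
                       control_source_probs = c(population = 0.5,
                                                hospital = 0.5),
                       seed = 1L) {
  cfg <- list(k = as.integer(k),
              n_cases_range = as.integer(n_cases_range),
              n_controls_range = as.integer(n_controls_range),
              maf_range = maf_range, true_log_or = true_log_or,
              tau = tau, hwe_violation_fraction = hwe_violation_fraction,
              inbreeding_f = inbreeding_f,
              small_study_bias = isTRUE(small_study_bias),
              true_beta = true_beta, true_se_beta = true_se_beta,
              ethnicity_probs = ethnicity_probs,
              control_source_probs = control_source_probs,
              seed = as.integer(seed))
  if (cfg$k < 1L) stop_usage("k must be at least 1")
  for (r in list(cfg$n_cases_range, cfg$n_controls_range))
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2])
      stop_usage("sample-size ranges must be increasing pairs of positive integers")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] >= 1 || cfg$maf_range[1] > cfg$maf_range[2])
    stop_usage("maf_range must lie inside (0, 1)")
  if (cfg$tau < 0) stop_usage("tau must be non-negative")
  if (cfg$hwe_violation_fraction < 0 || cfg$hwe_violation_fraction > 1)
    stop_usage("hwe_violation_fraction must be in [0, 1]")
  if (cfg$inbreeding_f < 0 || cfg$inbreeding_f >= 1)
    stop_usage("inbreeding_f must be in [0, 1)")
  if (cfg$true_se_beta < 0) stop_usage("true_se_beta must be non-negative")
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-8 ||
      abs(sum(cfg$control_source_probs) - 1) > 1e-8)
    stop_usage("stratum probabilities must sum to 1")
  structure(cfg, class = "sim_config")
}

#' Configuration emulating the published MTHFR C677T gastric-cancer
#' literature
#'
#' Twenty-seven case-control studies with a true per-allele odds ratio of
#' 1.16, moderate between-study heterogeneity (tau = 0.15), arm sizes
#' matching the literature's totals (roughly 230 cases and 300 controls
#' per study on average), a mixed ethnicity composition dominated by
#' Asian studies, and 7 of the 27 studies with controls out of
#' Hardy-Weinberg equilibrium (inbreeding F = 0.2).
#'
#' @param seed Root seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
mthfr_gc_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(k = 27L, hwe_violation_fraction = 7 / 27, seed = as.integer(seed)),
    list(...))
  do.call(sim_config, args)
}

## substream seed for study i (kept below 2^31 - 1; double arithmetic to
## avoid integer overflow for large indices)
study_seed <- function(root, i) {
  as.integer((abs(as.numeric(root)) + as.numeric(i) * 100003) %% 2147483647)
}

## deterministic, prefix-stable assignment of HWE-violating studies:
## study i violates iff floor(i*f) > floor((i-1)*f), giving floor(k*f)
## violators among the first k studies
violates_hwe <- function(i, fraction) {
  floor(i * fraction) > floor((i - 1) * fraction)
}

hwe_probs <- function(q, f = 0) {
  ## q = T-allele frequency; order (CC, CT, TT)
  c((1 - q)^2 + f * q * (1 - q),
    2 * q * (1 - q) * (1 - f),
    q^2 + f * q * (1 - q))
}

## case genotype probabilities under the multiplicative per-allele odds
## model: weight HWE(q) by exp(delta * g), g = T-allele count
case_probs <- function(q, delta) {
  w <- hwe_probs(q) * exp(delta * 0:2)
  w / sum(w)
}

draw_study <- function(cfg, i) {
  set.seed(study_seed(cfg$seed, i))
  eth <- sample(names(cfg$ethnicity_probs), 1, prob = cfg$ethnicity_probs)
  src <- sample(names(cfg$control_source_probs), 1,
                prob = cfg$control_source_probs)
  year <- sample(1998:2015, 1)
  q <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
  delta <- cfg$true_log_or +
    if (cfg$tau > 0) stats::rnorm(1, 0, cfg$tau) else 0
  n_ca <- sample(cfg$n_cases_range[1]:cfg$n_cases_range[2], 1)
  n_co <- sample(cfg$n_controls_range[1]:cfg$n_controls_range[2], 1)
  f <- if (violates_hwe(i, cfg$hwe_violation_fraction)) cfg$inbreeding_f else 0
  p_ctrl <- hwe_probs(q, f)
  p_case <- case_probs(q, delta)

  draw_counts <- function() {
    list(case = as.integer(stats::rmultinom(1, n_ca, p_case)),
         ctrl = as.integer(stats::rmultinom(1, n_co, p_ctrl)))
  }
  cnt <- draw_counts()
  if (cfg$small_study_bias &&
      n_ca < mean(cfg$n_cases_range)) {
    ## censor small studies whose observed allele log OR falls below the
    ## true value: redraw, emulating selective publication
    for (try in seq_len(200L)) {
      tab <- genetic_contrast(cnt$case, cnt$ctrl, "allele")
      est <- suppressWarnings(odds_ratio(tab, correction = TRUE))
      if (est$estimable && est$log_or >= cfg$true_log_or) break
      cnt <- draw_counts()
    }
  }
  data.frame(study_id = sprintf("S%02d", i), year = year,
             ethnicity = eth, control_source = src,
             case_cc = cnt$case[1], case_ct = cnt$case[2],
             case_tt = cnt$case[3],
             ctrl_cc = cnt$ctrl[1], ctrl_ct = cnt$ctrl[2],
             ctrl_tt = cnt$ctrl[3],
             true_log_or = delta, maf = q,
             hwe_violating = f > 0,
             stringsAsFactors = FALSE)
}

#' Simulate a collection of case-control genotype studies
#'
#' Per study: a control T-allele frequency `q` is drawn uniformly from
#' `maf_range` and a study-specific per-allele log OR
#' `delta_i = true_log_or + N(0, tau)`. Control genotype probabilities
#' follow Hardy-Weinberg proportions in `q` (distorted by the inbreeding
#' coefficient for the violating studies); case genotype probabilities
#' weight the control proportions by `exp(delta_i * g)` (g = T-allele
#' count) and renormalize — the multiplicative per-allele odds model.
#' Genotype counts are multinomial at the drawn arm sizes. The generator
#' is deterministic given the root seed, and each study is drawn from an
#' index-derived substream, so increasing `k` appends studies without
#' changing earlier ones.
#'
#' @param config A [sim_config()].
#' @return A validated study data frame with the standard columns plus
#'   the generator truth: `true_log_or` (the study's delta), `maf`,
#'   `hwe_violating`.
#' @examples
#' studies <- simulate_studies(sim_config(k = 5, seed = 7))
#' studies$study_id
#' @export
simulate_studies <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_usage("config must come from sim_config()")
  rows <- lapply(seq_len(config$k), function(i) draw_study(config, i))
  validate_studies(do.call(rbind, rows))
}

#' Simulate the gene-exposure summary statistic
#'
#' Draws the per-allele effect on SD ln-tHcy as
#' `Normal(true_beta, true_se_beta)` (exactly `true_beta` when
#' `true_se_beta = 0`), deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [gene_exposure()] with the drawn `beta` and
#'   `se_beta = true_se_beta`.
#' @export
simulate_gene_exposure <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_usage("config must come from sim_config()")
  set.seed(study_seed(config$seed, 999983L))
  beta <- if (config$true_se_beta > 0)
    stats::rnorm(1, config$true_beta, config$true_se_beta)
  else config$true_beta
  gene_exposure(beta = beta, se_beta = config$true_se_beta)
}
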