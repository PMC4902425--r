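## Per-study effect sizes under the five genetic-model contrasts, and the
## Hardy-Weinberg screen of control genotypes.

#' Collapse genotype counts into a 2x2 table under a genetic model
#'
#' Builds the 2x2 exposure table for one study under one of the five
#' genetic-model contrasts. `a`/`b` are exposed/unexposed cases, `c`/`d`
#' exposed/unexposed controls:
#' \describe{
#'   \item{allele}{T alleles vs C alleles; each person contributes two
#'     alleles, so cell counts are allele counts.}
#'   \item{homozygous}{TT vs CC, CT carriers excluded.}
#'   \item{heterozygous}{CT vs CC, TT carriers excluded.}
#'   \item{dominant}{TT+CT vs CC.}
#'   \item{recessive}{TT vs CT+CC.}
#' }
#'
#' @param cases,controls [genotype_counts()] objects (or length-3 CC/CT/TT
#'   vectors) for the two arms.
#' @param model One of `r paste(GENETIC_MODELS, collapse = ", ")`.
#' @return A list of class `two_by_two` with elements `a`, `b`, `c`, `d`
#'   and `model`.
#' @examples
#' genetic_contrast(c(10, 20, 10), c(20, 20, 10), "allele")
#' @export
genetic_contrast <- function(cases, controls, model) {
  if (length(model) != 1L || !model %in% GENETIC_MODELS)
    stop_usage("unknown genetic model: ", paste(model, collapse = ", "),
               " (expected one of ", paste(GENETIC_MODELS, collapse = ", "), ")")
  ca <- as_genotype_counts(cases)
  co <- as_genotype_counts(controls)
  cell <- switch(model,
    allele = {
      aca <- allele_counts(ca); aco <- allele_counts(co)
      c(aca[["T"]], aca[["C"]], aco[["T"]], aco[["C"]])
    },
    homozygous = c(ca[["tt"]], ca[["cc"]], co[["tt"]], co[["cc"]]),
    heterozygous = c(ca[["ct"]], ca[["cc"]], co[["ct"]], co[["cc"]]),
    dominant = c(ca[["tt"]] + ca[["ct"]], ca[["cc"]],
                 co[["tt"]] + co[["ct"]], co[["cc"]]),
    recessive = c(ca[["tt"]], ca[["ct"]] + ca[["cc"]],
                  co[["tt"]], co[["ct"]] + co[["cc"]])
  )
  structure(list(a = cell[1], b = cell[2], c = cell[3], d = cell[4],
                 model = model),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 table (%s model)\n", x$model))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' Computes the log odds ratio `ln(ad/bc)` and its large-sample standard
#' error `sqrt(1/a + 1/b + 1/c + 1/d)`. With `correction = TRUE` the
#' Haldane-Anscombe rule is applied: if any cell is zero, 0.5 is added to
#' all four cells before computing. A table with an entire row or column
#' zero (and correction disabled, or the table degenerate) is returned
#' with `estimable = FALSE` and a warning; pooling functions drop such
#' studies.
#'
#' @param tab A `two_by_two` from [genetic_contrast()], or a length-4
#'   vector `(a, b, c, d)`.
#' @param correction Apply the half-unit continuity correction when a zero
#'   cell is present (default `TRUE`).
#' @param study_id Optional label carried into the result.
#' @return A list of class `effect_estimate`: `study_id`, `model`,
#'   `log_or`, `se`, `corrected`, `estimable`.
#' @examples
#' odds_ratio(c(20, 10, 10, 20))   # OR = 4
#' @export
odds_ratio <- function(tab, correction = TRUE, study_id = NA_character_) {
  if (is.numeric(tab) && length(tab) == 4L)
    tab <- structure(list(a = tab[1], b = tab[2], c = tab[3], d = tab[4],
                          model = NA_character_), class = "two_by_two")
  if (!inherits(tab, "two_by_two"))
    stop_usage("odds_ratio expects a two_by_two table")
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells < 0)) stop_usage("negative cell count")
  corrected <- FALSE
  if (any(cells == 0) && correction) {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  est <- structure(list(study_id = study_id, model = tab$model,
                        log_or = NA_real_, se = NA_real_,
                        corrected = corrected, estimable = FALSE),
                   class = "effect_estimate")
  ## a row (cases/controls) or a column (exposed/unexposed) that is wholly
  ## zero carries no information about the odds ratio
  if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0 ||
      cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0 ||
      any(cells == 0)) {
    warning(sprintf("study %s: odds ratio not estimable under the %s model",
                    study_id, tab$model), call. = FALSE)
    return(est)
  }
  est$log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  est$se <- sqrt(sum(1 / cells))
  est$estimable <- TRUE
  est
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("effect estimate [%s, %s]: not estimable\n",
                x$study_id, x$model))
  } else {
    cat(sprintf(
      "effect estimate [%s, %s]: OR = %.4f (log OR %.4f, SE %.4f)%s\n",
      x$study_id, x$model, exp(x$log_or), x$log_or, x$se,
      if (x$corrected) ", continuity-corrected" else ""))
  }
  invisible(x)
}

#' Per-study effect estimates for a study collection
#'
#' Applies [genetic_contrast()] and [odds_ratio()] to every study in a
#' table and returns one row per study.
#'
#' @param studies A validated study data frame.
#' @param model Genetic model name.
#' @param correction Continuity-correction switch passed to [odds_ratio()].
#' @return Data frame with columns `study_id`, `model`, `log_or`, `se`,
#'   `corrected`, `estimable`. Non-estimable studies are retained here
#'   (flagged) and dropped, with a warning, by the pooling functions.
#' @export
study_effects <- function(studies, model = "allele", correction = TRUE) {
  studies <- validate_studies(studies)
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    tab <- genetic_contrast(case_counts(s), control_counts(s), model)
    e <- odds_ratio(tab, correction = correction, study_id = s$study_id)
    data.frame(study_id = e$study_id, model = model, log_or = e$log_or,
               se = e$se, corrected = e$corrected, estimable = e$estimable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Hardy-Weinberg --------------------------------------------------------------

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square goodness-of-fit test (1 df) of control genotype
#' counts against the Hardy-Weinberg proportions `p^2 : 2p(1-p) : (1-p)^2`
#' implied by the observed allele frequency. Monomorphic samples
#' (allele frequency 0 or 1) return probability 1 by convention, with a
#' message.
#'
#' @param controls [genotype_counts()] for the control arm (or a CC/CT/TT
#'   vector).
#' @return The upper-tail probability of the chi-square statistic.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: P = 1
#' @export
hwe_test <- function(controls) {
  g <- as_genotype_counts(controls)
  n <- sum(g)
  if (n < 1) stop_usage("control arm is empty")
  p <- (2 * g[["cc"]] + g[["ct"]]) / (2 * n)  # C-allele frequency
  if (p == 0 || p == 1) {
    message("monomorphic controls: HWE probability 1 by convention")
    return(1)
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((as.numeric(g) - expected)^2 / expected)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Stamp each study with its control-group HWE probability
#'
#' @param studies A study data frame.
#' @return The same table with an `hwe_p` column appended (recomputed if
#'   already present).
#' @export
add_hwe <- function(studies) {
  studies <- validate_studies(studies)
  studies$hwe_p <- vapply(seq_len(nrow(studies)), function(i)
    hwe_test(control_counts(studies[i, ])), numeric(1))
  studies
}
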