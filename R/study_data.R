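#' @keywords internal
"_PACKAGE"

## Canonical vocabulary -------------------------------------------------------

#' Genetic-model contrasts
#'
#' The five standard contrasts collapsing the 3x2 genotype table of a
#' biallelic SNP (here MTHFR C677T, alleles C and T) into a 2x2 table:
#' allele (T vs C), homozygous (TT vs CC), heterozygous (CT vs CC),
#' dominant (TT+CT vs CC) and recessive (TT vs CT+CC).
#'
#' @format Character vector of length five.
#' @export
GENETIC_MODELS <- c("allele", "homozygous", "heterozygous",
                    "dominant", "recessive")

.STUDY_COLUMNS <- c("study_id", "year", "ethnicity", "control_source",
                    "case_cc", "case_ct", "case_tt",
                    "ctrl_cc", "ctrl_ct", "ctrl_tt")
.COUNT_COLUMNS <- .STUDY_COLUMNS[5:10]
.ETHNICITY_LEVELS <- c("Asian", "Caucasian", "Mixed")
.CONTROL_SOURCE_LEVELS <- c("population", "hospital")

## Conditions ------------------------------------------------------------------
## Distinct condition classes so callers (and the CLI) can map failures to
## schema / validation / usage / io exit codes.

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("hcymr_schema_error",
                                             "hcymr_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("hcymr_validation_error",
                                             "hcymr_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("hcymr_usage_error",
                                             "hcymr_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("hcymr_io_error",
                                             "hcymr_error", "error")))
}

## Genotype counts -------------------------------------------------------------

#' Genotype counts for one study arm
#'
#' Bundles the three genotype counts of a biallelic SNP for one arm
#' (cases or controls) of a case-control study.
#'
#' @param cc,ct,tt Non-negative integer counts of CC, CT and TT carriers.
#' @return An object of class `genotype_counts`: a named integer vector
#'   with elements `cc`, `ct`, `tt`.
#' @examples
#' g <- genotype_counts(10, 20, 10)
#' allele_counts(g)  # C = 2*10 + 20, T = 2*10 + 20
#' @export
genotype_counts <- function(cc, ct, tt) {
  x <- c(cc = cc, ct = ct, tt = tt)
  if (any(!is.finite(x)) || any(x < 0))
    stop_validation("genotype counts must be finite and non-negative")
  if (any(abs(x - round(x)) > 1e-8))
    stop_validation("genotype counts must be whole numbers")
  structure(as.integer(round(x)), names = c("cc", "ct", "tt"),
            class = "genotype_counts")
}

#' Allele counts implied by genotype counts
#'
#' @param g A [genotype_counts()] object or a length-3 vector (CC, CT, TT).
#' @return Named numeric vector with elements `C = 2*cc + ct` and
#'   `T = 2*tt + ct`; the two always sum to twice the genotype total.
#' @export
allele_counts <- function(g) {
  g <- as_genotype_counts(g)
  c(C = 2 * g[["cc"]] + g[["ct"]], T = 2 * g[["tt"]] + g[["ct"]])
}

as_genotype_counts <- function(g) {
  if (inherits(g, "genotype_counts")) return(g)
  if (is.numeric(g) && length(g) == 3L)
    return(genotype_counts(g[[1L]], g[[2L]], g[[3L]]))
  stop_usage("expected genotype counts (CC, CT, TT)")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts: CC=%d CT=%d TT=%d (n=%d)\n",
              x[["cc"]], x[["ct"]], x[["tt"]], sum(x)))
  invisible(x)
}

## Study tables ----------------------------------------------------------------

normalize_stratum <- function(x, levels, fallback, what, ids) {
  x <- trimws(as.character(x))
  idx <- match(tolower(x), tolower(levels))
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning(sprintf("%d unrecognized %s label(s) (%s) mapped to \"%s\"",
                    sum(unknown),
                    what,
                    paste(unique(x[unknown]), collapse = ", "),
                    fallback), call. = FALSE)
    idx[unknown] <- match(fallback, levels)
  }
  levels[idx]
}

#' Validate a study-level genotype table
#'
#' Checks the column schema, count integrity and study-label uniqueness of
#' a study table, and normalizes the ethnicity and control-source strata to
#' the canonical labels (`Asian`/`Caucasian`/`Mixed`,
#' `population`/`hospital`; matching is case-insensitive and unknown labels
#' fall back to `Mixed`/`hospital` with a warning).
#'
#' @param studies A data frame with one row per case-control study and
#'   columns `study_id`, `year`, `ethnicity`, `control_source`,
#'   `case_cc`, `case_ct`, `case_tt`, `ctrl_cc`, `ctrl_ct`, `ctrl_tt`.
#' @return The validated, normalized data frame (canonical column order,
#'   integer counts).
#' @export
validate_studies <- function(studies) {
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  missing <- setdiff(.STUDY_COLUMNS, names(studies))
  if (length(missing))
    stop_schema("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(studies) == 0L)
    stop_validation("study table has no rows")

  studies$study_id <- as.character(studies$study_id)
  dup <- unique(studies$study_id[duplicated(studies$study_id)])
  if (length(dup))
    stop_validation("duplicate study_id: ", paste(dup, collapse = ", "))

  for (col in .COUNT_COLUMNS) {
    v <- studies[[col]]
    if (!is.numeric(v))
      v <- suppressWarnings(as.numeric(v))
    bad <- !is.finite(v) | v < 0 | abs(v - round(v)) > 1e-8
    if (any(bad))
      stop_validation("invalid count in column ", col, " for study ",
                      paste(studies$study_id[bad], collapse = ", "),
                      " (counts must be non-negative integers)")
    studies[[col]] <- as.integer(round(v))
  }

  n_cases <- studies$case_cc + studies$case_ct + studies$case_tt
  n_ctrl  <- studies$ctrl_cc + studies$ctrl_ct + studies$ctrl_tt
  empty <- n_cases < 1L | n_ctrl < 1L
  if (any(empty))
    stop_validation("study ", paste(studies$study_id[empty], collapse = ", "),
                    " has an empty case or control arm")

  studies$year <- as.integer(studies$year)
  studies$ethnicity <- normalize_stratum(studies$ethnicity, .ETHNICITY_LEVELS,
                                         "Mixed", "ethnicity",
                                         studies$study_id)
  studies$control_source <- normalize_stratum(studies$control_source,
                                              .CONTROL_SOURCE_LEVELS,
                                              "hospital", "control-source",
                                              studies$study_id)
  keep <- c(.STUDY_COLUMNS, setdiff(names(studies), .STUDY_COLUMNS))
  studies[, keep, drop = FALSE]
}

infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a study-level genotype table
#'
#' Reads a delimited text file with one row per case-control study (six
#' genotype-count columns plus `study_id`, `year`, `ethnicity` and
#' `control_source`) and validates it with [validate_studies()].
#'
#' @param path Path to a TSV (default) or CSV file; the delimiter is taken
#'   from the extension unless `sep` is given. Lines starting with `#` are
#'   treated as comments.
#' @param sep Optional field delimiter overriding the extension-based guess.
#' @return A validated study data frame.
#' @seealso [write_studies()], [validate_studies()]
#' @export
read_studies <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop_io("input file not found: ", path)
  studies <- utils::read.table(path, header = TRUE,
                               sep = infer_sep(path, sep),
                               stringsAsFactors = FALSE,
                               comment.char = "#", quote = "\"",
                               check.names = TRUE)
  validate_studies(studies)
}

#' Write a study-level genotype table
#'
#' @param studies A study data frame (validated on the way out).
#' @param path Output path; `.csv` selects comma delimiting, anything else
#'   is tab-delimited.
#' @param sep Optional delimiter override.
#' @param comment Optional comment line(s) written as a `#` header.
#' @return Invisibly, the normalized table that was written.
#' @export
write_studies <- function(studies, path, sep = NULL, comment = NULL) {
  studies <- validate_studies(studies)
  sep <- infer_sep(path, sep)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_io("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(studies[, .STUDY_COLUMNS], con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(studies)
}

case_counts <- function(study) {
  genotype_counts(study$case_cc, study$case_ct, study$case_tt)
}

control_counts <- function(study) {
  genotype_counts(study$ctrl_cc, study$ctrl_ct, study$ctrl_tt)
}

## Reports ---------------------------------------------------------------------

pooled_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(model = p$model, k = p$k,
       or = exp(p$pooled_log_or),
       pooled_log_or = p$pooled_log_or, se = p$se,
       ci_low = p$ci_low, ci_high = p$ci_high, p_value = p$p_value,
       Q = p$Q, q_p = p$q_p, i_squared = p$i_squared,
       tau_squared = p$tau_squared, effects_model = p$effects_model)
}

meta_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  list(selected = m$selected,
       fixed = pooled_to_list(m$fixed),
       random = pooled_to_list(m$random),
       pooled = pooled_to_list(m$pooled))
}

bias_to_list <- function(b) {
  if (is.null(b)) return(NULL)
  out <- list(method = b$method, statistic = b$statistic,
              p_value = b$p_value, k = b$k)
  if (identical(b$method, "egger")) {
    out$intercept <- b$intercept
    out$intercept_se <- b$intercept_se
    out$slope <- b$slope
  } else {
    out$tau <- b$tau
  }
  out
}

mr_to_list <- function(mr) {
  if (is.null(mr)) return(NULL)
  list(log_or_per_sd = mr$log_or_per_sd, se = mr$se,
       or_per_sd = mr$or_per_sd, ci_low = mr$ci_low, ci_high = mr$ci_high,
       p_value = mr$p_value, se_mode = mr$se_mode,
       weak_instrument = mr$weak_instrument,
       beta = mr$beta, se_beta = mr$se_beta)
}

model_block_to_list <- function(blk) {
  list(
    pooled = meta_to_list(blk$pooled),
    bias = list(egger = bias_to_list(blk$bias$egger),
                begg = bias_to_list(blk$bias$begg)),
    subgroups = lapply(blk$subgroups, function(by)
      lapply(by, function(m) meta_to_list(m))),
    leave_one_out = if (is.null(blk$leave_one_out)) NULL else
      as.list(blk$leave_one_out),
    hwe_exclusion = meta_to_list(blk$hwe_exclusion)
  )
}

#' Write a machine-readable analysis report
#'
#' Serializes a full analysis bundle (the result of [run_pipeline()]) to a
#' JSON document and, optionally, a flat per-model TSV. Numbers are written
#' with 10 significant digits so a parse round-trip is faithful well beyond
#' 6 significant digits.
#'
#' @param bundle A `gc_analysis` object from [run_pipeline()], which must
#'   contain at least one pooled result.
#' @param path Output path for the JSON report.
#' @param tsv_path Optional output path for the per-model summary TSV.
#' @return Invisibly, the report list that was serialized.
#' @export
write_report <- function(bundle, path, tsv_path = NULL) {
  if (!inherits(bundle, "gc_analysis"))
    stop_usage("write_report expects a gc_analysis bundle from run_pipeline()")
  if (!length(bundle$models))
    stop_usage("analysis bundle contains no pooled results")
  rep <- list(
    generated_by = "hcymr",
    n_studies = nrow(bundle$studies),
    hwe = as.list(bundle$hwe),
    models = lapply(bundle$models, model_block_to_list),
    mr = mr_to_list(bundle$mr)
  )
  ok <- tryCatch({
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 10,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_io("cannot write report to ", path, ": ", conditionMessage(ok))
  if (!is.null(tsv_path)) {
    tab <- model_summary_table(bundle)
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(rep)
}

#' Per-model summary table of an analysis bundle
#'
#' @param bundle A `gc_analysis` object.
#' @return Data frame with one row per genetic model: pooled OR, 95% CI,
#'   p-value, Q, Q p-value, I-squared, tau-squared and the effects model
#'   the heterogeneity rule selected.
#' @export
model_summary_table <- function(bundle) {
  rows <- lapply(names(bundle$models), function(m) {
    p <- bundle$models[[m]]$pooled$pooled
    data.frame(model = m, k = p$k, or = exp(p$pooled_log_or),
               ci_low = p$ci_low, ci_high = p$ci_high,
               p_value = p$p_value, Q = p$Q, q_p = p$q_p,
               i_squared = p$i_squared, tau_squared = p$tau_squared,
               effects_model = p$effects_model,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read back a JSON analysis report
#'
#' Convenience parser for documents produced by [write_report()].
#'
#' @param path Path to the JSON report.
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io("report not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
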