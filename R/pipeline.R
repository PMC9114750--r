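# Full stratified analysis: all five genetic-model contrasts across the
# subgroup taxonomy, report rendering, and forest-data export.

default_config <- function() {
  list(hwe_threshold = 0.05, alpha_het = 0.05, correction = 0.5,
       level = 0.95, fixed_estimator = "MH", min_k = 1, seed = NA)
}

# Subgroup definitions for a roster: list of (axis, level, records).
subgroup_rows <- function(studies, hwe_threshold) {
  rows <- list(
    list(axis = "total", level = NA_character_, records = studies),
    list(axis = "hwe_subset", level = NA_character_,
         records = filter_subgroup(studies, "hwe_subset",
                                   hwe_threshold = hwe_threshold))
  )
  for (grp in names(groups <- group_cancer_types(studies)))
    rows[[length(rows) + 1]] <- list(axis = "cancer_type", level = grp,
                                     records = groups[[grp]])
  for (sys in sort(unique(stats::na.omit(studies$system))))
    rows[[length(rows) + 1]] <- list(axis = "system", level = sys,
                                     records = filter_subgroup(studies,
                                                               "system", sys))
  for (eth in ETHNICITIES[ETHNICITIES %in% studies$ethnicity])
    rows[[length(rows) + 1]] <- list(axis = "ethnicity", level = eth,
                                     records = filter_subgroup(studies,
                                                               "ethnicity",
                                                               eth))
  for (src in SOURCES[SOURCES %in% studies$source])
    rows[[length(rows) + 1]] <- list(axis = "source", level = src,
                                     records = filter_subgroup(studies,
                                                               "source", src))
  rows
}

#' Run the full stratified meta-analysis
#'
#' For each subgroup (total, the Hardy-Weinberg-consistent subset, each
#' multi-study cancer type plus `"others"`, each organ system, each
#' ethnicity, each control source) and each of the five genetic models:
#' per-study odds ratios, Cochran's Q with inverse-variance weights, the
#' fixed/random selection rule, and the pooled OR with CI and Z-test.
#' The reported heterogeneity statistics (`q, p_h, i2`) are always the
#' inverse-variance ones that drive model selection. Studies without
#' genotype counts contribute to the count columns only (with a warning
#' recorded per affected subgroup).
#'
#' @param studies A validated roster `data.frame`.
#' @param config Optional named list overriding the defaults:
#'   `hwe_threshold` (0.05), `alpha_het` (0.05), `correction` (0.5), `level`
#'   (0.95), `fixed_estimator` (`"MH"` or `"IV"`), `min_k` (1; subgroups
#'   with fewer effect-bearing studies get count-only rows).
#' @return A list of class `analysis_report`: `counts` (`data.frame`:
#'   `axis, level, k, n_case, n_control`), `results` (long `data.frame`:
#'   one row per subgroup x model with `or, ci_low, ci_high, p_h, p, z,
#'   method, q, i2, tau2, k_effect`), `settings`, `warnings`.
#' @export
run_full_analysis <- function(studies, config = list()) {
  if (nrow(studies) == 0) stop("no studies to analyse", call. = FALSE)
  validate_studies(studies)
  cfg <- utils::modifyList(default_config(), config)
  rows <- subgroup_rows(studies, cfg$hwe_threshold)
  warnings <- character()

  counts <- do.call(rbind, lapply(rows, function(r) {
    agg <- aggregate_counts(r$records)
    data.frame(axis = r$axis, level = r$level, k = agg$k,
               n_case = agg$case_total, n_control = agg$control_total,
               stringsAsFactors = FALSE)
  }))

  res <- list()
  for (r in rows) {
    label <- if (is.na(r$level)) r$axis else paste0(r$axis, ":", r$level)
    with_counts <- r$records[has_genotype_counts(r$records), , drop = FALSE]
    n_missing <- nrow(r$records) - nrow(with_counts)
    if (n_missing > 0)
      warnings <- c(warnings, sprintf(
        "%s: %d of %d studies lack genotype counts", label, n_missing,
        nrow(r$records)))
    if (nrow(with_counts) < max(1, cfg$min_k)) {
      if (nrow(with_counts) == 0)
        warnings <- c(warnings,
                      sprintf("%s: no effect estimates available", label))
      next
    }
    for (model in genetic_models()) {
      eff <- study_effects(with_counts, model, correction = cfg$correction,
                           level = cfg$level)
      if (any(eff$corrected))
        warnings <- c(warnings, sprintf(
          "%s/%s: continuity correction applied to %s", label, model,
          paste(eff$study_id[eff$corrected], collapse = ", ")))
      tabs <- if (cfg$fixed_estimator == "MH")
        contrast_tables(with_counts, model) else NULL
      pooled <- pool_effects(eff, tables = tabs,
                             fixed_estimator = cfg$fixed_estimator,
                             alpha_het = cfg$alpha_het, level = cfg$level)
      het <- cochran_q(eff, iv_fixed(eff)$log_or)
      res[[length(res) + 1]] <- data.frame(
        axis = r$axis, level = r$level, model = model,
        k_effect = pooled$k, or = pooled$or, ci_low = pooled$ci_low,
        ci_high = pooled$ci_high, p_h = het$p_q, p = pooled$p, z = pooled$z,
        method = pooled$method, q = het$q, i2 = het$i2, tau2 = pooled$tau2,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(res) > 0) do.call(rbind, res) else NULL
  structure(list(counts = counts, results = results, settings = cfg,
                 warnings = warnings),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Stratified SNP meta-analysis:", nrow(x$counts), "subgroup rows,",
      if (is.null(x$results)) 0 else nrow(x$results), "pooled cells,",
      length(x$warnings), "warnings\n")
  invisible(x)
}

#' Render the stratified report as a TSV table
#'
#' One row per subgroup: `axis, level, k, n_case, n_control`, then per
#' genetic model the blocks `or, ci_low, ci_high, p_h, p, method, tau2,
#' i2`. The `"machine"` variant keeps full precision; the `"human"` variant
#' rounds ORs/CIs to 2 decimals and p-values to 3.
#'
#' @param report An `analysis_report`.
#' @param path Output TSV path; warnings (if any) go to `<path>.warnings.txt`.
#' @param variant `"machine"` (default) or `"human"`.
#' @return `path`, invisibly.
#' @export
render_table2 <- function(report, path, variant = c("machine", "human")) {
  variant <- match.arg(variant)
  out <- report$counts
  for (model in genetic_models()) {
    block <- c("or", "ci_low", "ci_high", "p_h", "p", "method", "tau2", "i2")
    sub <- report$results[report$results$model == model, , drop = FALSE]
    idx <- match(paste(out$axis, out$level),
                 if (is.null(sub)) character() else paste(sub$axis, sub$level))
    for (col in block) {
      val <- if (is.null(sub)) rep(NA, nrow(out)) else sub[[col]][idx]
      if (variant == "human" && is.numeric(val))
        val <- round(val, if (col %in% c("p_h", "p")) 3 else 2)
      out[[paste0(model, "_", col)]] <- val
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (length(report$warnings) > 0)
    writeLines(report$warnings, paste0(path, ".warnings.txt"))
  invisible(path)
}

#' Export forest-plot data
#'
#' Per-study OR, CI and percent weight under the pooled model's weighting
#' (`1 / (v_i + tau2)`), plus a summary row for the pooled estimate.
#'
#' @param effects A `data.frame` of per-study effects.
#' @param pooled A `pooled_result` computed on the same effects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_forest_data <- function(effects, pooled, path) {
  w <- 1 / (effects$var + pooled$tau2)
  rows <- data.frame(study_id = effects$study_id, or = effects$or,
                     ci_low = effects$ci_low, ci_high = effects$ci_high,
                     weight_pct = 100 * w / sum(w),
                     stringsAsFactors = FALSE)
  summary_row <- data.frame(study_id = sprintf("POOLED (%s)", pooled$method),
                            or = pooled$or, ci_low = pooled$ci_low,
                            ci_high = pooled$ci_high, weight_pct = 100,
                            stringsAsFactors = FALSE)
  utils::write.table(rbind(rows, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
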