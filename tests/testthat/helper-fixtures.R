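# Shared fixtures and small generators for the test suite.

fixture_studies <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- read_study_table(snpmeta_extdata("table1_studies.tsv"))
    cache
  }
})

# Random per-study effects with positive variances, in the study_effects()
# column layout.
make_effects <- function(k, mean = 0, sd = 0.3, vmin = 0.01, vmax = 0.2) {
  y <- stats::rnorm(k, mean, sd)
  v <- stats::runif(k, vmin, vmax)
  z <- stats::qnorm(0.975)
  data.frame(study_id = sprintf("s%02d", seq_len(k)),
             log_or = y, var = v, or = exp(y),
             ci_low = exp(y - z * sqrt(v)), ci_high = exp(y + z * sqrt(v)),
             corrected = FALSE, stringsAsFactors = FALSE)
}

# A bare 2x2 contrast table.
ct <- function(a, b, c, d) {
  structure(list(a = a, b = b, c = c, d = d, corrected = FALSE),
            class = "contrast_table")
}

# Minimal valid roster rows with genotype counts, for hand-built datasets.
make_study_rows <- function(case_counts, ctrl_counts,
                            cancer_type = "Breast", ethnicity = "Asian",
                            source = "HB") {
  k <- nrow(case_counts)
  data.frame(study_id = sprintf("h%02d", seq_len(k)),
             first_author = "Handmade", year = 2010L, origin = "Nowhere",
             cancer_type = cancer_type, system = classify_system(cancer_type),
             ethnicity = ethnicity, source = source,
             n_case = rowSums(case_counts), n_control = rowSums(ctrl_counts),
             hwe_p = 0.5, hwe_below_detection = FALSE, method = "PCR-RFLP",
             case_AA = case_counts[, 1], case_AG = case_counts[, 2],
             case_GG = case_counts[, 3],
             ctrl_AA = ctrl_counts[, 1], ctrl_AG = ctrl_counts[, 2],
             ctrl_GG = ctrl_counts[, 3],
             stringsAsFactors = FALSE)
}
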