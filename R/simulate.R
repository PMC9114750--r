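# Seeded generator of synthetic case-control genotype-count meta-datasets
# with known truth, for calibration and recovery testing.

# Roster-shaped default metadata mixes (study counts, used as sampling
# weights): 60:25:2 Asian:Caucasian:African, 53:34 HB:PB, and the empirical
# cancer-type distribution of the packaged 87-study roster.
default_metadata_mix <- function() {
  list(
    ethnicity = c(Asian = 60, Caucasian = 25, African = 2),
    source = c(HB = 53, PB = 34),
    cancer_type = c(Colorectal = 11, Cervical = 10, Breast = 8,
                    `Head and neck` = 8, Lung = 7, Bone = 6, Lymphoma = 6,
                    Gastric = 5, Liver = 4, Bladder = 3, Renal = 3,
                    Melanoma = 3, Myeloma = 2, Leukemia = 2, Pancreatic = 2,
                    Thyroid = 2, Esophageal = 1, Glioma = 1, Prostate = 1,
                    Skin = 1, Thymoma = 1)
  )
}

#' Configuration for the synthetic meta-dataset generator
#'
#' Collects the generating conditions: number of studies, true per-G-allele
#' log odds ratio, between-study variance of the true effects, bounds for
#' the control G-allele frequency draw, per-arm sample-size bounds, the
#' inbreeding coefficient controlling departure from Hardy-Weinberg in
#' controls (0 = exact HWE), the publication-selection probability (chance
#' that a study with allelic-contrast p >= 0.05 is suppressed), metadata
#' proportions, and the seed.
#'
#' @param k Number of studies (>= 0).
#' @param true_log_or True mean per-allele log odds ratio (default 0).
#' @param tau2 Between-study variance of true log odds ratios (default 0).
#' @param allele_freq_range Bounds for the control G-allele frequency draw
#'   (default `c(0.25, 0.70)`, spanning the Caucasian-to-Asian control
#'   frequency range of the packaged roster).
#' @param n_range Per-arm sample-size bounds (default `c(50, 2200)`,
#'   mirroring the roster's study sizes).
#' @param inbreeding_f Inbreeding coefficient in `[0, 1)` for control
#'   genotypes (default 0 = exact Hardy-Weinberg).
#' @param selection_prob Suppression probability for non-significant studies
#'   in [apply_selection_bias()] (default 0 = no bias).
#' @param metadata_mix List of named weight vectors for `ethnicity`,
#'   `source`, `cancer_type`; defaults mirror the packaged roster.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(k = 87, true_log_or = 0, tau2 = 0,
                       allele_freq_range = c(0.25, 0.70),
                       n_range = c(50L, 2200L), inbreeding_f = 0,
                       selection_prob = 0, metadata_mix = NULL,
                       seed = NULL) {
  stopifnot(k >= 0, tau2 >= 0,
            length(allele_freq_range) == 2,
            allele_freq_range[1] <= allele_freq_range[2],
            allele_freq_range[1] > 0, allele_freq_range[2] < 1,
            length(n_range) == 2, n_range[1] <= n_range[2], n_range[1] >= 1,
            inbreeding_f >= 0, inbreeding_f < 1,
            selection_prob >= 0, selection_prob <= 1)
  mix <- default_metadata_mix()
  if (!is.null(metadata_mix)) mix[names(metadata_mix)] <- metadata_mix
  structure(list(k = as.integer(k), true_log_or = true_log_or, tau2 = tau2,
                 allele_freq_range = allele_freq_range,
                 n_range = as.integer(n_range), inbreeding_f = inbreeding_f,
                 selection_prob = selection_prob, metadata_mix = mix,
                 seed = seed),
            class = "sim_config")
}

# Genotype probabilities (AA, AG, GG) for G-allele frequency q and
# inbreeding coefficient f.
genotype_probs <- function(q, f) {
  c((1 - q)^2 + f * q * (1 - q),
    2 * q * (1 - q) * (1 - f),
    q^2 + f * q * (1 - q))
}

#' Simulate one case-control study
#'
#' Draws a control G-allele frequency from the configured range, forms
#' control genotype probabilities (with optional inbreeding departure from
#' Hardy-Weinberg), tilts them by `exp(theta_i)` per G allele
#' (multiplicative per-allele model, renormalized — the retrospective
#' case-control construction) to get the case distribution, and draws both
#' arms' genotype counts multinomially. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param theta_i True log odds ratio for this study.
#' @param study_id Study label.
#' @return A one-row roster `data.frame` (the [read_study_table()] schema,
#'   genotype counts filled in, `hwe_p` computed from the simulated control
#'   counts) with the true parameters attached as attribute `truth`
#'   (`data.frame`: `study_id, theta, q_control, f`).
#' @export
simulate_study <- function(config, theta_i = config$true_log_or,
                           study_id = "sim_1") {
  q <- stats::runif(1, config$allele_freq_range[1],
                    config$allele_freq_range[2])
  ctrl_p <- genotype_probs(q, config$inbreeding_f)
  case_p <- ctrl_p * exp(theta_i)^(0:2)
  case_p <- case_p / sum(case_p)
  n_case <- sample(config$n_range[1]:config$n_range[2], 1)
  n_control <- sample(config$n_range[1]:config$n_range[2], 1)
  case_counts <- as.integer(stats::rmultinom(1, n_case, case_p))
  ctrl_counts <- as.integer(stats::rmultinom(1, n_control, ctrl_p))
  mix <- config$metadata_mix
  draw <- function(wts) sample(names(wts), 1, prob = wts)
  cancer_type <- draw(mix$cancer_type)
  rec <- data.frame(
    study_id = study_id, first_author = "Simulated",
    year = sample(2003:2021, 1), origin = "Simulated",
    cancer_type = cancer_type,
    system = classify_system(cancer_type),
    ethnicity = draw(mix$ethnicity), source = draw(mix$source),
    n_case = n_case, n_control = n_control,
    hwe_p = hwe_chisq(ctrl_counts)$p, hwe_below_detection = FALSE,
    method = "Simulated",
    case_AA = case_counts[1], case_AG = case_counts[2],
    case_GG = case_counts[3],
    ctrl_AA = ctrl_counts[1], ctrl_AG = ctrl_counts[2],
    ctrl_GG = ctrl_counts[3],
    stringsAsFactors = FALSE
  )
  attr(rec, "truth") <- data.frame(study_id = study_id, theta = theta_i,
                                   q_control = q, f = config$inbreeding_f,
                                   stringsAsFactors = FALSE)
  rec
}

#' Simulate a meta-dataset of case-control studies
#'
#' Study-specific true effects are drawn `theta_i ~ N(true_log_or, tau2)`;
#' each study is then generated by [simulate_study()]. Deterministic under a
#' fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A roster `data.frame` with `config$k` rows and a `truth`
#'   attribute holding the per-study true parameters.
#' @export
simulate_meta_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$k == 0) {
    out <- simulate_study(sim_config(k = 1))[0, ]
    attr(out, "truth") <- NULL
    return(out)
  }
  k <- config$k
  theta <- stats::rnorm(k, config$true_log_or, sqrt(config$tau2))
  ids <- sprintf("sim_%03d", seq_len(k))
  # vectorized equivalent of k independent simulate_study() draws
  q <- stats::runif(k, config$allele_freq_range[1],
                    config$allele_freq_range[2])
  f <- config$inbreeding_f
  ctrl_p <- cbind((1 - q)^2 + f * q * (1 - q),
                  2 * q * (1 - q) * (1 - f),
                  q^2 + f * q * (1 - q))
  case_p <- ctrl_p * outer(exp(theta), 0:2, `^`)
  case_p <- case_p / rowSums(case_p)
  n_case <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)
  n_control <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)
  case_counts <- t(vapply(seq_len(k), function(i)
    as.integer(stats::rmultinom(1, n_case[i], case_p[i, ])), integer(3)))
  ctrl_counts <- t(vapply(seq_len(k), function(i)
    as.integer(stats::rmultinom(1, n_control[i], ctrl_p[i, ])), integer(3)))
  hwe_p <- vapply(seq_len(k), function(i) hwe_chisq(ctrl_counts[i, ])$p,
                  numeric(1))
  mix <- config$metadata_mix
  draw <- function(wts, n) sample(names(wts), n, replace = TRUE, prob = wts)
  cancer_type <- draw(mix$cancer_type, k)
  out <- data.frame(
    study_id = ids, first_author = "Simulated",
    year = sample(2003:2021, k, replace = TRUE), origin = "Simulated",
    cancer_type = cancer_type, system = classify_system(cancer_type),
    ethnicity = draw(mix$ethnicity, k), source = draw(mix$source, k),
    n_case = n_case, n_control = n_control,
    hwe_p = hwe_p, hwe_below_detection = FALSE, method = "Simulated",
    case_AA = case_counts[, 1], case_AG = case_counts[, 2],
    case_GG = case_counts[, 3],
    ctrl_AA = ctrl_counts[, 1], ctrl_AG = ctrl_counts[, 2],
    ctrl_GG = ctrl_counts[, 3],
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- data.frame(study_id = ids, theta = theta,
                                   q_control = q, f = f,
                                   stringsAsFactors = FALSE)
  validate_studies(out)
  out
}

#' Apply a publication-selection mechanism to a simulated meta-dataset
#'
#' With `direction = "two.sided"` (the default), each study whose
#' allelic-contrast two-sided p-value is `>= alpha` is removed independently
#' with probability `config$selection_prob`; significant studies always
#' survive. Note that this filter acts on the standardized effect alone,
#' symmetrically in its sign, so at a null true odds ratio it hollows the
#' funnel without tilting it. `direction = "greater"` is the classical
#' directional mechanism — studies are at risk of suppression unless they
#' show a *significant risk-increasing* effect (log OR > 0 and p < alpha) —
#' which does induce funnel asymmetry detectable by [egger_test()].
#' Uses the current RNG state.
#'
#' @param records A roster `data.frame` whose rows carry genotype counts.
#' @param config A [sim_config()] (only `selection_prob` is consumed).
#' @param alpha Significance threshold of the selection mechanism
#'   (default 0.05).
#' @param direction `"two.sided"` (default) or `"greater"`.
#' @return The surviving subset, `truth` attribute filtered to match.
#' @export
apply_selection_bias <- function(records, config, alpha = 0.05,
                                 direction = c("two.sided", "greater")) {
  direction <- match.arg(direction)
  if (nrow(records) == 0 || config$selection_prob == 0) return(records)
  eff <- study_effects(records, "allelic")
  p <- 2 * stats::pnorm(-abs(eff$log_or) / sqrt(eff$var))
  at_risk <- if (direction == "two.sided") p >= alpha
             else p >= alpha | eff$log_or <= 0
  suppress <- at_risk & stats::runif(nrow(records)) < config$selection_prob
  out <- records[!suppress, , drop = FALSE]
  truth <- attr(records, "truth")
  if (!is.null(truth))
    attr(out, "truth") <- truth[!suppress, , drop = FALSE]
  out
}

#' Write a simulated meta-dataset and its truth sidecar
#'
#' Emits the same TSV dialect read by [read_study_table()] plus a
#' `<path>.truth.tsv` sidecar with the true per-study parameters.
#'
#' @param records Output of [simulate_meta_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(records, path) {
  out <- records
  out$hwe_below_detection <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(records, "truth")
  if (!is.null(truth))
    utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
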