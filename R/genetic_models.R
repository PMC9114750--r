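# Genetic-model contrasts, per-study odds ratios, and the HWE chi-square test.

#' The five genetic-model contrasts
#'
#' Closed vocabulary of the genotype-table recodings used throughout:
#' `allelic` (G vs A alleles, 2N observations per arm), `heterozygote`
#' (AG vs AA, GG excluded), `homozygote` (GG vs AA, AG excluded), `dominant`
#' (GG+AG vs AA) and `recessive` (GG vs AG+AA). G is the effect (exposed)
#' allele in every model; genotype class order is AA, AG, GG (ascending
#' G dosage).
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() {
  c("allelic", "heterozygote", "homozygote", "dominant", "recessive")
}

#' Build the 2x2 contrast table for one genetic model
#'
#' Collapses per-arm genotype counts `(AA, AG, GG)` into a 2x2 table with
#' cells `a` (case, G-bearing/exposed), `b` (case, unexposed), `c` (control,
#' exposed), `d` (control, unexposed). The allelic contrast counts the 2N
#' alleles of each arm as independent observations; heterozygote and
#' homozygote contrasts drop the excluded genotype class.
#'
#' @param model One of [genetic_models()].
#' @param case,control Numeric vectors `c(AA, AG, GG)` of genotype counts,
#'   each summing to at least 1.
#' @return A list of class `contrast_table` with fields `a, b, c, d`
#'   (numeric) and `corrected = FALSE`.
#' @export
build_contrast <- function(model, case, control) {
  model <- match.arg(model, genetic_models())
  for (arm in list(case, control)) {
    if (length(arm) != 3 || anyNA(arm))
      stop("genotype counts required: numeric (AA, AG, GG) per arm",
           call. = FALSE)
    if (any(arm < 0) || sum(arm) < 1)
      stop("genotype counts must be non-negative with total >= 1",
           call. = FALSE)
  }
  cells <- function(g) { # g = c(AA, AG, GG) -> c(exposed, unexposed)
    switch(model,
      allelic      = c(2 * g[3] + g[2], 2 * g[1] + g[2]),
      heterozygote = c(g[2], g[1]),
      homozygote   = c(g[3], g[1]),
      dominant     = c(g[3] + g[2], g[1]),
      recessive    = c(g[3], g[2] + g[1]))
  }
  ca <- cells(case); co <- cells(control)
  structure(list(a = unname(ca[1]), b = unname(ca[2]),
                 c = unname(co[1]), d = unname(co[2]),
                 corrected = FALSE),
            class = "contrast_table")
}

#' Odds ratio with Woolf variance from a 2x2 table
#'
#' Computes the study-level log odds ratio `y = ln(ad/bc)`, its Woolf
#' variance `v = 1/a + 1/b + 1/c + 1/d`, and the Wald confidence interval
#' `exp(y +/- z * sqrt(v))`. When any cell is zero the Haldane-Anscombe
#' continuity correction adds `correction` to all four cells (flagged in the
#' output); with `correction = 0` a zero cell is an error.
#'
#' @param table A `contrast_table` (or list with fields `a, b, c, d`).
#' @param correction Continuity correction added to every cell when at least
#'   one cell is zero (default 0.5).
#' @param level Confidence level (default 0.95).
#' @param study_id Optional study label carried through to the output.
#' @return A list of class `effect_estimate`: `study_id, log_or, var, or,
#'   ci_low, ci_high, corrected`.
#' @export
study_odds_ratio <- function(table, correction = 0.5, level = 0.95,
                             study_id = NA_character_) {
  cells <- c(table$a, table$b, table$c, table$d)
  stopifnot(all(cells >= 0), correction >= 0)
  if (all(cells == 0)) stop("all cells are zero", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) {
    if (correction == 0)
      stop("zero cell with correction = 0: odds ratio undefined",
           call. = FALSE)
    cells <- cells + correction
  }
  y <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  v <- sum(1 / cells)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(study_id = study_id, log_or = y, var = v, or = exp(y),
                 ci_low = exp(y - z * sqrt(v)), ci_high = exp(y + z * sqrt(v)),
                 corrected = corrected),
            class = "effect_estimate")
}

#' Per-study effect estimates for one genetic model
#'
#' Convenience over [build_contrast()] + [study_odds_ratio()]: one row per
#' study carrying genotype counts.
#'
#' @param studies A roster `data.frame` whose rows all carry genotype counts.
#' @param model One of [genetic_models()].
#' @param correction,level Passed to [study_odds_ratio()].
#' @return A `data.frame` with columns `study_id, log_or, var, or, ci_low,
#'   ci_high, corrected`.
#' @export
study_effects <- function(studies, model, correction = 0.5, level = 0.95) {
  model <- match.arg(model, genetic_models())
  if (!all(has_genotype_counts(studies)))
    stop("genotype counts required for every study", call. = FALSE)
  # vectorized equivalent of build_contrast() + study_odds_ratio() per row
  cells <- function(AA, AG, GG) {
    switch(model,
      allelic      = cbind(2 * GG + AG, 2 * AA + AG),
      heterozygote = cbind(AG, AA),
      homozygote   = cbind(GG, AA),
      dominant     = cbind(GG + AG, AA),
      recessive    = cbind(GG, AG + AA))
  }
  m <- cbind(cells(studies$case_AA, studies$case_AG, studies$case_GG),
             cells(studies$ctrl_AA, studies$ctrl_AG, studies$ctrl_GG))
  corrected <- rowSums(m == 0) > 0
  if (any(corrected) && correction == 0)
    stop("zero cell with correction = 0: odds ratio undefined", call. = FALSE)
  m[corrected, ] <- m[corrected, , drop = FALSE] + correction
  y <- log(m[, 1] * m[, 4] / (m[, 2] * m[, 3]))
  v <- rowSums(1 / m)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(study_id = studies$study_id, log_or = y, var = v, or = exp(y),
             ci_low = exp(y - z * sqrt(v)), ci_high = exp(y + z * sqrt(v)),
             corrected = corrected, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Contrast tables for every study in a roster
#'
#' @param studies A roster `data.frame` whose rows all carry genotype counts.
#' @param model One of [genetic_models()].
#' @return A list of `contrast_table` objects, one per study, named by
#'   `study_id`.
#' @export
contrast_tables <- function(studies, model) {
  if (!all(has_genotype_counts(studies)))
    stop("genotype counts required for every study", call. = FALSE)
  tabs <- lapply(seq_len(nrow(studies)), function(i)
    build_contrast(model,
      case = as.numeric(studies[i, c("case_AA", "case_AG", "case_GG")]),
      control = as.numeric(studies[i, c("ctrl_AA", "ctrl_AG", "ctrl_GG")])))
  names(tabs) <- studies$study_id
  tabs
}

#' Pearson chi-square test for Hardy-Weinberg equilibrium
#'
#' Estimates the A-allele frequency `p = (2 n_AA + n_AG) / 2n` from the
#' genotype counts, forms the Hardy-Weinberg expected counts
#' `n p^2, 2 n p (1 - p), n (1 - p)^2`, and computes the Pearson chi-square
#' statistic over the three genotype classes on 1 degree of freedom. A class
#' with expected count zero contributes nothing when its observed count is
#' also zero (a monomorphic sample on Hardy-Weinberg proportions gives
#' `chi2 = 0, p = 1`).
#'
#' @param counts Numeric vector `c(AA, AG, GG)` of control genotype counts,
#'   total at least 1.
#' @return A list of class `hwe_result`: `chi2`, `p`, `allele_freq_A`, `df`.
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3 || anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative (AA, AG, GG)", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  terms <- ifelse(expected > 0, (counts - expected)^2 / expected, 0)
  chi2 <- sum(terms)
  structure(list(chi2 = unname(chi2),
                 p = stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE),
                 allele_freq_A = unname(p), df = 1L),
            class = "hwe_result")
}
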