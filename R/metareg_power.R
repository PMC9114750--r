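# Univariable random-effects meta-regression and allele-based power
# calculation.

#' Random-effects meta-regression over a study-level covariate
#'
#' Weighted least squares of study log odds ratios on an intercept plus one
#' covariate. Categorical covariates are dummy-coded against the most
#' frequent level. The residual between-study variance is estimated by the
#' method of moments (the generalized DerSimonian-Laird estimator from the
#' residual heterogeneity statistic `Q_E` and the trace of the weighted
#' projection), or by restricted maximum likelihood with
#' `tau2_method = "REML"`; coefficients are then refitted with weights
#' `1 / (v_i + tau2)` and tested by Wald z.
#'
#' @param effects A `data.frame` with columns `study_id`, `log_or`, `var`.
#' @param covariate Vector of covariate values, one per study (numeric for
#'   `kind = "continuous"`, character/factor for `"categorical"`), or a
#'   named vector / list indexed by `study_id`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param tau2_method `"DL"` (method of moments, default) or `"REML"`.
#' @param collapse_below For categorical covariates, levels carried by fewer
#'   than this many studies are merged into `"other_method"` before coding
#'   (default 0 = no merging); used by the pipeline for sparse
#'   genotyping-method levels.
#' @param covariate_name Label carried into the result.
#' @return A list of class `metareg_result`: `covariate`, `coefficients`
#'   (`data.frame`: `term, beta, se, z, p`), `tau2`, `q_e` (residual
#'   heterogeneity), `k`.
#' @export
metareg_fit <- function(effects, covariate, kind = c("continuous", "categorical"),
                        tau2_method = c("DL", "REML"), collapse_below = 0,
                        covariate_name = deparse(substitute(covariate))) {
  kind <- match.arg(kind)
  tau2_method <- match.arg(tau2_method)
  check_effects(effects, 2)
  k <- nrow(effects)
  if (!is.null(names(covariate))) {
    miss <- setdiff(effects$study_id, names(covariate))
    if (length(miss) > 0)
      stop("missing covariate value for study ", miss[1], call. = FALSE)
    covariate <- unlist(covariate[effects$study_id], use.names = FALSE)
  }
  if (length(covariate) != k)
    stop("one covariate value per study required", call. = FALSE)
  if (anyNA(covariate)) {
    bad <- effects$study_id[which(is.na(covariate))[1]]
    stop("missing covariate value for study ", bad, call. = FALSE)
  }

  if (kind == "categorical") {
    covariate <- as.character(covariate)
    if (collapse_below > 0) {
      tab <- table(covariate)
      covariate[covariate %in% names(tab)[tab < collapse_below]] <-
        "other_method"
    }
  }
  if (length(unique(covariate)) == 1) {
    # constant covariate: no contrast to estimate, intercept-only model
    # (numerically identical to DerSimonian-Laird pooling for tau2 = "DL")
    X <- matrix(1, nrow = k, dimnames = list(NULL, "(Intercept)"))
  } else if (kind == "continuous") {
    X <- cbind("(Intercept)" = 1, beta = as.numeric(covariate))
    colnames(X)[2] <- covariate_name
  } else {
    tab <- sort(table(covariate), decreasing = TRUE)
    ref <- names(tab)[1]
    f <- factor(covariate, levels = c(ref, setdiff(names(tab), ref)))
    X <- stats::model.matrix(~ f)
    colnames(X) <- c("(Intercept)", paste0(covariate_name, ":",
                                           levels(f)[-1]))
  }
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient design: collinear levels in '", covariate_name, "'",
         call. = FALSE)
  if (k < p + 2)
    stop("need at least ", p + 2, " studies for ", p, " design columns",
         call. = FALSE)

  y <- effects$log_or
  v <- effects$var
  w <- 1 / v
  XtWX <- crossprod(X, X * w)
  beta_f <- solve(XtWX, crossprod(X, w * y))
  resid_f <- y - X %*% beta_f
  q_e <- sum(w * resid_f^2)

  if (tau2_method == "DL") {
    # trace of P = W - W X (X'WX)^-1 X'W with W = diag(w)
    tr_p <- sum(w) - sum(diag(solve(XtWX, crossprod(X, X * w^2))))
    tau2 <- max(0, (q_e - (k - p)) / tr_p)
  } else {
    reml_ll <- function(tau2) {
      wi <- 1 / (v + tau2)
      XtWiX <- crossprod(X, X * wi)
      b <- solve(XtWiX, crossprod(X, wi * y))
      r <- y - X %*% b
      -0.5 * (sum(log(v + tau2)) + determinant(XtWiX)$modulus[1] +
                sum(wi * r^2))
    }
    upper <- max(stats::var(y), 1e-6) * 10
    tau2 <- stats::optimize(reml_ll, c(0, upper), maximum = TRUE,
                            tol = 1e-9)$maximum
    if (reml_ll(0) >= reml_ll(tau2)) tau2 <- 0
  }

  ws <- 1 / (v + tau2)
  XtWsX <- crossprod(X, X * ws)
  beta <- drop(solve(XtWsX, crossprod(X, ws * y)))
  se <- sqrt(diag(solve(XtWsX)))
  z <- beta / se
  structure(list(covariate = covariate_name,
                 coefficients = data.frame(term = colnames(X), beta = beta,
                                           se = se, z = z,
                                           p = 2 * stats::pnorm(-abs(z)),
                                           row.names = NULL,
                                           stringsAsFactors = FALSE),
                 tau2 = tau2, q_e = q_e, k = k),
            class = "metareg_result")
}

#' Write meta-regression results to TSV
#'
#' One row per coefficient with `tau2` and `q_e` repeated alongside.
#'
#' @param fit A `metareg_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metareg <- function(fit, path) {
  out <- fit$coefficients
  out$tau2 <- fit$tau2
  out$q_e <- fit$q_e
  out$covariate <- fit$covariate
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Power of the two-proportion allele-frequency test
#'
#' Power of the two-sided two-proportion z-test (unpooled-variance normal
#' approximation, no continuity correction) to detect an allelic odds ratio
#' `or_alt` given the control G-allele frequency `p_control`. The implied
#' case frequency is `p1 = or * p0 / (1 + p0 * (or - 1))`. At `or_alt = 1`
#' the power equals `alpha` exactly.
#'
#' @param alpha Two-sided type-I error rate, in (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio (> 0).
#' @param p_control Control G-allele frequency, in (0, 1).
#' @param n_case_alleles,n_control_alleles Allele counts per arm (2N; >= 2).
#' @return A list of class `power_spec` echoing the inputs plus `p_case`
#'   (implied case allele frequency) and `power`.
#' @export
power_two_proportions <- function(alpha, or_alt, p_control,
                                  n_case_alleles, n_control_alleles) {
  stopifnot(alpha > 0, alpha < 1, or_alt > 0,
            p_control > 0, p_control < 1,
            n_case_alleles >= 2, n_control_alleles >= 2)
  p1 <- or_alt * p_control / (1 + p_control * (or_alt - 1))
  if (p1 <= 0 || p1 >= 1 || !is.finite(p1))
    stop("degenerate case allele frequency under the alternative",
         call. = FALSE)
  se <- sqrt(p1 * (1 - p1) / n_case_alleles +
             p_control * (1 - p_control) / n_control_alleles)
  zq <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p_control) / se
  power <- stats::pnorm(d - zq) + stats::pnorm(-d - zq)
  structure(list(alpha = alpha, or_alt = or_alt, p_control = p_control,
                 p_case = p1, n_case_alleles = n_case_alleles,
                 n_control_alleles = n_control_alleles, power = power),
            class = "power_spec")
}
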