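# Fixed-effect (inverse-variance, Mantel-Haenszel) and DerSimonian-Laird
# random-effects pooling of study log odds ratios, with Cochran's Q, I^2,
# tau^2, and the Z-test on the pooled estimate.

pooled_result <- function(method, k, log_or, se, z_crit, q, p_q, i2, tau2) {
  zt <- z_test(log_or, se)
  structure(list(method = method, k = as.integer(k), log_or = log_or, se = se,
                 or = exp(log_or),
                 ci_low = exp(log_or - z_crit * se),
                 ci_high = exp(log_or + z_crit * se),
                 z = zt$z, p = zt$p, q = q, p_q = p_q, i2 = i2, tau2 = tau2),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled OR (%s, k = %d): %.3f [%.3f, %.3f]\n",
              x$method, x$k, x$or, x$ci_low, x$ci_high))
  cat(sprintf("  Z = %.3f, p = %.4g; Q = %.3f (p = %.4g), I2 = %.1f%%, tau2 = %.4g\n",
              x$z, x$p, x$q, x$p_q, x$i2, x$tau2))
  invisible(x)
}

check_effects <- function(effects, k_min = 1) {
  stopifnot(is.data.frame(effects),
            all(c("log_or", "var") %in% names(effects)))
  if (nrow(effects) < k_min)
    stop("at least ", k_min, " studies required", call. = FALSE)
  if (any(effects$var <= 0)) stop("variances must be > 0", call. = FALSE)
  invisible(effects)
}

#' Inverse-variance fixed-effect pooling
#'
#' Pools study log odds ratios with weights `w_i = 1 / v_i`:
#' `theta = sum(w y) / sum(w)`, `se = 1 / sqrt(sum(w))`. Cochran's Q, I^2
#' and the Z-test on the pooled estimate are attached.
#'
#' @param effects A `data.frame` with columns `log_or` and `var` (one row per
#'   study), e.g. from [study_effects()].
#' @param level Confidence level (default 0.95).
#' @return A `pooled_result` with `method = "fixed_IV"` and `tau2 = 0`.
#' @export
iv_fixed <- function(effects, level = 0.95) {
  check_effects(effects, 1)
  w <- 1 / effects$var
  theta <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- cochran_q(effects, theta)
  pooled_result("fixed_IV", nrow(effects), theta, se,
                stats::qnorm(1 - (1 - level) / 2),
                het$q, het$p_q, het$i2, tau2 = 0)
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 tables
#'
#' Pools stratified 2x2 tables by the Mantel-Haenszel odds ratio
#' `OR_MH = sum(a d / n) / sum(b c / n)`; the variance of `ln OR_MH` uses the
#' Robins-Breslow-Greenland estimator. Heterogeneity (Q, I^2) is computed on
#' the per-study Woolf log odds ratios with inverse-variance weights around
#' `ln OR_MH`.
#'
#' @param tables A list of `contrast_table` objects (see [build_contrast()]),
#'   each with positive margin totals.
#' @param correction Continuity correction forwarded to the per-study Woolf
#'   estimates used for the heterogeneity statistics (default 0.5). The MH
#'   estimate itself uses the raw cells.
#' @param level Confidence level (default 0.95).
#' @return A `pooled_result` with `method = "fixed_MH"` and `tau2 = 0`.
#' @export
mh_fixed <- function(tables, correction = 0.5, level = 0.95) {
  if (length(tables) == 0) stop("at least 1 table required", call. = FALSE)
  m <- vapply(tables, function(t) c(t$a, t$b, t$c, t$d), numeric(4))
  a <- m[1, ]; b <- m[2, ]; cc <- m[3, ]; d <- m[4, ]
  n <- a + b + cc + d
  if (any((a + cc) == 0) || any((b + d) == 0))
    stop("each table needs positive margin totals", call. = FALSE)
  R <- a * d / n; S <- b * cc / n
  if (sum(S) == 0)
    stop("undefined Mantel-Haenszel estimate: sum(b*c/n) = 0", call. = FALSE)
  theta <- log(sum(R) / sum(S))
  # Robins-Breslow-Greenland variance of ln OR_MH
  P <- (a + d) / n; Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
       sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
       sum(Q * S) / (2 * sum(S)^2)
  ids <- names(tables)
  if (is.null(ids)) ids <- as.character(seq_along(tables))
  effects <- do.call(rbind, lapply(seq_along(tables), function(i)
    as.data.frame(unclass(study_odds_ratio(tables[[i]],
                                           correction = correction,
                                           study_id = ids[i])),
                  stringsAsFactors = FALSE)))
  het <- cochran_q(effects, theta)
  pooled_result("fixed_MH", length(tables), theta, sqrt(v),
                stats::qnorm(1 - (1 - level) / 2),
                het$q, het$p_q, het$i2, tau2 = 0)
}

#' Cochran's Q heterogeneity test and I^2
#'
#' `Q = sum((1 / v_i) (y_i - theta)^2)`, referred to a chi-square with
#' `k - 1` degrees of freedom; `I2 = max(0, (Q - (k - 1)) / Q) * 100`
#' (0 when `Q = 0`). For `k = 1`, `Q = 0` and `p_q = 1`.
#'
#' @param effects A `data.frame` with columns `log_or` and `var`.
#' @param theta_fixed The pooled estimate Q is centred on.
#' @return A list `q`, `p_q`, `i2`.
#' @export
cochran_q <- function(effects, theta_fixed) {
  check_effects(effects, 1)
  k <- nrow(effects)
  q <- sum((effects$log_or - theta_fixed)^2 / effects$var)
  p_q <- if (k < 2) 1 else stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q = q, p_q = p_q, i2 = i2)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))` with
#' inverse-variance weights `w = 1 / v` and Q centred on the
#' inverse-variance fixed estimate; the pooled estimate then uses weights
#' `1 / (v + tau2)`. When `Q <= k - 1` the result collapses to [iv_fixed()]
#' (identical numbers, `method` label aside).
#'
#' @inheritParams iv_fixed
#' @return A `pooled_result` with `method = "random_DL"`.
#' @export
dl_random <- function(effects, level = 0.95) {
  check_effects(effects, 2)
  k <- nrow(effects)
  w <- 1 / effects$var
  theta_f <- sum(w * effects$log_or) / sum(w)
  het <- cochran_q(effects, theta_f)
  tau2 <- max(0, (het$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (effects$var + tau2)
  theta <- sum(ws * effects$log_or) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  pooled_result("random_DL", k, theta, se,
                stats::qnorm(1 - (1 - level) / 2),
                het$q, het$p_q, het$i2, tau2 = tau2)
}

#' Fixed- vs random-effects model selection on the heterogeneity p-value
#'
#' The fixed-effect model is retained when the Q-test shows no evidence of
#' heterogeneity, i.e. strictly `p_q > alpha_het`; otherwise random effects.
#'
#' @param p_q Heterogeneity p-value from [cochran_q()].
#' @param alpha_het Significance threshold (default 0.05).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(p_q, alpha_het = 0.05) {
  stopifnot(p_q >= 0, p_q <= 1, alpha_het >= 0, alpha_het <= 1)
  if (p_q > alpha_het) "fixed" else "random"
}

#' Z-test on a pooled log odds ratio
#'
#' @param log_or Pooled log odds ratio.
#' @param se Its standard error (> 0).
#' @return A list `z = log_or / se` and two-sided standard-normal `p`.
#' @export
z_test <- function(log_or, se) {
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  z <- log_or / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pool one set of study effects under the selection rule
#'
#' Applies [select_model()] to the inverse-variance Q-test and returns the
#' corresponding pooled result: Mantel-Haenszel (default) or inverse-variance
#' fixed effect when heterogeneity is absent, DerSimonian-Laird random
#' effects otherwise (fixed for `k = 1` regardless).
#'
#' @param effects A `data.frame` of per-study effects (`log_or`, `var`).
#' @param tables Optional list of `contrast_table`s matching `effects`;
#'   required when `fixed_estimator = "MH"`.
#' @param fixed_estimator `"MH"` (default) or `"IV"`.
#' @param alpha_het Heterogeneity threshold for [select_model()].
#' @param level Confidence level.
#' @return A `pooled_result`.
#' @export
pool_effects <- function(effects, tables = NULL, fixed_estimator = c("MH", "IV"),
                         alpha_het = 0.05, level = 0.95) {
  fixed_estimator <- match.arg(fixed_estimator)
  check_effects(effects, 1)
  fit_iv <- iv_fixed(effects, level = level)
  if (nrow(effects) >= 2 && select_model(fit_iv$p_q, alpha_het) == "random")
    return(dl_random(effects, level = level))
  if (fixed_estimator == "MH") {
    if (is.null(tables))
      stop("contrast tables required for the Mantel-Haenszel estimator",
           call. = FALSE)
    mh_fixed(tables, level = level)
  } else fit_iv
}
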