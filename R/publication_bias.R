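# Egger weighted-regression intercept test, Begg-Mazumdar rank correlation,
# and funnel-plot data export.

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effects `t_i = y_i / sqrt(v_i)`
#' on the precisions `x_i = 1 / sqrt(v_i)` (the classic unweighted 1997
#' formulation). The intercept estimates small-study asymmetry; its
#' two-sided p-value uses Student's t with `k - 2` degrees of freedom.
#'
#' @param effects A `data.frame` with columns `log_or` and `var`, `k >= 3`
#'   rows.
#' @return A list of class `bias_test`: `test = "egger"`, `statistic`
#'   (intercept), `se`, `t_or_z`, `p`, `k`, plus `slope`.
#' @export
egger_test <- function(effects) {
  check_effects(effects, 3)
  k <- nrow(effects)
  x <- 1 / sqrt(effects$var)
  t_std <- effects$log_or / sqrt(effects$var)
  if (stats::var(x) == 0)
    stop("all precisions identical: Egger design is singular", call. = FALSE)
  fit <- stats::lm(t_std ~ x)
  sm <- suppressWarnings(summary(fit)) # perfect fits handled explicitly below
  cf <- sm$coefficients
  b0 <- cf["(Intercept)", "Estimate"]
  se0 <- cf["(Intercept)", "Std. Error"]
  scale <- stats::sd(t_std) + .Machine$double.xmin
  if (sm$sigma < 1e-10 * scale) {
    # exact collinearity: the regression fits perfectly, so the intercept is
    # determined without error; in the limit p -> 1 when it sits at zero
    exact0 <- abs(b0) < 1e-10 * scale
    b0 <- if (exact0) 0 else b0
    tval <- if (exact0) 0 else sign(b0) * Inf
    p <- if (exact0) 1 else 0
    se0 <- 0
  } else {
    tval <- b0 / se0
    p <- 2 * stats::pt(-abs(tval), df = k - 2)
  }
  structure(list(test = "egger", statistic = b0, se = se0, t_or_z = tval,
                 p = p, k = k, slope = cf["x", "Estimate"]),
            class = "bias_test")
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between the standardized deviates
#' `u_i = (y_i - theta) / sqrt(v_i - vbar)` — with `theta` the
#' inverse-variance fixed pooled estimate and `vbar` its variance — and the
#' study variances `v_i`. The statistic is tie-adjusted Kendall's tau; the
#' normal deviate uses the untied null variance
#' `k (k - 1) (2 k + 5) / 18` on the concordant-minus-discordant count.
#' No continuity correction is applied.
#'
#' @param effects A `data.frame` with columns `log_or` and `var`, `k >= 2`
#'   rows.
#' @return A list of class `bias_test`: `test = "begg"`, `statistic`
#'   (Kendall tau), `t_or_z` (z), `p`, `k`, plus `c_minus_d`.
#' @export
begg_test <- function(effects) {
  check_effects(effects, 2)
  k <- nrow(effects)
  w <- 1 / effects$var
  theta <- sum(w * effects$log_or) / sum(w)
  vbar <- 1 / sum(w)
  excess <- effects$var - vbar
  if (any(excess <= 0)) {
    bad <- effects$study_id[which(excess <= 0)[1]]
    stop("degenerate variance (v_i <= var of pooled estimate) for study ",
         if (is.null(bad) || is.na(bad)) which(excess <= 0)[1] else bad,
         call. = FALSE)
  }
  u <- (effects$log_or - theta) / sqrt(excess)
  kt <- kendall_counts(u, effects$var)
  z <- kt$s / sqrt(k * (k - 1) * (2 * k + 5) / 18)
  structure(list(test = "begg", statistic = kt$tau, se = NULL, t_or_z = z,
                 p = 2 * stats::pnorm(-abs(z)), k = k, c_minus_d = kt$s),
            class = "bias_test")
}

# Concordant-minus-discordant count S over all pairs and tie-adjusted
# (tau-b) Kendall correlation.
kendall_counts <- function(u, v) {
  k <- length(u)
  s <- 0; tie_u <- 0; tie_v <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      du <- sign(u[i] - u[j]); dv <- sign(v[i] - v[j])
      s <- s + du * dv
      if (du == 0) tie_u <- tie_u + 1
      if (dv == 0) tie_v <- tie_v + 1
    }
  }
  n0 <- k * (k - 1) / 2
  denom <- sqrt((n0 - tie_u) * (n0 - tie_v))
  list(s = s, tau = if (denom > 0) s / denom else 0)
}

#' Funnel-plot data export
#'
#' One point per study (log OR against its standard error and precision)
#' plus pseudo-confidence guide lines `theta +/- z * se` evaluated on a grid
#' of standard errors from 0 to the largest observed `se`.
#'
#' @param effects A `data.frame` of per-study effects with `study_id`,
#'   `log_or`, `var`.
#' @param pooled A `pooled_result` computed on the same effects.
#' @param level Confidence level of the guide lines (default 0.95).
#' @param grid_n Number of grid points for the guide lines (default 50).
#' @return A list with `points` (`data.frame`: `study_id, log_or, se,
#'   precision`) and `guides` (`data.frame`: `se, lower, upper`).
#' @export
funnel_data <- function(effects, pooled, level = 0.95, grid_n = 50) {
  if (nrow(effects) == 0)
    return(list(points = data.frame(study_id = character(), log_or = numeric(),
                                    se = numeric(), precision = numeric()),
                guides = data.frame(se = numeric(), lower = numeric(),
                                    upper = numeric())))
  se <- sqrt(effects$var)
  points <- data.frame(study_id = effects$study_id, log_or = effects$log_or,
                       se = se, precision = 1 / se,
                       stringsAsFactors = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  grid <- seq(0, max(se), length.out = grid_n)
  guides <- data.frame(se = grid,
                       lower = pooled$log_or - z * grid,
                       upper = pooled$log_or + z * grid)
  list(points = points, guides = guides)
}

#' Write funnel data to TSV files
#'
#' @param fd Output of [funnel_data()].
#' @param path Path of the points TSV (`study_id, log_or, se, precision`);
#'   the guide lines go to a sidecar file `<path>.guides.tsv`.
#' @return `path`, invisibly.
#' @export
write_funnel <- function(fd, path) {
  utils::write.table(fd$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fd$guides, paste0(path, ".guides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
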