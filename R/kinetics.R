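#' Cultivation time series container
#'
#' Product (P, mg/L), biomass (X as cell dry weight, g/L) and optionally
#' glucose (S, g/L) sampled on a strictly increasing time grid in days.
#'
#' @param t_days Sampling times (days), strictly increasing, length >= 2.
#' @param P_mg_per_L Product concentration (mg/L).
#' @param X_g_per_L Cell dry weight concentration (g/L).
#' @param S_g_per_L Optional glucose concentration (g/L).
#' @param condition Condition label.
#' @return Data frame of class `cultivation_series` with attribute
#'   `condition`.
#' @export
cultivation_series <- function(t_days, P_mg_per_L, X_g_per_L,
                               S_g_per_L = NULL, condition = "unlabelled") {
  n <- length(t_days)
  if (n < 2L) stop("a cultivation series needs at least 2 time points")
  if (any(diff(t_days) <= 0)) stop("time grid must be strictly increasing")
  stopifnot(length(P_mg_per_L) == n, length(X_g_per_L) == n,
            is.null(S_g_per_L) || length(S_g_per_L) == n)
  if (any(P_mg_per_L < 0) || any(X_g_per_L < 0) ||
      (!is.null(S_g_per_L) && any(S_g_per_L < 0)))
    stop("concentrations must be non-negative")
  d <- data.frame(t_days = t_days, P_mg_per_L = P_mg_per_L,
                  X_g_per_L = X_g_per_L)
  if (!is.null(S_g_per_L)) d$S_g_per_L <- S_g_per_L
  attr(d, "condition") <- condition
  class(d) <- c("cultivation_series", "data.frame")
  d
}

#' Biomass-specific productivity q_P
#'
#' `q_P(t) = (1/X) * dP/dt` in mg per g biomass per day. The derivative is
#' taken by central differences on interior points and one-sided differences
#' at the ends (non-uniform grids supported). Points where X is zero are
#' returned as `NA` and flagged rather than propagating infinities.
#'
#' @param series A [cultivation_series()].
#' @return Data frame: `t_days`, `qP_mg_per_g_per_d`, `defined` (logical,
#'   `FALSE` where X = 0).
#' @export
specific_productivity <- function(series) {
  if (nrow(series) < 2L) stop("at least 2 time points required")
  dPdt <- pracma::gradient(series$P_mg_per_L, series$t_days)
  ok <- series$X_g_per_L > 0
  qP <- ifelse(ok, dPdt / series$X_g_per_L, NA_real_)
  data.frame(t_days = series$t_days, qP_mg_per_g_per_d = qP, defined = ok)
}

#' One-way (single-factor) analysis of variance
#'
#' Classical fixed-effects one-way ANOVA with unequal group sizes:
#' `F = MS_between / MS_within`, p-value from the upper tail of the F
#' distribution, significance at `alpha` (default 0.05). Groups with fewer
#' than 2 observations are rejected rather than silently pooled, since
#' tests on single observations are dominated by type II error.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level.
#' @return List of class `anova_result`: `f_value`, `p_value`,
#'   `df_between`, `df_within`, `group_ns`, `alpha`, `significant`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least 2 groups required")
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("every group needs at least 2 observations")
  all_x <- unlist(groups, use.names = FALSE)
  if (!is.numeric(all_x) || any(!is.finite(all_x)))
    stop("groups must be finite numeric vectors")
  N <- sum(ns); k <- length(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i)
    sum((groups[[i]] - means[i])^2), numeric(1)))
  df_b <- k - 1L; df_w <- N - k
  if (ss_within == 0)
    stop(if (ss_between == 0) "degenerate: zero variance between and within groups"
         else "degenerate: zero within-group variance")
  f <- (ss_between / df_b) / (ss_within / df_w)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(f_value = f, p_value = p, df_between = df_b,
                 df_within = df_w, group_ns = as.integer(ns), alpha = alpha,
                 significant = p < alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$df_between, x$df_within, x$f_value, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Per-day ANOVA comparison between cultivation conditions
#'
#' Runs [anova_oneway()] separately for each cultivation day over a long
#' table of replicate metric values, comparing conditions within the day.
#' Days where fewer than two conditions have at least two replicates, or
#' where the ANOVA is degenerate (zero within-group variance), are reported
#' as skipped with a reason instead of failing the whole table. No
#' correction for multiple testing across days is applied; the
#' `multiple_testing` attribute records this.
#'
#' @param metric_table Data frame with columns `day`, `condition`, `value`.
#' @param alpha Significance level per day.
#' @return Data frame with one row per day: `day`, `status`
#'   (`"tested"`/`"skipped"`/`"degenerate"`), `n_groups`, `f_value`,
#'   `p_value`, `df_between`, `df_within`, `significant`, `reason`.
#' @export
compare_conditions_per_day <- function(metric_table, alpha = 0.05) {
  stopifnot(all(c("day", "condition", "value") %in% names(metric_table)))
  days <- sort(unique(metric_table$day))
  rows <- lapply(days, function(d) {
    sub <- metric_table[metric_table$day == d, , drop = FALSE]
    groups <- split(sub$value, sub$condition)
    groups <- groups[lengths(groups) >= 2L]
    base <- data.frame(day = d, status = "skipped", n_groups = length(groups),
                       f_value = NA_real_, p_value = NA_real_,
                       df_between = NA_integer_, df_within = NA_integer_,
                       significant = NA, reason = "")
    if (length(groups) < 2L) {
      base$reason <- "fewer than 2 conditions with n >= 2"
      return(base)
    }
    res <- tryCatch(anova_oneway(groups, alpha), error = function(e) e)
    if (inherits(res, "error")) {
      base$status <- "degenerate"; base$reason <- conditionMessage(res)
      return(base)
    }
    data.frame(day = d, status = "tested", n_groups = length(groups),
               f_value = res$f_value, p_value = res$p_value,
               df_between = res$df_between, df_within = res$df_within,
               significant = res$significant, reason = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "multiple_testing") <- "none"
  out
}
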