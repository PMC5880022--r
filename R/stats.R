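# Shared statistical tests and binning.

#' Welch one-way test across groups
#'
#' Heteroscedastic (Welch) one-way test via `stats::oneway.test` with
#' `var.equal = FALSE`; the classical equal-variance ANOVA p-value is
#' reported alongside. For two groups the Welch statistic equals the
#' squared Welch two-sample t statistic.
#'
#' @param groups either a named list of numeric vectors, or a numeric
#'   vector when `labels` is given.
#' @param labels optional grouping factor matching `groups` as a vector.
#' @return list: `statistic`, `df` (numerator/denominator), `p`,
#'   `p_classical`, `n`, `medians`, `means`, and `p_display` (the
#'   conventional "< 2.2e-16"-style string).
#' @export
welch_oneway <- function(groups, labels = NULL) {
  if (!is.null(labels)) groups <- split(groups, labels)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("a group has zero within-group variance", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  w <- stats::oneway.test(y ~ g, var.equal = FALSE)
  a <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(w$statistic),
       df = unname(w$parameter),
       p = w$p.value,
       p_classical = a$p.value,
       n = lengths(groups),
       medians = vapply(groups, stats::median, numeric(1)),
       means = vapply(groups, mean, numeric(1)),
       p_display = format_pvalue(w$p.value))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin mean beta-values into deciles with MV summaries
#'
#' Ten bins at the 10th..90th percentiles (same linear-interpolation
#' quantile rule and open/closed convention as [quartile_bin()]). When
#' `mv` is supplied, per-decile MV summaries are returned — the classic
#' display of the intermediate-methylation variability peak.
#'
#' @param mean_betas numeric vector (per-probe mean methylation).
#' @param mv optional numeric vector of the same length (per-probe MV).
#' @return list `labels` (factor D1..D10), `boundaries`, and — with `mv`
#'   — `summary` (per-decile n, median/mean MV).
#' @export
decile_bin <- function(mean_betas, mv = NULL) {
  qb <- quantile_bin(mean_betas, 10L, prefix = "D")
  out <- list(labels = qb$labels, boundaries = qb$boundaries)
  if (!is.null(mv)) {
    stopifnot(length(mv) == length(mean_betas))
    out$summary <- data.frame(
      decile = levels(qb$labels),
      n = as.integer(table(qb$labels)),
      median_mv = as.numeric(tapply(mv, qb$labels, stats::median)),
      mean_mv = as.numeric(tapply(mv, qb$labels, mean)),
      stringsAsFactors = FALSE)
  }
  out
}
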