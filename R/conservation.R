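# Ancient selective pressure: intersect a base-resolution conservation
# (GERP-RS "rejected substitutions") track with probe positions, drop
# negative scores, bin the rest into quartiles and test the MV trend.
# GERP-RS spans [-12.36, 6.18]; positive values indicate a substitution
# deficit (evolutionary constraint).

GERP_MIN <- -12.36
GERP_MAX <- 6.18

#' Intersect a conservation track with probe positions
#'
#' Each probe receives the score of the track interval containing its
#' position (1-based probe position against 0-based half-open intervals).
#' Probes covered by no interval are dropped and counted. Overlapping
#' track intervals are a format error.
#'
#' @param track data.frame `chrom`, `start` (0-based), `end`, `score`.
#' @param manifest probe manifest with `probe`, `chrom`, `pos` (1-based).
#' @return data.frame `probe`, `score` for covered probes, with attribute
#'   `n_dropped` (probes with no covering interval).
#' @export
gerp_lookup <- function(track, manifest) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(track)),
            all(track$score >= GERP_MIN - 1e-9),
            all(track$score <= GERP_MAX + 1e-9))
  idx <- interval_lookup(manifest$chrom, manifest$pos - 1L, track)
  hit <- !is.na(idx)
  structure(
    data.frame(probe = manifest$probe[hit], score = track$score[idx[hit]],
               stringsAsFactors = FALSE),
    n_dropped = sum(!hit))
}

#' Drop probes with negative conservation scores
#'
#' Negative GERP-RS values are hard to interpret, so only probes with
#' score >= 0 (zero retained) are kept for the quartile analysis.
#'
#' @param annotated data.frame with `probe`, `score`.
#' @return the retained rows; warns when everything is dropped.
#' @export
nonneg_filter <- function(annotated) {
  keep <- annotated$score >= 0
  if (!any(keep)) warning("all probes have negative conservation scores")
  annotated[keep, , drop = FALSE]
}

#' Bin values into quartiles
#'
#' Boundaries at the 25/50/75th percentiles under the
#' linear-interpolation quantile rule; bins left-closed right-open, Q4
#' right-closed. Requires at least 4 distinct values; coincident
#' boundaries are an error.
#'
#' @param values numeric vector.
#' @return list with `labels` (factor Q1..Q4) and `boundaries`.
#' @examples
#' quartile_bin(1:8)$labels # Q1 Q1 Q2 Q2 Q3 Q3 Q4 Q4
#' @export
quartile_bin <- function(values) {
  quantile_bin(values, 4L, prefix = "Q")
}

#' MV by conservation quartile, with trend test
#'
#' Joins the MV table with conservation-annotated probes (non-negative
#' scores), bins scores into quartiles, and summarises MV per quartile.
#' The trend is tested with a Welch one-way test (classical ANOVA p is
#' also reported); the monotone flag records whether quartile medians are
#' non-increasing from Q1 (least conserved) to Q4 (most conserved).
#'
#' @param mv_table MV table from [compute_mv()].
#' @param annotated data.frame `probe`, `score` (already non-negative
#'   filtered, e.g. via [nonneg_filter()]).
#' @return list: `summary` (per-quartile n, median/mean MV, score range),
#'   `test` ([welch_oneway()] result), `monotone_decreasing` flag,
#'   `boundaries`.
#' @export
mv_by_quartile <- function(mv_table, annotated) {
  shared <- merge(mv_table[, c("probe", "mv")], annotated, by = "probe")
  if (nrow(shared) < 4L) stop("fewer than 4 probes shared between MV ",
                              "table and conservation annotation",
                              call. = FALSE)
  qb <- quartile_bin(shared$score)
  shared$quartile <- qb$labels
  if (nlevels(droplevels(shared$quartile)) < 2L) {
    stop("all probes fall in a single quartile", call. = FALSE)
  }
  med <- tapply(shared$mv, shared$quartile, stats::median)
  summ <- data.frame(
    quartile = levels(shared$quartile),
    n = as.integer(table(shared$quartile)),
    median_mv = as.numeric(med),
    mean_mv = as.numeric(tapply(shared$mv, shared$quartile, mean)),
    stringsAsFactors = FALSE)
  test <- welch_oneway(split(shared$mv, shared$quartile))
  list(summary = summ, test = test,
       monotone_decreasing = all(diff(stats::na.omit(as.numeric(med))) <= 0),
       boundaries = qb$boundaries, annotated = shared)
}
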