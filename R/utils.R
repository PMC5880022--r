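# Internal shared primitives: quantile binning and interval containment.
# Both are deliberately implemented once so that every consumer (decile and
# quartile binning; density-region and conservation-track lookup) agrees
# bit-for-bit.

#' Bin values into equal-probability quantile bins
#'
#' Shared quantile machinery behind [quartile_bin()] and [decile_bin()].
#' Boundaries use the linear-interpolation quantile rule
#' (`stats::quantile(type = 7)`, R's default). Bins are left-closed,
#' right-open, except the last bin which is right-closed.
#'
#' @param values numeric vector to bin.
#' @param n_bins number of bins (4 for quartiles, 10 for deciles).
#' @param prefix single character used to build labels (`"Q"` -> `Q1..Q4`).
#' @return list with `labels` (factor, one level per bin, same length as
#'   `values`) and `boundaries` (the interior quantile cut points).
#' @keywords internal
quantile_bin <- function(values, n_bins, prefix = "Q") {
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be numeric with no missing entries", call. = FALSE)
  }
  if (length(unique(values)) < n_bins) {
    stop("need at least ", n_bins, " distinct values to form ", n_bins,
         " bins", call. = FALSE)
  }
  probs <- seq_len(n_bins - 1L) / n_bins
  cuts <- stats::quantile(values, probs = probs, type = 7, names = FALSE)
  if (anyDuplicated(cuts)) {
    stop("degenerate bin boundaries: two quantiles coincide", call. = FALSE)
  }
  lev <- paste0(prefix, seq_len(n_bins))
  # left-closed/right-open: value goes to bin i iff cuts[i-1] <= v < cuts[i];
  # the top bin absorbs the maximum (right-closed).
  idx <- findInterval(values, cuts, left.open = FALSE) + 1L
  list(labels = factor(lev[idx], levels = lev),
       boundaries = cuts)
}

#' Look up containing intervals for point positions
#'
#' One code path for all point-in-interval queries (probe vs density region,
#' probe vs conservation track). Intervals are 0-based half-open
#' `[start, end)` per chromosome and must be non-overlapping; points are
#' 0-based positions.
#'
#' @param point_chrom,point_pos0 character/integer vectors of equal length.
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return integer vector: row index into `intervals` of the containing
#'   interval, or `NA` where no interval covers the point.
#' @keywords internal
interval_lookup <- function(point_chrom, point_pos0, intervals) {
  stopifnot(length(point_chrom) == length(point_pos0))
  out <- rep(NA_integer_, length(point_pos0))
  if (nrow(intervals) == 0L || length(out) == 0L) return(out)
  for (ch in unique(point_chrom)) {
    iv <- which(intervals$chrom == ch)
    if (length(iv) == 0L) next
    o <- iv[order(intervals$start[iv])]
    starts <- intervals$start[o]
    ends <- intervals$end[o]
    if (any(ends[-length(ends)] > starts[-1L])) {
      stop("overlapping intervals on ", ch, call. = FALSE)
    }
    pt <- which(point_chrom == ch)
    k <- findInterval(point_pos0[pt], starts)
    hit <- k > 0L & point_pos0[pt] < ends[pmax(k, 1L)]
    out[pt[hit]] <- o[k[hit]]
  }
  out
}

# Deterministic child seed for stage `offset` of a simulation; keeps the
# result a valid 32-bit integer for set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}

# display helper mirroring R's conventional "< 2.2e-16" style
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, digits = 3, format = "g"))
}
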