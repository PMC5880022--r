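# Promoter-level gene ranking and preranked gene-set enrichment.
#
# Probes are mapped to symmetric TSS windows, per-gene MV is the mean of
# promoter-probe MV, genes are z-scored and ranked, and gene sets are
# scored with the weighted Kolmogorov-Smirnov running-sum statistic under
# a gene-set permutation null (the only null available to a preranked
# list). Significance convention: NOM p <= 0.01 and FDR q <= 0.25.

#' Map probes to promoter windows
#'
#' A probe is assigned to every gene whose TSS lies within `flank` bp
#' (inclusive, symmetric regardless of strand); a probe inside two genes'
#' windows is assigned to both.
#'
#' @param annotation data.frame `gene`, `chrom`, `tss` (1-based),
#'   optionally `strand`.
#' @param manifest probe manifest (`probe`, `chrom`, `pos`).
#' @param flank half-window in bp (default 1500, i.e. a -1500..+1500
#'   promoter window).
#' @return data.frame `probe`, `gene`; zero rows if nothing maps.
#' @export
map_probes_to_promoters <- function(annotation, manifest, flank = 1500L) {
  stopifnot(!anyDuplicated(annotation$gene), all(annotation$tss >= 1))
  out <- vector("list", nrow(annotation))
  for (g in seq_len(nrow(annotation))) {
    hit <- manifest$chrom == annotation$chrom[g] &
      abs(manifest$pos - annotation$tss[g]) <= flank
    if (any(hit)) {
      out[[g]] <- data.frame(probe = manifest$probe[hit],
                             gene = annotation$gene[g],
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(probe = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene MV
#'
#' Aggregates the MV of each gene's promoter probes (mean by default;
#' median available). Assigned probes absent from the MV table (filtered
#' upstream) are ignored; genes left with no surviving probe are dropped
#' and counted in attribute `n_dropped_genes`.
#'
#' @param assignments data.frame `probe`, `gene` from
#'   [map_probes_to_promoters()].
#' @param mv_table MV table (`probe`, `mv`).
#' @param agg `"mean"` or `"median"`.
#' @return data.frame `gene`, `x` (aggregated MV), `n_probes`.
#' @export
gene_mv <- function(assignments, mv_table, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  m <- merge(assignments, mv_table[, c("probe", "mv")], by = "probe")
  n_dropped <- length(setdiff(assignments$gene, m$gene))
  if (nrow(m) == 0L) {
    return(structure(data.frame(gene = character(), x = numeric(),
                                n_probes = integer(),
                                stringsAsFactors = FALSE),
                     n_dropped_genes = n_dropped))
  }
  f <- if (agg == "mean") mean else stats::median
  x <- tapply(m$mv, m$gene, f)
  res <- data.frame(gene = names(x), x = as.numeric(x),
                    n_probes = as.integer(table(m$gene)[names(x)]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, n_dropped_genes = n_dropped)
}

#' Z-score and rank genes by MV
#'
#' `z = (X - mu) / sigma` with `mu` the mean and `sigma` the sample
#' standard deviation of the gene-level MV values; genes are sorted by
#' descending z with alphabetical tie-break, ready for preranked
#' enrichment.
#'
#' @param gene_mv_table data.frame `gene`, `x` from [gene_mv()].
#' @return data.frame `gene`, `x`, `z` in ranking order.
#' @export
zscore_rank <- function(gene_mv_table) {
  stopifnot(nrow(gene_mv_table) >= 2L)
  sigma <- stats::sd(gene_mv_table$x)
  if (!is.finite(sigma) || sigma == 0) {
    stop("all gene-level MV values identical: z-scores undefined",
         call. = FALSE)
  }
  res <- gene_mv_table
  res$z <- (res$x - mean(res$x)) / sigma
  res <- res[order(-res$z, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Weighted KS running-sum enrichment score for one set.
# scores: ranking scores in list order; hit: logical, same length.
gsea_es <- function(scores, hit, weight = 1) {
  n_hit <- sum(hit)
  n_miss <- length(scores) - n_hit
  w <- abs(scores[hit])^weight
  tot <- sum(w)
  inc <- numeric(length(scores))
  inc[hit] <- if (tot > 0) w / tot else 1 / n_hit
  inc[!hit] <- -1 / n_miss
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: walking down the
#' ranked list, set members increment the sum by `|z|^weight` (normalised
#' by the in-set total) and non-members decrement it by `1/(N - N_hit)`;
#' ES is the signed maximum deviation. The null is gene-set permutation:
#' for each set size, `n_perm` random same-size gene sets (enumerated
#' exhaustively instead when there are at most `n_perm` same-size
#' subsets, giving exact permutation p-values on small lists).
#' NES divides ES by the mean magnitude of same-sign null ES; nominal p
#' is the fraction of same-sign null ES at least as extreme; FDR q uses
#' the pooled-NES procedure (null and observed NES pooled over all tested
#' sets, compared tail-wise, with monotone clean-up). Positive-ES sets
#' are labelled `high-MV tail`, negative `low-MV tail`.
#'
#' @param ranked data.frame `gene`, `z` from [zscore_rank()] (descending).
#' @param sets named list of gene-symbol vectors.
#' @param weight running-sum weight (1 = classic weighted statistic).
#' @param n_perm permutations per set size.
#' @param min_size,max_size set-size bounds after restriction to list
#'   genes (defaults 3 and 500); sets covering the whole list are skipped.
#' @param seed integer seed for the permutation draws.
#' @return data.frame `set`, `size`, `es`, `nes`, `p`, `q`, `direction`,
#'   `leading_edge` (comma-joined genes before/at the ES extremum that
#'   are in the set). Sets with no usable size are skipped with a warning.
#' @export
gsea_preranked <- function(ranked, sets, weight = 1, n_perm = 1000L,
                           min_size = 3L, max_size = 500L, seed = 1L) {
  stopifnot(nrow(ranked) > 0L, !is.null(names(sets)))
  genes <- ranked$gene
  scores <- ranked$z
  N <- length(genes)
  set.seed(as.integer(seed))

  restricted <- lapply(sets, function(s) intersect(genes, s))
  sizes <- lengths(restricted)
  usable <- sizes >= min_size & sizes <= max_size & sizes < N
  if (any(!usable)) {
    warning("skipping ", sum(!usable), " set(s) outside the usable size ",
            "range: ", paste(names(sets)[!usable], collapse = ", "))
  }
  restricted <- restricted[usable]
  sizes <- sizes[usable]
  if (length(restricted) == 0L) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), q = numeric(),
                      direction = character(), leading_edge = character(),
                      stringsAsFactors = FALSE))
  }

  # null ES per distinct set size (exhaustive when feasible)
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    n_comb <- choose(N, k)
    idx_sets <- if (is.finite(n_comb) && n_comb <= n_perm) {
      utils::combn(N, k, simplify = FALSE)
    } else {
      lapply(seq_len(n_perm), function(i) sample.int(N, k))
    }
    null_by_size[[as.character(k)]] <- vapply(idx_sets, function(ii) {
      hit <- logical(N); hit[ii] <- TRUE
      gsea_es(scores, hit, weight)
    }, numeric(1))
  }

  res <- lapply(names(restricted), function(nm) {
    hit <- genes %in% restricted[[nm]]
    es <- gsea_es(scores, hit, weight)
    null_es <- null_by_size[[as.character(sum(hit))]]
    pos <- null_es[null_es >= 0]
    neg <- null_es[null_es < 0]
    if (es >= 0) {
      p <- if (length(pos)) sum(pos >= es) / length(pos) else 1
      nes <- if (length(pos) && mean(pos) > 0) es / mean(pos) else NA_real_
    } else {
      p <- if (length(neg)) sum(neg <= es) / length(neg) else 1
      nes <- if (length(neg)) es / abs(mean(neg)) else NA_real_
    }
    # leading edge: set members at or before the running-sum extremum
    w <- abs(scores[hit])^weight
    inc <- numeric(N)
    inc[hit] <- if (sum(w) > 0) w / sum(w) else 1 / sum(hit)
    inc[!hit] <- -1 / (N - sum(hit))
    run <- cumsum(inc)
    peak <- which.max(abs(run))
    le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
    else genes[peak:N][hit[peak:N]]
    data.frame(set = nm, size = sum(hit), es = es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  # null NES pool: normalise every null ES by its size's same-sign mean
  null_nes <- unlist(lapply(names(null_by_size), function(k) {
    ne <- null_by_size[[k]]
    pos <- ne[ne >= 0]; neg <- ne[ne < 0]
    c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
      if (length(neg)) neg / abs(mean(neg)))
  }), use.names = FALSE)
  res$q <- vapply(seq_len(nrow(res)), function(i) {
    nes <- res$nes[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num_null <- mean(null_nes >= nes)
      den_null <- mean(null_nes >= 0)
      num_obs <- sum(res$nes >= nes, na.rm = TRUE)
      den_obs <- sum(res$nes >= 0, na.rm = TRUE)
    } else {
      num_null <- mean(null_nes <= nes)
      den_null <- mean(null_nes < 0)
      num_obs <- sum(res$nes <= nes, na.rm = TRUE)
      den_obs <- sum(res$nes < 0, na.rm = TRUE)
    }
    if (den_null == 0 || den_obs == 0 || num_obs == 0) return(NA_real_)
    min(1, (num_null / den_null) / (num_obs / den_obs))
  }, numeric(1))
  # monotone clean-up within each tail: a more extreme NES cannot have a
  # larger q than a less extreme one
  for (sgn in c(1, -1)) {
    tail_i <- which(sign(res$nes) == sgn | (sgn == 1 & res$nes == 0))
    if (length(tail_i) > 1L) {
      o <- tail_i[order(-sgn * res$nes[tail_i])]
      res$q[o] <- cummin(ifelse(is.na(res$q[o]), 1, res$q[o]))
    }
  }
  res$direction <- ifelse(res$es >= 0, "high-MV tail", "low-MV tail")
  res <- res[, c("set", "size", "es", "nes", "p", "q", "direction",
                 "leading_edge")]
  rownames(res) <- NULL
  res
}

#' Filter enrichment results on the significance convention
#'
#' Retains gene sets with nominal p <= `p_max` and FDR q <= `q_max`
#' simultaneously (defaults 0.01 and 0.25), split by tail.
#'
#' @param results data.frame from [gsea_preranked()].
#' @param p_max,q_max thresholds.
#' @return list `high` and `low`: the retained rows per direction.
#' @export
significant_sets <- function(results, p_max = 0.01, q_max = 0.25) {
  keep <- !is.na(results$p) & !is.na(results$q) &
    results$p <= p_max & results$q <= q_max
  sig <- results[keep, , drop = FALSE]
  list(high = sig[sig$direction == "high-MV tail", , drop = FALSE],
       low = sig[sig$direction == "low-MV tail", , drop = FALSE])
}
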