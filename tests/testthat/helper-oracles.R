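# Hand-built oracle fixtures shared across test files.

# A SNP strictly satisfying every criterion, from which violations are
# derived by perturbing one statistic at a time.
passing_record <- function(rsid = "rs1", chrom = "chr1", pos = 1000L) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             DAF = 0.10, GFHOM1 = 0.01, GFHET = 0.10, HWE2 = 0.001,
             HET = 0.3, PI = 0.2, DDAF = 0.3, TD = -1.0, FST1 = 0.10,
             UIHS = 2.0, UXPEHH = 1.5, XPCLR = 6,
             stringsAsFactors = FALSE)
}

# 24-row toy table: 12 passing rows, then one row per criterion violating
# exactly that criterion (boundary values included: strict comparisons)
toy_snp_table <- function() {
  passing <- do.call(rbind, lapply(1:12, function(i) {
    passing_record(sprintf("pass%02d", i), pos = 1000L + i)
  }))
  thr <- selection_thresholds()
  failing <- do.call(rbind, lapply(seq_len(nrow(thr)), function(i) {
    r <- passing_record(sprintf("fail_%s", thr$statistic[i]),
                        pos = 5000L + i)
    # set the statistic exactly to its cutoff: strictness means it fails
    r[[thr$statistic[i]]] <- thr$cutoff[i]
    r
  }))
  rbind(passing, failing)
}

# independent running-sum implementation used as the test oracle
es_oracle <- function(z, hit, weight = 1) {
  run <- 0; best <- 0
  tot <- sum(abs(z[hit])^weight)
  n_miss <- length(z) - sum(hit)
  for (i in seq_along(z)) {
    run <- run + if (hit[i]) abs(z[i])^weight / tot else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}

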