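test_that("the 12-criterion filter matches exhaustive enumeration", {
  snps <- toy_snp_table()
  got <- filter_dbpshp(snps)
  # independent enumeration: hand-written conjunction per row
  oracle <- with(snps, DAF > 0.05 & GFHOM1 > 0.001 & GFHET > 0.05 &
                   HWE2 > 0.0001 & HET < 0.5 & PI < 0.5 & DDAF > 0.2 &
                   TD < 0 & FST1 > 0.05 & UIHS > 1.5 & UXPEHH > 1 &
                   XPCLR > 5)
  expect_identical(got$rsid, snps$rsid[oracle])
  expect_equal(nrow(got), 12L)
  expect_true(all(grepl("^pass", got$rsid)))

  # per-criterion coverage: each single-violation row fails
  expect_false(any(grepl("^fail", got$rsid)))
})

test_that("filter edge cases: direction, missing values, bad thresholds", {
  r <- passing_record()
  expect_equal(nrow(filter_dbpshp(r)), 1L)
  r$TD <- 0.5
  expect_equal(nrow(filter_dbpshp(r)), 0L)
  r2 <- passing_record(); r2$UIHS <- NA
  expect_equal(nrow(filter_dbpshp(r2)), 0L)
  expect_equal(nrow(filter_dbpshp(passing_record()[0, ])), 0L)
  bad <- selection_thresholds()
  bad$statistic[1] <- "NOT_A_STAT"
  expect_error(filter_dbpshp(passing_record(), bad), "unknown|NOT_A_STAT")
})

test_that("SNP dataset merge dedups by rsid, preferring passing copies", {
  a <- do.call(rbind, lapply(1:3, function(i)
    passing_record(sprintf("rs%d", i), pos = i * 100L)))
  b <- do.call(rbind, lapply(4:7, function(i)
    passing_record(sprintf("rs%d", i), pos = i * 100L)))
  m <- merge_snp_datasets(a, b)
  expect_equal(nrow(m$snps), 7L)
  expect_equal(m$n_dedup, 0L)

  # identical sets: idempotent
  m2 <- merge_snp_datasets(a, a)
  expect_equal(nrow(m2$snps), 3L)
  expect_equal(m2$n_dedup, 3L)

  # 5 SNPs, 2 duplicated rsids where only one copy passes
  a3 <- rbind(passing_record("rs1", pos = 100L),
              passing_record("rs2", pos = 200L),
              passing_record("rs3", pos = 300L))
  a3$TD[1:2] <- 0.5                       # failing copies in set A
  b3 <- rbind(passing_record("rs1", pos = 100L),
              passing_record("rs2", pos = 200L))
  m3 <- merge_snp_datasets(a3, b3)
  expect_equal(nrow(m3$snps), 3L)
  expect_equal(m3$n_dedup, 2L)
  kept <- m3$snps[match(c("rs1", "rs2"), m3$snps$rsid), ]
  expect_true(all(kept$TD == -1.0))       # the passing copies won

  # conflicting positions are an error
  b4 <- passing_record("rs1", pos = 999L)
  expect_error(merge_snp_datasets(a3, b4), "conflicting")
})

test_that("RSP window assignment equals the all-pairs distance oracle", {
  manifest <- data.frame(probe = c("at_snp", "far"),
                         chrom = "chr1", pos = c(1000L, 6000L),
                         stringsAsFactors = FALSE)
  snps <- passing_record(pos = 1000L)
  rsp <- define_rsp_cpgs(snps, manifest, half_window = 1000L)
  expect_equal(rsp$rsp, c(TRUE, FALSE))
  expect_equal(rsp$support, c("rs1", ""))

  set.seed(55)
  manifest2 <- data.frame(probe = sprintf("cg%03d", 1:200),
                          chrom = sample(c("chr1", "chr2"), 200, TRUE),
                          pos = sample.int(50000, 200),
                          stringsAsFactors = FALSE)
  snps2 <- do.call(rbind, lapply(1:20, function(i)
    passing_record(sprintf("rs%d", i),
                   chrom = sample(c("chr1", "chr2"), 1),
                   pos = sample.int(50000, 1))))
  got <- define_rsp_cpgs(snps2, manifest2, half_window = 800L)
  oracle <- vapply(seq_len(nrow(manifest2)), function(i) {
    any(snps2$chrom == manifest2$chrom[i] &
          abs(snps2$pos - manifest2$pos[i]) <= 800L)
  }, logical(1))
  expect_equal(got$rsp, oracle)
})

test_that("bootstrap p matches exact enumeration on tiny instances", {
  # degenerate: identical MV values -> p = 1
  mv0 <- toy_mv_table(rep(0.3, 6))
  b0 <- bootstrap_mean_test(mv0, "p01", B = 200, seed = 1)
  expect_equal(b0$p, 1)

  # size-1 RSP over {0.1..0.5}: exact P(mean <= 0.1) = 1/5
  mv1 <- toy_mv_table(c(0.1, 0.2, 0.3, 0.4, 0.5))
  b1 <- bootstrap_mean_test(mv1, "p01", B = 10000, seed = 3)
  expect_lt(abs(b1$p - 0.2), 0.02)
  expect_equal(b1$p, (b1$count_le + 1) / (b1$B + 1))

  # exhaustive-enumeration bound on n = 8, |RSP| = 3
  set.seed(9)
  vals <- round(runif(8), 3)
  mv2 <- toy_mv_table(vals)
  rsp_ids <- mv2$probe[c(2, 5, 7)]
  obs <- mean(vals[c(2, 5, 7)])
  combos <- combn(8, 3)
  p_exact <- mean(apply(combos, 2, function(ii) mean(vals[ii])) <= obs)
  B <- 4000
  b2 <- bootstrap_mean_test(mv2, rsp_ids, B = B, seed = 11)
  expect_lte(abs(b2$p - p_exact),
             3 * sqrt(p_exact * (1 - p_exact) / B) + 2 / B)

  # determinism and seed sensitivity
  expect_identical(bootstrap_mean_test(mv2, rsp_ids, B = 500, seed = 4),
                   bootstrap_mean_test(mv2, rsp_ids, B = 500, seed = 4))
  ref_count <- bootstrap_mean_test(mv2, rsp_ids, B = 500, seed = 4)$count_le
  other <- vapply(5:9, function(s) {
    bootstrap_mean_test(mv2, rsp_ids, B = 500, seed = s)$count_le
  }, numeric(1))
  expect_false(all(other == ref_count))

  # domain errors
  expect_error(bootstrap_mean_test(mv1, character(0)), "subset")
  expect_error(bootstrap_mean_test(mv1, mv1$probe), "subset")
})

test_that("planted selection effect is detected, absent effect is not", {
  # sparse cluster-free design: the planted shrink is the only structure,
  # so the window-defined RSP group is exchangeable apart from the effect
  x <- sim_mv(sparse_null_config(seed = 61, n_probes = 500,
                                 genome_length = 800000,
                                 rsp_mv_shrink = 0.5))
  rsp <- define_rsp_cpgs(filter_dbpshp(x$sim$snps), x$manifest)
  b <- bootstrap_mean_test(x$mv, rsp$probe[rsp$rsp], B = 2000, seed = 1)
  expect_lt(b$p, 0.01)
  expect_lt(b$observed_mean, b$non_rsp_mean)

  # same design, no effect: not significant
  x0 <- sim_mv(sparse_null_config(seed = 62, n_probes = 500,
                                  genome_length = 800000))
  rsp0 <- define_rsp_cpgs(filter_dbpshp(x0$sim$snps), x0$manifest)
  b0 <- bootstrap_mean_test(x0$mv, rsp0$probe[rsp0$rsp], B = 2000,
                            seed = 1)
  expect_gt(b0$p, 0.01)
})

test_that("Welch comparison of conservation between RSP groups", {
  ann <- data.frame(probe = sprintf("p%d", 1:6), score = c(1, 2, 3, 1, 2, 3),
                    stringsAsFactors = FALSE)
  rsp <- data.frame(probe = ann$probe, rsp = rep(c(TRUE, FALSE), each = 3),
                    stringsAsFactors = FALSE)
  res <- gerp_compare_groups(ann, rsp)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # hand-applied Welch formula on {1,2,3} vs {4,5,6}
  ann2 <- data.frame(probe = ann$probe, score = 1:6,
                     stringsAsFactors = FALSE)
  res2 <- gerp_compare_groups(ann2, rsp)
  se <- sqrt(1 / 3 + 1 / 3)             # var = 1 in both groups, n = 3
  expect_equal(res2$statistic, (2 - 5) / se, tolerance = 1e-12)
  expect_equal(res2$df, 4, tolerance = 1e-9)

  expect_error(gerp_compare_groups(ann2[1:3, ], rsp), "at least 2")
})

test_that("conservation and selection plantings are independent", {
  # no planted link between GERP score and RSP membership: the group
  # comparison should reject at roughly the nominal rate
  ps <- vapply(1:40, function(i) {
    x <- sim_mv(sparse_null_config(seed = 700 + i))
    rsp <- define_rsp_cpgs(filter_dbpshp(x$sim$snps), x$manifest)
    ann <- gerp_lookup(x$sim$gerp, x$manifest)
    gerp_compare_groups(ann, rsp)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.85)
})
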