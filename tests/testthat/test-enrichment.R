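test_that("promoter mapping is symmetric and matches the oracle", {
  ann <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                    tss = c(5000L, 7000L), stringsAsFactors = FALSE)
  manifest <- data.frame(
    probe = c("at_tss", "edge", "outside", "shared"),
    chrom = "chr1", pos = c(5000L, 6500L, 6501L, 6200L),
    stringsAsFactors = FALSE)
  asn <- map_probes_to_promoters(ann, manifest, flank = 1500L)
  expect_true(all(c("at_tss", "edge") %in% asn$probe[asn$gene == "G1"]))
  expect_false("outside" %in% asn$probe[asn$gene == "G1"])
  # a probe within two windows is assigned to both genes
  expect_equal(sort(asn$gene[asn$probe == "shared"]), c("G1", "G2"))

  set.seed(77)
  ann2 <- data.frame(gene = sprintf("G%02d", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     tss = sample.int(60000, 30), stringsAsFactors = FALSE)
  manifest2 <- data.frame(probe = sprintf("cg%03d", 1:300),
                          chrom = sample(c("chr1", "chr2"), 300, TRUE),
                          pos = sample.int(60000, 300),
                          stringsAsFactors = FALSE)
  asn2 <- map_probes_to_promoters(ann2, manifest2)
  oracle <- do.call(rbind, lapply(seq_len(nrow(manifest2)), function(i) {
    hit <- ann2$chrom == manifest2$chrom[i] &
      abs(ann2$tss - manifest2$pos[i]) <= 1500L
    if (any(hit)) data.frame(probe = manifest2$probe[i],
                             gene = ann2$gene[hit])
  }))
  key <- function(d) sort(paste(d$probe, d$gene))
  expect_equal(key(asn2), key(oracle))
})

test_that("gene-level MV aggregates promoter probes", {
  asn <- data.frame(probe = c("p1", "p2", "p3", "p2"),
                    gene = c("A", "A", "B", "C"), stringsAsFactors = FALSE)
  mv <- toy_mv_table(c(0.1, 0.3, 0.5), probes = c("p1", "p2", "p3"))
  gm <- gene_mv(asn, mv)
  expect_equal(gm$x[gm$gene == "A"], 0.2)
  expect_equal(gm$x[gm$gene == "B"], 0.5)
  # shared probe contributes to both its genes
  expect_equal(gm$x[gm$gene == "C"], 0.3)
  expect_equal(gm$n_probes, c(2L, 1L, 1L))

  # genes whose probes were all filtered upstream are dropped and counted
  asn2 <- rbind(asn, data.frame(probe = "gone", gene = "D"))
  gm2 <- gene_mv(asn2, mv)
  expect_false("D" %in% gm2$gene)
  expect_equal(attr(gm2, "n_dropped_genes"), 1L)
})

test_that("z-scoring is exact and deterministically ordered", {
  gm <- data.frame(gene = c("b", "a", "c"), x = c(2, 1, 3),
                   stringsAsFactors = FALSE)
  rk <- zscore_rank(gm)
  expect_equal(rk$z, c(1, 0, -1))
  expect_equal(rk$gene, c("c", "b", "a"))

  set.seed(5)
  gm2 <- data.frame(gene = sprintf("g%03d", 1:200), x = runif(200))
  rk2 <- zscore_rank(gm2)
  expect_lt(abs(mean(rk2$z)), 1e-10)
  expect_lt(abs(sd(rk2$z) - 1), 1e-10)
  expect_false(is.unsorted(rev(rk2$z)))

  # ties break alphabetically
  gm3 <- data.frame(gene = c("zz", "aa", "mm"), x = c(1, 1, 2))
  expect_equal(zscore_rank(gm3)$gene, c("mm", "aa", "zz"))

  expect_error(zscore_rank(data.frame(gene = c("a", "b"), x = c(1, 1))),
               "identical")
})

test_that("GSEA core: exact ES and exhaustive permutation p on a toy list", {
  ranked <- data.frame(gene = LETTERS[1:6], z = c(3, 2, 1, -1, -2, -3),
                       stringsAsFactors = FALSE)
  res <- gsea_preranked(ranked, list(top2 = c("A", "B")), n_perm = 20,
                        min_size = 2, seed = 1)
  expect_equal(res$es, 1.0)
  expect_equal(res$direction, "high-MV tail")
  expect_equal(res$leading_edge, "A,B")

  # oracle: enumerate all C(6,2) = 15 same-size sets
  null_es <- apply(combn(6, 2), 2, function(ii) {
    hit <- logical(6); hit[ii] <- TRUE
    es_oracle(ranked$z, hit)
  })
  pos <- null_es[null_es >= 0]
  expect_equal(res$p, sum(pos >= 1.0) / length(pos))
  expect_equal(res$nes, 1.0 / mean(pos))

  # a set spanning the whole list is skipped
  expect_warning(
    res_all <- gsea_preranked(ranked, list(all = LETTERS[1:6]),
                              n_perm = 10, min_size = 2, seed = 1),
    "skipping")
  expect_equal(nrow(res_all), 0L)
})

test_that("ES stays in [-1, 1] and negates under score reversal", {
  set.seed(19)
  z <- sort(rnorm(40), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%02d", 1:40), z = z,
                       stringsAsFactors = FALSE)
  sets <- list(s1 = ranked$gene[c(1, 5, 9, 30)],
               s2 = ranked$gene[c(35, 38, 40)],
               s3 = sample(ranked$gene, 8))
  res <- gsea_preranked(ranked, sets, n_perm = 50, seed = 2)
  expect_true(all(res$es >= -1 & res$es <= 1))

  flipped <- data.frame(gene = rev(ranked$gene), z = rev(-ranked$z),
                        stringsAsFactors = FALSE)
  res_f <- gsea_preranked(flipped, sets, n_perm = 50, seed = 2)
  expect_equal(res_f$es[match(res$set, res_f$set)], -res$es,
               tolerance = 1e-12)
})

test_that("ES agrees with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  z <- sort(rnorm(60), decreasing = TRUE)
  for (k in c(3, 7, 15)) {
    idx <- sort(sample.int(60, k))
    hit <- logical(60); hit[idx] <- TRUE
    expect_equal(methvar:::gsea_es(z, hit, weight = 1),
                 fgsea::calcGseaStat(z, idx, gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("planted gene sets are recovered on synthetic data", {
  x <- sim_mv(medium_config(seed = 81))
  asn <- map_probes_to_promoters(x$sim$genes, x$manifest)
  ranked <- zscore_rank(gene_mv(asn, x$mv))
  res <- suppressWarnings(gsea_preranked(ranked, x$sim$gmt,
                                         n_perm = 500, seed = 3))
  hi <- res[res$set == "PLANTED_HIGH_MV", ]
  lo <- res[res$set == "PLANTED_LOW_MV", ]
  expect_equal(hi$direction, "high-MV tail")
  expect_equal(lo$direction, "low-MV tail")
  expect_lte(hi$p, 0.05)
  expect_lte(lo$p, 0.05)
})

test_that("significance filter enforces both thresholds", {
  res <- data.frame(
    set = c("a", "b", "c", "d"), size = 5, es = c(0.8, 0.7, -0.6, 0.5),
    nes = c(2, 1.8, -1.5, 1.2), p = c(0.005, 0.005, 0.002, 0.2),
    q = c(0.1, 0.3, 0.2, 0.01),
    direction = c("high-MV tail", "high-MV tail", "low-MV tail",
                  "high-MV tail"),
    leading_edge = "", stringsAsFactors = FALSE)
  sig <- significant_sets(res)
  expect_equal(sig$high$set, "a")   # b fails q, d fails p
  expect_equal(sig$low$set, "c")
  empty <- significant_sets(res[0, ])
  expect_equal(nrow(empty$high) + nrow(empty$low), 0L)
})
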