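make_metadata <- function(n_m, n_f, ages_m, ages_f, status = "healthy") {
  data.frame(
    sample = sprintf("S%03d", seq_len(n_m + n_f)),
    sex = rep(c("M", "F"), c(n_m, n_f)),
    age = c(ages_m, ages_f),
    status = status, stringsAsFactors = FALSE)
}

test_that("cohort selection pairs by greedy nearest age", {
  md <- make_metadata(5, 3, ages_m = 40:44, ages_f = c(40, 50, 60))
  ids <- select_cohort(md, n_per_sex = 3, age_min = 30, age_max = 70)
  pairs <- attr(ids, "pairs")
  # greedy: (40,40) gap 0, then (44,50) gap 6, then (43,60) gap 17
  expect_equal(pairs$age_male, c(40, 44, 43))
  expect_equal(pairs$age_female, c(40, 50, 60))
  expect_equal(pairs$gap, c(0, 6, 17))
  expect_length(ids, 6)
})

test_that("cohort selection returns the requested 83 + 83 when available", {
  md <- make_metadata(83, 83, ages_m = rep(36:65, length.out = 83),
                      ages_f = rep(36:65, length.out = 83))
  ids <- select_cohort(md, n_per_sex = 83)
  expect_length(ids, 166)
})

test_that("cohort selection errors and shortfalls are reported", {
  md <- make_metadata(4, 4, 40:43, 40:43, status = "other")
  expect_error(select_cohort(md, 2), "eligible")
  md2 <- make_metadata(5, 2, 40:44, c(41, 42))
  expect_message(ids <- select_cohort(md2, n_per_sex = 4, age_min = 30,
                                      age_max = 70), "2 of 4")
  expect_length(ids, 4)
  # exclusion list removes samples before eligibility
  md3 <- make_metadata(2, 2, c(40, 41), c(40, 41))
  ids3 <- select_cohort(md3, 2, age_min = 30, age_max = 70,
                        exclude = c("S001", "S003"))
  expect_length(ids3, 2)
})

toy_filter_fixture <- function() {
  probes <- sprintf("p%02d", 1:10)
  manifest <- data.frame(
    probe = probes,
    chrom = c("chrX", "chrX", rep("chr1", 8)),
    pos = 1:10 * 100L,
    snp_overlap = probes == "p03",
    cross_reactive = probes == "p04",
    stringsAsFactors = FALSE)
  beta <- matrix(0.5, nrow = 10, ncol = 4,
                 dimnames = list(probes, paste0("S", 1:4)))
  beta["p05", 2] <- NA
  list(manifest = manifest, beta = beta)
}

test_that("probe filtering applies every exclusion rule", {
  fx <- toy_filter_fixture()
  fp <- filter_probes(fx$manifest, fx$beta)
  expect_equal(fp$retained, sprintf("p%02d", 6:10))
  expect_equal(unname(fp$tally[c("sex_chromosome", "snp_overlap",
                                 "cross_reactive", "missing_values")]),
               c(2L, 1L, 1L, 1L))
  expect_gte(sum(fp$tally[1:4]), fp$tally[["excluded"]])

  # idempotence: filtering the retained set changes nothing
  fp2 <- filter_probes(fx$manifest, fx$beta[fp$retained, ])
  expect_equal(fp2$retained, fp$retained)
  expect_equal(fp2$tally[["excluded"]], 0L)

  # all-clean identity
  clean <- fx$beta[6:10, ]
  expect_equal(filter_probes(fx$manifest, clean)$retained, rownames(clean))

  # manifest must cover the beta matrix
  expect_error(filter_probes(fx$manifest[-1, ], fx$beta), "absent")
})

test_that("MV computation matches the sample-SD formula", {
  beta <- rbind(p1 = c(0.2, 0.4, 0.6), p2 = c(0.3, 0.3, 0.3))
  colnames(beta) <- paste0("S", 1:3)
  mv <- compute_mv(beta)
  expect_equal(mv$mv[mv$probe == "p1"], 0.2)
  expect_equal(mv$mv[mv$probe == "p2"], 0)
  expect_equal(mv$variance, mv$mv^2, tolerance = 1e-15)

  # two-pass oracle agreement on random data
  set.seed(42)
  x <- matrix(runif(600), 60, 10,
              dimnames = list(sprintf("p%02d", 1:60), paste0("S", 1:10)))
  mvx <- compute_mv(x)
  expect_equal(mvx$mv, unname(apply(x, 1, sd)), tolerance = 1e-12)
  expect_equal(mvx$mean, unname(rowMeans(x)), tolerance = 1e-12)

  # contract violations
  x[1, 1] <- NA
  expect_error(compute_mv(x), "missing")
  expect_error(compute_mv(beta[, 1, drop = FALSE]), "2 samples")
})

test_that("cell-composition flags catch large shifted probes only", {
  set.seed(7)
  n <- 6
  groups <- rep(c("PBMC", "CD4T"), each = n)
  flat <- matrix(0.5 + rnorm(2 * n * 3, sd = 0.01), nrow = 3)
  shifted <- rbind(c(rep(0.1, n), rep(0.9, n)) + rnorm(2 * n, sd = 0.01))
  panel <- rbind(flat, shifted)
  rownames(panel) <- c("flat1", "flat2", "flat3", "shifted")
  flags <- cell_composition_flags(panel, groups)
  expect_equal(as.character(flags), "shifted")
  expect_equal(unname(attr(flags, "per_type")), 1L)

  # per-probe statistic agrees with t.test on the same data
  tt <- t.test(panel["shifted", groups == "CD4T"],
               panel["shifted", groups == "PBMC"], var.equal = TRUE)
  expect_lt(tt$p.value, 1e-07)

  expect_error(cell_composition_flags(panel, rep("PBMC", 12)),
               "cell type")
  expect_error(cell_composition_flags(panel[, 1:7],
                                      c(rep("PBMC", 6), "CD4T")),
               "2 samples")
})
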