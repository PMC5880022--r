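# Cohort selection, probe filtering and the MV statistic.
#
# MV (methylation variability) is the sample standard deviation of a
# probe's beta-values across individuals. Only complete-case probes enter
# the MV table; sex-chromosome, SNP-overlapping and cross-reactive probes
# are excluded first.

#' Select an age-matched healthy cohort
#'
#' Picks up to `n_per_sex` healthy males and the same number of healthy
#' females within the age range, matched by greedy nearest-age pairing
#' without replacement: repeatedly take the male-female pair with the
#' smallest absolute age difference (ties broken by younger age, then
#' sample ID) until `n_per_sex` pairs are formed or one sex is exhausted.
#' If fewer pairs than requested exist the maximum achievable is returned,
#' with a message.
#'
#' @param metadata data.frame with `sample`, `sex` (`"M"`/`"F"`), `age`,
#'   `status` (`"healthy"` or other).
#' @param n_per_sex number of pairs requested.
#' @param age_min,age_max inclusive age range.
#' @param exclude optional character vector of sample IDs to drop first
#'   (e.g. externally flagged age/sex discrepancies).
#' @return character vector of selected sample IDs (males and females
#'   interleaved by pair), with attribute `pairs` (data.frame of the
#'   matched pairs and their age gaps).
#' @export
select_cohort <- function(metadata, n_per_sex, age_min = 36, age_max = 65,
                          exclude = character()) {
  stopifnot(is.data.frame(metadata), nrow(metadata) > 0,
            all(c("sample", "sex", "age", "status") %in% names(metadata)),
            !anyDuplicated(metadata$sample), all(metadata$age > 0))
  md <- metadata[!(metadata$sample %in% exclude), , drop = FALSE]
  elig <- md[md$status == "healthy" & md$age >= age_min &
               md$age <= age_max, , drop = FALSE]
  males <- elig[elig$sex == "M", , drop = FALSE]
  females <- elig[elig$sex == "F", , drop = FALSE]
  if (nrow(males) == 0L || nrow(females) == 0L) {
    stop("no eligible healthy samples of one sex in the age range",
         call. = FALSE)
  }
  pairs <- list()
  while (length(pairs) < n_per_sex && nrow(males) > 0L &&
         nrow(females) > 0L) {
    d <- abs(outer(males$age, females$age, "-"))
    # smallest gap; ties: younger pair, then sample IDs
    cand <- which(d == min(d), arr.ind = TRUE)
    key <- order(pmin(males$age[cand[, 1]], females$age[cand[, 2]]),
                 males$sample[cand[, 1]], females$sample[cand[, 2]])
    i <- cand[key[1], 1]; j <- cand[key[1], 2]
    pairs[[length(pairs) + 1L]] <- data.frame(
      male = males$sample[i], female = females$sample[j],
      age_male = males$age[i], age_female = females$age[j],
      gap = abs(males$age[i] - females$age[j]), stringsAsFactors = FALSE)
    males <- males[-i, , drop = FALSE]
    females <- females[-j, , drop = FALSE]
  }
  pairs <- do.call(rbind, pairs)
  if (nrow(pairs) < n_per_sex) {
    message("only ", nrow(pairs), " of ", n_per_sex,
            " requested pairs could be formed")
  }
  ids <- as.vector(rbind(pairs$male, pairs$female))
  attr(ids, "pairs") <- pairs
  ids
}

#' Filter probes before MV computation
#'
#' Retains probes that are autosomal, not SNP-overlapping, not
#' cross-reactive, and complete-case (no missing beta-value) across the
#' supplied samples. The exclusion tally counts a probe under every reason
#' it triggers, so tallies may sum to more than the number of excluded
#' probes.
#'
#' @param manifest probe manifest (`probe`, `chrom`, `pos`, `snp_overlap`,
#'   `cross_reactive`); must cover every probe of `beta`.
#' @param beta probes x samples numeric matrix (rownames = probe IDs),
#'   `NA` for missing.
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @param samples optional sample IDs (columns) to restrict the
#'   missing-value check to; default all columns.
#' @return list with `retained` (character vector of probe IDs, in beta
#'   row order) and `tally` (named integer vector of exclusion counts).
#' @export
filter_probes <- function(manifest, beta, sex_chroms = c("chrX", "chrY"),
                          samples = colnames(beta)) {
  probes <- rownames(beta)
  if (!all(probes %in% manifest$probe)) {
    stop("beta matrix contains probes absent from the manifest",
         call. = FALSE)
  }
  mf <- manifest[match(probes, manifest$probe), , drop = FALSE]
  sex <- mf$chrom %in% sex_chroms
  snp <- as.logical(mf$snp_overlap)
  xr <- as.logical(mf$cross_reactive)
  miss <- rowSums(is.na(beta[, samples, drop = FALSE])) > 0L
  drop <- sex | snp | xr | miss
  list(
    retained = probes[!drop],
    tally = c(sex_chromosome = sum(sex), snp_overlap = sum(snp),
              cross_reactive = sum(xr), missing_values = sum(miss),
              excluded = sum(drop), retained = sum(!drop))
  )
}

#' Compute the MV table
#'
#' Per-probe mean, sample variance and sample standard deviation (the MV
#' statistic; `n - 1` denominator) of beta-values across samples. Input
#' probes must be complete-case — missing values violate the contract and
#' raise an error.
#'
#' @param beta probes x samples numeric matrix.
#' @param probe_ids probes to include (default all rows).
#' @param samples optional column subset.
#' @return data.frame `probe`, `mean`, `variance`, `mv`.
#' @export
compute_mv <- function(beta, probe_ids = rownames(beta),
                       samples = colnames(beta)) {
  x <- beta[probe_ids, samples, drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 samples to compute variance",
                         call. = FALSE)
  if (anyNA(x)) stop("beta values contain missing entries; filter to ",
                     "complete-case probes first", call. = FALSE)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (ncol(x) - 1L)
  data.frame(probe = probe_ids, mean = unname(m), variance = unname(v),
             mv = unname(sqrt(v)), stringsAsFactors = FALSE)
}

#' Flag probes driven by blood cell composition
#'
#' For every purified cell type in the reference panel, fits a per-probe
#' two-group comparison (that cell type vs PBMC) as an ordinary
#' pooled-variance linear model — equivalent to a per-probe equal-variance
#' t-test — and flags the probe when `p < p_threshold` and
#' `|mean difference| > delta_threshold` for at least one cell type.
#' Flags are report-only: the pipeline's default analysis proceeds without
#' removing them.
#'
#' @param panel_beta probes x reference-samples beta matrix.
#' @param groups character vector (one per column) of cell-type labels;
#'   must contain `pbmc_label` and at least one other group, each with at
#'   least 2 samples.
#' @param p_threshold,delta_threshold the flagging thresholds (defaults
#'   1e-07 and 0.05).
#' @param pbmc_label label of the mixed-cell reference group.
#' @return character vector of flagged probe IDs (union over cell types),
#'   with attribute `per_type` (named integer counts).
#' @export
cell_composition_flags <- function(panel_beta, groups, p_threshold = 1e-07,
                                   delta_threshold = 0.05,
                                   pbmc_label = "PBMC") {
  stopifnot(ncol(panel_beta) == length(groups))
  if (!pbmc_label %in% groups) stop("panel must contain a ", pbmc_label,
                                    " group", call. = FALSE)
  types <- setdiff(unique(groups), pbmc_label)
  if (length(types) == 0L) stop("panel needs at least one cell type ",
                                "besides ", pbmc_label, call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2L)) stop("every group needs at least 2 samples",
                          call. = FALSE)
  ref <- panel_beta[, groups == pbmc_label, drop = FALSE]
  n2 <- ncol(ref)
  m2 <- rowMeans(ref)
  ss2 <- rowSums((ref - m2)^2)
  flagged <- character(0)
  per_type <- integer(length(types)); names(per_type) <- types
  for (ty in types) {
    x <- panel_beta[, groups == ty, drop = FALSE]
    n1 <- ncol(x)
    m1 <- rowMeans(x)
    ss1 <- rowSums((x - m1)^2)
    df <- n1 + n2 - 2L
    sp2 <- (ss1 + ss2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    hit <- !is.na(p) & p < p_threshold & abs(m1 - m2) > delta_threshold
    per_type[ty] <- sum(hit)
    flagged <- union(flagged, rownames(panel_beta)[hit])
  }
  structure(flagged, per_type = per_type)
}
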