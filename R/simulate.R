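# Synthetic-data generator.
#
# Emulates every input the pipeline consumes — a genome with planted
# CpG-dense clusters, an array-style beta-value matrix with sample
# metadata and a probe manifest, a base-resolution conservation track, a
# SNP table carrying the 12 recent-selection statistics, TSS annotation
# and gene sets — with planted couplings: HC < IC < LC dispersion,
# conserved sites with shrunk dispersion, shrunk dispersion inside
# selected-SNP windows, and designated high-MV / low-MV gene sets.

#' Simulation configuration
#'
#' Collects and validates all generator parameters. Dispersion parameters
#' (`hc_mv_sd` < `ic_mv_sd` < `lc_mv_sd`) set the target per-probe
#' standard deviation of beta-values by density class; each probe's actual
#' target SD is additionally scaled by `4*m*(1-m)` of its true mean
#' `m` (so intermediate-methylation probes are the most variable),
#' multiplied by `rsp_mv_shrink` inside selected-SNP windows, and by
#' `1 - gerp_mv_slope * score/6.18` for positively conserved probes.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_samples,n_probes cohort size and number of array probes.
#' @param genome_length length of the main autosomal contig (bp).
#' @param n_hc,n_ic number of planted high-/intermediate-density clusters.
#' @param hc_mv_sd,ic_mv_sd,lc_mv_sd class dispersion parameters
#'   (beta-value SD scale; must be strictly increasing).
#' @param frac_missing fraction of beta entries masked as missing.
#' @param n_genes,n_snps number of genes and SNP records.
#' @param frac_selected_snps fraction of SNPs passing all 12
#'   recent-selection criteria by construction.
#' @param rsp_mv_shrink multiplicative dispersion factor in (0,1] for
#'   probes inside selected-SNP windows (0.77 plants a ~23% MV reduction).
#' @param conserved_frac fraction of probes given a positive conservation
#'   score.
#' @param gerp_mv_slope strength of the planted negative
#'   conservation-dispersion coupling (0 = none).
#' @return an object of class `methvar_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_samples = 50L, n_probes = 5000L,
                       genome_length = 1e6, n_hc = 40L, n_ic = 50L,
                       hc_mv_sd = 0.010, ic_mv_sd = 0.030, lc_mv_sd = 0.050,
                       frac_missing = 0.001, n_genes = 60L, n_snps = 200L,
                       frac_selected_snps = 0.25, rsp_mv_shrink = 0.77,
                       conserved_frac = 0.4, gerp_mv_slope = 0.8) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              genome_length = as.integer(genome_length),
              n_hc = as.integer(n_hc), n_ic = as.integer(n_ic),
              hc_mv_sd = hc_mv_sd, ic_mv_sd = ic_mv_sd, lc_mv_sd = lc_mv_sd,
              frac_missing = frac_missing, n_genes = as.integer(n_genes),
              n_snps = as.integer(n_snps),
              frac_selected_snps = frac_selected_snps,
              rsp_mv_shrink = rsp_mv_shrink,
              conserved_frac = conserved_frac,
              gerp_mv_slope = gerp_mv_slope)
  with(cfg, {
    stopifnot(n_samples > 0L, n_probes > 0L, genome_length > 0L,
              n_hc >= 0L, n_ic >= 0L, n_genes > 0L, n_snps > 0L,
              frac_missing >= 0, frac_missing < 1,
              frac_selected_snps >= 0, frac_selected_snps <= 1,
              conserved_frac >= 0, conserved_frac <= 1,
              hc_mv_sd >= 0, hc_mv_sd < ic_mv_sd, ic_mv_sd < lc_mv_sd,
              rsp_mv_shrink > 0, rsp_mv_shrink <= 1)
  })
  structure(cfg, class = "methvar_sim_config")
}

# iid sequence with the given per-base probabilities (A, C, G, T order)
random_seq <- function(n, probs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
}

BG_PROBS <- c(0.42, 0.08, 0.08, 0.42)  # AT-rich, low-CpG background
HC_PROBS <- c(0.175, 0.325, 0.325, 0.175)
IC_PROBS <- c(0.23, 0.27, 0.27, 0.23)
SEX_PROBS <- c(0.40, 0.10, 0.10, 0.40) # sex contigs, modest CpG supply
MIN_GAP <- 300L                        # bp of background between clusters

# Generate one cluster block and verify its class with a safety margin so
# window-based discovery (which may clip < 60 bp at the edges) still
# recovers it; rejection-sample until the margin holds.
plant_block <- function(len, class) {
  for (i in 1:200) {
    x <- random_seq(len, if (class == "HC") HC_PROBS else IC_PROBS)
    gc <- mean(x %in% c("C", "G"))
    oe <- obs_exp_ratio(paste(x, collapse = ""))
    ok <- if (class == "HC") gc > 0.57 && oe > 0.80 else
      gc > 0.52 && gc < 0.60 && oe > 0.55
    if (ok) return(x)
  }
  stop("could not generate a ", class, " block of length ", len,
       call. = FALSE)
}

#' Simulate a genome with planted CpG clusters
#'
#' Builds a main contig (`chr1`) of AT-rich background with `n_hc` planted
#' blocks satisfying the HC criteria and `n_ic` blocks satisfying IC (but
#' not HC, by construction: their length is kept below 500 bp), plus small
#' `chrX`/`chrY` contigs to exercise the sex-chromosome probe filter.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of sequences) and
#'   `regions` (truth data.frame of planted intervals: `chrom`, `start`,
#'   `end` 0-based half-open, `length`, `gc_content`, `obs_exp`, `class`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "methvar_sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n_blk <- config$n_hc + config$n_ic
  lens <- integer(0)
  cls <- character(0)
  if (n_blk > 0L) {
    lens <- c(sample(520:700, config$n_hc, replace = TRUE),
              sample(280:460, config$n_ic, replace = TRUE))
    cls <- c(rep("HC", config$n_hc), rep("IC", config$n_ic))
    ord <- sample.int(n_blk)
    lens <- lens[ord]; cls <- cls[ord]
    if (config$genome_length < 10L * max(lens)) {
      stop("genome_length must be at least 10x the largest planted cluster",
           call. = FALSE)
    }
  }
  extra <- config$genome_length - sum(lens) - MIN_GAP * (n_blk + 1L)
  if (extra < 0L) {
    stop("clusters cannot fit: increase genome_length or reduce clusters",
         call. = FALSE)
  }
  w <- stats::runif(n_blk + 1L)
  gaps <- MIN_GAP + floor(extra * w / sum(w))
  gaps[n_blk + 1L] <- config$genome_length - sum(lens) - sum(gaps[-(n_blk + 1L)])
  pieces <- vector("list", 2L * n_blk + 1L)
  regions <- vector("list", n_blk)
  pos <- 0L
  for (i in seq_len(n_blk + 1L)) {
    pieces[[2L * i - 1L]] <- random_seq(gaps[i], BG_PROBS)
    pos <- pos + gaps[i]
    if (i <= n_blk) {
      blk <- plant_block(lens[i], cls[i])
      pieces[[2L * i]] <- blk
      regions[[i]] <- data.frame(
        chrom = "chr1", start = pos, end = pos + lens[i],
        length = lens[i], gc_content = mean(blk %in% c("C", "G")),
        obs_exp = obs_exp_ratio(paste(blk, collapse = "")),
        class = cls[i], stringsAsFactors = FALSE)
      pos <- pos + lens[i]
    }
  }
  genome <- c(
    chr1 = paste(unlist(pieces), collapse = ""),
    chrX = paste(random_seq(20000L, SEX_PROBS), collapse = ""),
    chrY = paste(random_seq(8000L, SEX_PROBS), collapse = "")
  )
  regions <- if (n_blk > 0L) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), gc_content = numeric(),
               obs_exp = numeric(), class = character(),
               stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  list(genome = genome, regions = regions)
}

# 1-based positions of the C of every CpG dinucleotide in a sequence string
cpg_positions <- function(seq_string) {
  x <- strsplit(seq_string, "", fixed = TRUE)[[1]]
  which(x[-length(x)] == "C" & x[-1L] == "G")
}

#' Simulate the beta-value matrix, metadata and probe manifest
#'
#' Probes are placed at actual CpG dinucleotide positions of the simulated
#' genome — stratified so that high- and intermediate-density clusters are
#' over-represented, as on methylation arrays — plus a small quota on the
#' sex contigs. Each probe gets a true mean beta (class-dependent: HC
#' probes hypomethylated, LC hypermethylated, IC intermediate) and a
#' target dispersion combining the class parameter, the
#' intermediate-methylation peak factor `2*sqrt(m*(1-m))`, the
#' conservation coupling and the selected-window shrink; beta-values are
#' drawn from a Beta distribution with that mean and SD, then
#' `frac_missing` entries are masked. Gene TSS anchors and the planted
#' high-/low-MV gene memberships are also fixed here so that dispersion
#' boosts can be applied to promoter probes.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_genome()].
#' @return list with `beta` (probes x samples matrix, NAs where masked),
#'   `metadata` (sample, sex, age, status), `manifest` (probe, chrom, pos,
#'   snp_overlap, cross_reactive), `probe_truth` (per-probe class, true
#'   mean, dispersion, conservation score, RSP flag), `genes`,
#'   `gene_sets` (list: planted high/low + names), and `selected_snps`
#'   (positions of the planted passing SNPs).
#' @export
simulate_betas <- function(config, truth) {
  stopifnot(inherits(config, "methvar_sim_config"),
            is.list(truth), !is.null(truth$genome))
  set.seed(derive_seed(config$seed, 2L))
  gen <- truth$genome

  pos1 <- cpg_positions(gen[["chr1"]])
  cand <- data.frame(chrom = "chr1", pos = pos1, stringsAsFactors = FALSE)
  idx <- interval_lookup(cand$chrom, cand$pos - 1L, truth$regions)
  cand$class <- ifelse(is.na(idx), "LC", truth$regions$class[idx])

  n_sex <- min(round(0.02 * config$n_probes),
               length(cpg_positions(gen[["chrX"]])) +
                 length(cpg_positions(gen[["chrY"]])))
  n_auto <- config$n_probes - n_sex
  if (nrow(cand) < n_auto) {
    stop("synthetic genome has too few CpG sites for n_probes",
         call. = FALSE)
  }
  # array-like stratification: oversample clusters relative to genome share
  want <- c(HC = round(0.22 * n_auto), IC = round(0.26 * n_auto))
  take <- integer(0)
  for (cl in c("HC", "IC")) {
    avail <- which(cand$class == cl)
    take <- c(take, if (length(avail) <= want[[cl]]) avail else
      sample(avail, want[[cl]]))
  }
  rest <- setdiff(which(cand$class == "LC"), take)
  if (length(rest) < n_auto - length(take)) {
    rest <- setdiff(seq_len(nrow(cand)), take)
  }
  take <- c(take, sample(rest, n_auto - length(take)))
  probes_auto <- cand[sort(take), , drop = FALSE]

  sex_tab <- do.call(rbind, lapply(c("chrX", "chrY"), function(ch) {
    p <- cpg_positions(gen[[ch]])
    data.frame(chrom = ch, pos = p, class = "LC", stringsAsFactors = FALSE)
  }))
  probes_sex <- sex_tab[sort(sample(nrow(sex_tab), n_sex)), , drop = FALSE]

  probes <- rbind(probes_auto, probes_sex)
  probes$probe <- sprintf("cg%08d", seq_len(nrow(probes)))
  n <- nrow(probes)

  manifest <- data.frame(
    probe = probes$probe, chrom = probes$chrom, pos = probes$pos,
    snp_overlap = stats::runif(n) < 0.02,
    cross_reactive = stats::runif(n) < 0.02,
    stringsAsFactors = FALSE)

  # class-dependent true means: clusters hypomethylated, open sea high
  m <- numeric(n)
  m[probes$class == "HC"] <- stats::rbeta(sum(probes$class == "HC"), 2, 22)
  m[probes$class == "IC"] <- stats::rbeta(sum(probes$class == "IC"), 3, 3)
  m[probes$class == "LC"] <- stats::rbeta(sum(probes$class == "LC"), 7, 2.5)
  m <- pmin(pmax(m, 0.005), 0.995)

  class_sd <- c(HC = config$hc_mv_sd, IC = config$ic_mv_sd,
                LC = config$lc_mv_sd)
  # inverted-U mean-dispersion coupling: variability peaks at
  # intermediate methylation and is strongly suppressed near 0 and 1
  s <- class_sd[probes$class] * 4 * m * (1 - m)

  # conservation coupling: a fixed fraction of probes positively conserved,
  # with dispersion shrinking linearly in the score
  gerp <- stats::runif(n, min = -12.36, max = -0.01)
  n_cons <- round(config$conserved_frac * n)
  cons_idx <- sample.int(n, n_cons)
  gerp[cons_idx] <- stats::runif(n_cons, min = 0.01, max = 6.18)
  s <- s * ifelse(gerp > 0, 1 - config$gerp_mv_slope * gerp / 6.18, 1)

  # recent-selection coupling: passing SNPs anchored near autosomal
  # probes. Anchor windows capture every probe within +/-1000 bp, so
  # naive uniform anchoring would over-sample CpG-dense (low-MV) regions
  # and confound the planted selection effect with the density effect.
  # Anchors are therefore allocated per density class in proportion to
  # the class's effective number of windows (probes / mean window
  # capture) and drawn within class with probability inversely
  # proportional to local capture — making window coverage approximately
  # uniform over probes, with low composition variance across runs.
  n_sel <- round(config$frac_selected_snps * config$n_snps)
  auto_idx <- which(probes$chrom == "chr1")
  apos <- probes$pos[auto_idx]
  local_n <- findInterval(apos + 1000L, apos) -
    findInterval(apos - 1001L, apos)
  acls <- probes$class[auto_idx]
  eff_windows <- tapply(local_n, acls, function(cn) length(cn) / mean(cn))
  eff_windows <- eff_windows[!is.na(eff_windows)]
  alloc <- round(n_sel * eff_windows / sum(eff_windows))
  if (sum(alloc) != n_sel && length(alloc) > 0L) {
    big <- which.max(eff_windows)
    alloc[big] <- alloc[big] + (n_sel - sum(alloc))
  }
  sel_anchor <- unlist(lapply(names(alloc), function(cl) {
    ii <- which(acls == cl)
    k <- max(0L, min(alloc[[cl]], length(ii)))
    if (k == 0L) return(integer(0))
    auto_idx[ii][sample.int(length(ii), k, prob = 1 / local_n[ii])]
  }), use.names = FALSE)
  selected_snps <- data.frame(
    chrom = probes$chrom[sel_anchor],
    pos = probes$pos[sel_anchor] + sample(-200:200, length(sel_anchor),
                                          replace = TRUE),
    stringsAsFactors = FALSE)
  selected_snps$pos <- pmax(selected_snps$pos, 1L)
  rsp <- rep(FALSE, n)
  if (nrow(selected_snps) > 0L) {
    for (ch in unique(selected_snps$chrom)) {
      sp <- sort(selected_snps$pos[selected_snps$chrom == ch])
      pr <- which(probes$chrom == ch)
      k <- findInterval(probes$pos[pr], sp)
      d_lo <- ifelse(k > 0L, probes$pos[pr] - sp[pmax(k, 1L)], Inf)
      d_hi <- ifelse(k < length(sp), sp[pmin(k + 1L, length(sp))] -
                       probes$pos[pr], Inf)
      rsp[pr[pmin(d_lo, d_hi) <= 1000L]] <- TRUE
    }
  }
  s[rsp] <- s[rsp] * config$rsp_mv_shrink

  # gene anchors: well-separated autosomal probes; first block of genes is
  # the planted high-MV set, second the planted low-MV set
  ord <- sample(auto_idx)
  anchors <- integer(0)
  for (i in ord) {
    if (length(anchors) >= config$n_genes) break
    if (all(abs(probes$pos[anchors] - probes$pos[i]) >= 4000L)) {
      anchors <- c(anchors, i)
    }
  }
  genes <- data.frame(
    gene = sprintf("GENE%03d", seq_along(anchors)),
    chrom = probes$chrom[anchors],
    tss = probes$pos[anchors] + sample(-300:300, length(anchors),
                                       replace = TRUE),
    strand = sample(c("+", "-"), length(anchors), replace = TRUE),
    stringsAsFactors = FALSE)
  genes$tss <- pmax(genes$tss, 1L)
  n_set <- max(1L, min(10L, floor(length(anchors) / 4)))
  high_genes <- genes$gene[seq_len(n_set)]
  low_genes <- genes$gene[n_set + seq_len(min(n_set, nrow(genes) - n_set))]
  for (g in seq_len(nrow(genes))) {
    hit <- probes$chrom == genes$chrom[g] &
      abs(probes$pos - genes$tss[g]) <= 1500L
    if (genes$gene[g] %in% high_genes) s[hit] <- s[hit] * 2.2
    if (genes$gene[g] %in% low_genes) s[hit] <- s[hit] * 0.35
  }

  # bounded beta draws with target (mean, sd); sd clamped inside the
  # feasible region of the Beta family
  s <- pmin(s, 0.8 * sqrt(m * (1 - m)))
  beta <- matrix(NA_real_, nrow = n, ncol = config$n_samples,
                 dimnames = list(probes$probe,
                                 sprintf("S%03d", seq_len(config$n_samples))))
  pos_s <- s > 0
  v <- m[pos_s] * (1 - m[pos_s]) / s[pos_s]^2 - 1
  a <- rep(m[pos_s] * v, config$n_samples)
  b <- rep((1 - m[pos_s]) * v, config$n_samples)
  beta[pos_s, ] <- stats::rbeta(sum(pos_s) * config$n_samples, a, b)
  beta[!pos_s, ] <- m[!pos_s]
  if (config$frac_missing > 0) {
    mask <- stats::runif(length(beta)) < config$frac_missing
    beta[mask] <- NA_real_
  }

  n_samp <- config$n_samples
  metadata <- data.frame(
    sample = colnames(beta),
    sex = rep_len(c("M", "F"), n_samp),
    age = sample(30:70, n_samp, replace = TRUE),
    status = sample(c("healthy", "other"), n_samp, replace = TRUE,
                    prob = c(0.92, 0.08)),
    stringsAsFactors = FALSE)

  probe_truth <- data.frame(
    probe = probes$probe, chrom = probes$chrom, pos = probes$pos,
    class = probes$class, true_mean = m, dispersion = unname(s),
    gerp_score = gerp, rsp = rsp, stringsAsFactors = FALSE)

  list(beta = beta, metadata = metadata, manifest = manifest,
       probe_truth = probe_truth, genes = genes,
       gene_sets = list(high = high_genes, low = low_genes),
       selected_snps = selected_snps)
}

# passing ranges for the 12 recent-selection statistics
passing_snp_stats <- function(n) {
  data.frame(
    DAF = stats::runif(n, 0.10, 0.90), GFHOM1 = stats::runif(n, 0.01, 0.50),
    GFHET = stats::runif(n, 0.10, 0.50), HWE2 = stats::runif(n, 0.01, 1.00),
    HET = stats::runif(n, 0.05, 0.45), PI = stats::runif(n, 0.01, 0.45),
    DDAF = stats::runif(n, 0.25, 0.80), TD = stats::runif(n, -2.5, -0.1),
    FST1 = stats::runif(n, 0.10, 0.60), UIHS = stats::runif(n, 1.6, 4.0),
    UXPEHH = stats::runif(n, 1.1, 3.0), XPCLR = stats::runif(n, 6, 50))
}

#' Simulate the conservation track, SNP table, TSS annotation and gene sets
#'
#' Materialises the external tracks from the truth fixed by
#' [simulate_betas()]: a bedGraph-style conservation track covering every
#' probe with its true score (positive for the conserved fraction,
#' negative otherwise, all within \[-12.36, 6.18\]); a SNP table in which
#' the planted selected SNPs pass all 12 filter criteria by construction
#' and every other SNP fails exactly one randomly chosen criterion; BED6
#' TSS annotation; and a gene-set collection containing the planted
#' high-MV and low-MV sets plus random decoy sets.
#'
#' @param config a [sim_config()].
#' @param truth combined truth: the output of [simulate_genome()] merged
#'   with the output of [simulate_betas()] (see [simulate_methylome()]).
#' @return list with `gerp` (chrom/start/end/score), `snps` (rsid, chrom,
#'   pos + the 12 statistics), `tss` (BED6 data.frame) and `gmt`
#'   (named list of character vectors, the gene-set collection).
#' @export
simulate_selection_inputs <- function(config, truth) {
  stopifnot(inherits(config, "methvar_sim_config"),
            !is.null(truth$probe_truth))
  set.seed(derive_seed(config$seed, 3L))
  pt <- truth$probe_truth
  o <- order(pt$chrom, pt$pos)
  gerp <- data.frame(chrom = pt$chrom[o], start = pt$pos[o] - 1L,
                     end = pt$pos[o], score = round(pt$gerp_score[o], 4),
                     stringsAsFactors = FALSE)

  n_sel <- nrow(truth$selected_snps)
  n_fail <- config$n_snps - n_sel
  stats_tab <- passing_snp_stats(config$n_snps)
  thr <- selection_thresholds()
  if (n_fail > 0L) {
    which_stat <- sample(nrow(thr), n_fail, replace = TRUE)
    for (i in seq_len(n_fail)) {
      row <- n_sel + i
      st <- thr$statistic[which_stat[i]]
      cut <- thr$cutoff[which_stat[i]]
      stats_tab[row, st] <- if (thr$direction[which_stat[i]] == ">")
        cut * 0.5 else cut + 0.3
    }
  }
  fail_pos <- if (n_fail > 0L)
    sort(sample.int(config$genome_length - 1L, n_fail)) else integer(0)
  snps <- data.frame(
    rsid = sprintf("rs%06d", seq_len(config$n_snps)),
    chrom = c(truth$selected_snps$chrom, rep("chr1", n_fail)),
    pos = c(truth$selected_snps$pos, fail_pos),
    stringsAsFactors = FALSE)
  snps <- cbind(snps, round(stats_tab, 5))

  genes <- truth$genes
  tss <- data.frame(chrom = genes$chrom, start = genes$tss - 1L,
                    end = genes$tss, name = genes$gene, score = 0L,
                    strand = genes$strand, stringsAsFactors = FALSE)

  sets <- list(PLANTED_HIGH_MV = truth$gene_sets$high,
               PLANTED_LOW_MV = truth$gene_sets$low)
  for (i in 1:8) {
    sets[[sprintf("RANDOM_%02d", i)]] <-
      sort(sample(genes$gene, min(nrow(genes),
                                  sample(8:15, 1L))))
  }
  list(gerp = gerp, snps = snps, tss = tss, gmt = sets)
}

#' Simulate a complete study
#'
#' Runs [simulate_genome()], [simulate_betas()] and
#' [simulate_selection_inputs()] in order and returns everything the
#' pipeline consumes plus the ground truth. Identical `config` (including
#' seed) gives identical output.
#'
#' @param config a [sim_config()].
#' @return list combining all three stages' outputs.
#' @export
simulate_methylome <- function(config = sim_config()) {
  g <- simulate_genome(config)
  b <- simulate_betas(config, g)
  truth <- c(g, b)
  sel <- simulate_selection_inputs(config, truth)
  c(truth, sel, list(config = config))
}
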