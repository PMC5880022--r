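# End-to-end orchestration: simulate (or load) inputs, preprocess, density
# classification, conservation and recent-selection overlays, enrichment —
# collected into a single classed report object.

#' Run the full methylation-variability pipeline
#'
#' Executes simulate -> preprocess -> density -> conserve -> recent ->
#' enrich on a synthetic study and returns a `methvar_analysis` object
#' holding every stage's summaries and test results. Stages downstream of
#' preprocessing can be skipped. All randomness derives from
#' `config$seed`; two runs with the same config produce identical results
#' and (with `outdir`) byte-identical files.
#'
#' @param config a [sim_config()]; also accepts a pre-built simulation
#'   (the result of [simulate_methylome()]) to avoid re-simulating.
#' @param outdir optional directory; when given, per-stage tables and a
#'   JSON report are written there.
#' @param skip character subset of `c("conserve", "recent", "enrich")`.
#' @param n_per_sex pairs requested from the cohort matcher (default:
#'   half the sample size, i.e. everything achievable).
#' @param half_window RSP window half-width in bp (see
#'   [define_rsp_cpgs()]).
#' @param flank promoter half-window in bp.
#' @param B bootstrap resamples.
#' @param n_perm gene-set permutations.
#' @param alpha significance level echoed in the report (default 0.05).
#' @return an object of class `methvar_analysis`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         skip = character(), n_per_sex = NULL,
                         half_window = 1000L, flank = 1500L,
                         B = 10000L, n_perm = 1000L, alpha = 0.05) {
  stopifnot(all(skip %in% c("conserve", "recent", "enrich")))
  if (inherits(config, "methvar_sim_config")) {
    log_stage("simulate", "generating synthetic study (seed ",
              config$seed, ")")
    sim <- simulate_methylome(config)
  } else if (is.list(config) && !is.null(config$beta)) {
    sim <- config
    config <- sim$config
  } else {
    stop("'config' must be a sim_config() or a simulate_methylome() ",
         "result", call. = FALSE)
  }
  res <- list(config = config, alpha = alpha,
              seeds = c(simulation = config$seed))

  log_stage("preprocess", "cohort selection, probe filtering, MV")
  if (is.null(n_per_sex)) n_per_sex <- floor(config$n_samples / 2)
  cohort <- suppressMessages(
    select_cohort(sim$metadata, n_per_sex = n_per_sex))
  fp <- filter_probes(sim$manifest, sim$beta, samples = cohort)
  mv <- compute_mv(sim$beta, fp$retained, samples = cohort)
  manifest <- sim$manifest[match(fp$retained, sim$manifest$probe), ,
                           drop = FALSE]
  res$preprocess <- list(n_selected_samples = length(cohort),
                         cohort = cohort, filter_tally = fp$tally)
  res$mv <- mv

  log_stage("density", "CpG cluster discovery and classification")
  regions <- find_cpg_clusters(sim$genome)
  assignment <- assign_density(regions, manifest)
  cls_mv <- split(mv$mv, assignment$class)
  res$density <- list(
    regions = regions,
    assignment = assignment,
    class_counts = table(assignment$class),
    class_medians = vapply(cls_mv, stats::median, numeric(1)),
    test = welch_oneway(cls_mv))
  res$deciles <- decile_bin(mv$mean, mv$mv)[c("summary", "boundaries")]

  if (!"conserve" %in% skip) {
    log_stage("conserve", "conservation lookup and quartile trend")
    ann <- gerp_lookup(sim$gerp, manifest)
    keep <- nonneg_filter(ann)
    res$conservation <- c(
      mv_by_quartile(mv, keep)[c("summary", "test",
                                 "monotone_decreasing", "boundaries")],
      list(n_scored = nrow(ann), n_nonneg = nrow(keep),
           n_dropped = attr(ann, "n_dropped")))
    res$conservation_annotated <- ann
  }

  if (!"recent" %in% skip) {
    log_stage("recent", "selection filter, RSP windows, bootstrap")
    passing <- filter_dbpshp(sim$snps)
    rsp <- define_rsp_cpgs(passing, manifest, half_window = half_window)
    boot_seed <- derive_seed(config$seed, 7L)
    n_rsp <- sum(rsp$rsp)
    boot <- if (n_rsp > 0L && n_rsp < nrow(mv)) {
      bootstrap_mean_test(mv, rsp$probe[rsp$rsp], B = B, seed = boot_seed)
    } else NULL
    res$recent <- list(
      n_snps = nrow(sim$snps), n_passing = nrow(passing),
      n_rsp = n_rsp, half_window = half_window,
      bootstrap = boot, rsp = rsp)
    res$seeds["bootstrap"] <- boot_seed
    if (!"conserve" %in% skip) {
      res$recent$gerp_comparison <-
        gerp_compare_groups(res$conservation_annotated, rsp)
    }
  }

  if (!"enrich" %in% skip) {
    log_stage("enrich", "promoter mapping, ranking, preranked GSEA")
    asn <- map_probes_to_promoters(sim$genes, manifest, flank = flank)
    gm <- gene_mv(asn, mv)
    ranked <- zscore_rank(gm)
    gsea_seed <- derive_seed(config$seed, 8L)
    results <- suppressWarnings(
      gsea_preranked(ranked, sim$gmt, n_perm = n_perm, seed = gsea_seed))
    res$enrichment <- list(
      n_mapped_probes = length(unique(asn$probe)),
      n_genes = nrow(gm), ranked = ranked, results = results,
      significant = significant_sets(results))
    res$seeds["gsea"] <- gsea_seed
  }

  res <- structure(res, class = "methvar_analysis")
  if (!is.null(outdir)) write_report(res, sim, outdir)
  res
}

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

# Serialise the analysis: per-stage TSVs plus one JSON report. All output
# is timestamp-free so reruns are byte-identical.
write_report <- function(res, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(res$mv, file.path(outdir, "mv.tsv"))
  reg <- res$density$regions
  utils::write.table(reg[, c("chrom", "start", "end", "class")],
                     file.path(outdir, "regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_table_tsv(res$density$assignment,
                  file.path(outdir, "density_assignment.tsv"))
  if (!is.null(res$conservation_annotated)) {
    write_table_tsv(res$conservation_annotated,
                    file.path(outdir, "gerp_annotated.tsv"))
  }
  if (!is.null(res$recent)) {
    write_table_tsv(res$recent$rsp, file.path(outdir, "rsp.tsv"))
  }
  if (!is.null(res$enrichment)) {
    write_rnk(res$enrichment$ranked, file.path(outdir, "ranked.rnk"))
    write_table_tsv(res$enrichment$results,
                    file.path(outdir, "enrichment.tsv"))
  }
  jsonlite::write_json(report_list(res), file.path(outdir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

# plain-list view of the report for JSON serialisation
report_list <- function(res) {
  out <- list(
    config = unclass(res$config),
    alpha = res$alpha,
    seeds = as.list(res$seeds),
    preprocess = list(
      n_selected_samples = res$preprocess$n_selected_samples,
      filter_tally = as.list(res$preprocess$filter_tally)),
    density = list(
      class_counts = as.list(res$density$class_counts),
      class_medians = as.list(res$density$class_medians),
      welch_p = res$density$test$p,
      welch_p_display = res$density$test$p_display),
    deciles = res$deciles$summary)
  if (!is.null(res$conservation)) {
    out$conservation <- list(
      summary = res$conservation$summary,
      welch_p = res$conservation$test$p,
      monotone_decreasing = res$conservation$monotone_decreasing,
      n_nonneg = res$conservation$n_nonneg)
  }
  if (!is.null(res$recent)) {
    b <- res$recent$bootstrap
    out$recent <- list(
      n_passing_snps = res$recent$n_passing,
      n_rsp_cpgs = res$recent$n_rsp,
      bootstrap = if (!is.null(b)) b[c("observed_mean", "non_rsp_mean",
                                       "B", "count_le", "p", "seed")],
      gerp_comparison = res$recent$gerp_comparison[c("statistic", "df",
                                                     "p")])
  }
  if (!is.null(res$enrichment)) {
    sig <- res$enrichment$significant
    out$enrichment <- list(
      n_genes = res$enrichment$n_genes,
      results = res$enrichment$results[, c("set", "size", "es", "nes",
                                           "p", "q", "direction")],
      n_significant_high = nrow(sig$high),
      n_significant_low = nrow(sig$low))
  }
  out
}

#' @export
print.methvar_analysis <- function(x, ...) {
  cat("Methylation-variability analysis\n")
  cat(sprintf("  samples: %d selected; probes retained: %d\n",
              x$preprocess$n_selected_samples, nrow(x$mv)))
  cc <- x$density$class_counts
  cm <- x$density$class_medians
  cat(sprintf("  density classes: HC %d / IC %d / LC %d\n",
              cc[["HC"]], cc[["IC"]], cc[["LC"]]))
  cat(sprintf("  median MV by class: HC %.4f, IC %.4f, LC %.4f (Welch p %s)\n",
              cm[["HC"]], cm[["IC"]], cm[["LC"]],
              x$density$test$p_display))
  if (!is.null(x$conservation)) {
    cat(sprintf("  conservation quartile trend: %s (Welch p %s)\n",
                if (x$conservation$monotone_decreasing)
                  "monotone decreasing" else "not monotone",
                x$conservation$test$p_display))
  }
  if (!is.null(x$recent)) {
    b <- x$recent$bootstrap
    if (!is.null(b)) {
      cat(sprintf(
        "  RSP-CpGs: %d (of %d passing SNPs); MV %.4f vs %.4f, bootstrap p %s\n",
        x$recent$n_rsp, x$recent$n_passing, b$observed_mean,
        b$non_rsp_mean, format_pvalue(b$p)))
    }
  }
  if (!is.null(x$enrichment)) {
    sig <- x$enrichment$significant
    cat(sprintf("  enriched sets (p<=0.01 & q<=0.25): %d high-MV, %d low-MV\n",
                nrow(sig$high), nrow(sig$low)))
  }
  invisible(x)
}

#' @export
summary.methvar_analysis <- function(object, ...) {
  print(object)
  cat("\nFilter tally:\n")
  print(object$preprocess$filter_tally)
  cat("\nMV by beta decile:\n")
  print(object$deciles$summary, row.names = FALSE)
  if (!is.null(object$conservation)) {
    cat("\nMV by conservation quartile:\n")
    print(object$conservation$summary, row.names = FALSE)
  }
  if (!is.null(object$enrichment)) {
    cat("\nTop enrichment results:\n")
    r <- object$enrichment$results
    print(utils::head(r[order(r$p), c("set", "es", "nes", "p", "q",
                                      "direction")], 10),
          row.names = FALSE)
  }
  invisible(object)
}

#' Boxplot panels of the analysis
#'
#' Four base-graphics panels: MV by density class, MV by beta-value
#' decile, MV by conservation quartile (when run), and MV for RSP vs
#' non-RSP probes (when run).
#'
#' @param x a `methvar_analysis`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.methvar_analysis <- function(x, ...) {
  n_panel <- 2L + !is.null(x$conservation) + !is.null(x$recent)
  op <- graphics::par(mfrow = c(2, ceiling(n_panel / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::boxplot(split(x$mv$mv, x$density$assignment$class),
                    main = "MV by density class", ylab = "MV",
                    outline = FALSE, ...)
  dl <- decile_bin(x$mv$mean, x$mv$mv)
  graphics::boxplot(split(x$mv$mv, dl$labels),
                    main = "MV by beta decile", ylab = "MV", las = 2,
                    outline = FALSE, ...)
  if (!is.null(x$conservation)) {
    ann <- merge(x$mv[, c("probe", "mv")],
                 nonneg_filter(x$conservation_annotated), by = "probe")
    qb <- quartile_bin(ann$score)
    graphics::boxplot(split(ann$mv, qb$labels),
                      main = "MV by conservation quartile", ylab = "MV",
                      outline = FALSE, ...)
  }
  if (!is.null(x$recent)) {
    grp <- ifelse(x$recent$rsp$rsp[match(x$mv$probe, x$recent$rsp$probe)],
                  "RSP", "non-RSP")
    graphics::boxplot(split(x$mv$mv, grp), main = "MV by recent selection",
                      ylab = "MV", outline = FALSE, ...)
  }
  invisible(x)
}
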