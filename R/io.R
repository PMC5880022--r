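# Plain-text readers and writers for every format the pipeline exchanges:
# FASTA (via Biostrings), beta/metadata/MV TSV, manifest CSV, bedGraph,
# BED, SNP TSV, GMT and RNK. Writers are deterministic (fixed column
# orders, no timestamps) so identical inputs give byte-identical files.

#' @name methvar_io
#' @rdname methvar_io
#' @title Read and write pipeline files
#' @description Small, schema-checked I/O helpers. The schemas match what
#'   the simulator writes and what real array exports provide: beta TSV
#'   (first column `probe`, one column per sample), metadata TSV
#'   (`sample`, `sex`, `age`, `status`), manifest CSV (`probe`, `chrom`,
#'   `pos`, `snp_overlap`, `cross_reactive`), bedGraph (0-based
#'   half-open), BED6, SNP TSV (rsid, chrom, pos + 12 statistics), GMT
#'   (set, description, genes), RNK (gene, score) and MV TSV (`probe`,
#'   `mean`, `variance`, `mv`).
#' @param path file path.
#' @param x object to write (see individual writers).
NULL

#' @rdname methvar_io
#' @export
write_genome_fasta <- function(x, path) {
  dss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname methvar_io
#' @export
write_beta_tsv <- function(x, path) {
  df <- data.frame(probe = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname methvar_io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "sex", "age", "status") %in% names(df)))
  df
}

#' @rdname methvar_io
#' @export
write_manifest_csv <- function(x, path) {
  utils::write.csv(x, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "chrom", "pos", "snp_overlap",
                  "cross_reactive") %in% names(df)))
  df$snp_overlap <- as.logical(df$snp_overlap)
  df$cross_reactive <- as.logical(df$cross_reactive)
  df
}

#' @rdname methvar_io
#' @export
write_bedgraph <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          stringsAsFactors = FALSE)[, 1:4]
  names(df) <- c("chrom", "start", "end", "score")
  df
}

#' @rdname methvar_io
#' @export
write_bed6 <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "name", "score",
                           "strand")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_tss_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          stringsAsFactors = FALSE)[, 1:6]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")
  data.frame(gene = df$name, chrom = df$chrom, tss = df$end,
             strand = df$strand, stringsAsFactors = FALSE)
}

#' @rdname methvar_io
#' @export
read_snp_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", selection_thresholds()$statistic)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("SNP table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname methvar_io
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, "synthetic", x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT",
                                       call. = FALSE)
  sets
}

#' @rdname methvar_io
#' @export
write_rnk <- function(x, path) {
  utils::write.table(x[, c("gene", "z")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname methvar_io
#' @export
read_mv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "mean", "variance", "mv") %in% names(df)))
  df
}

#' Write all simulated inputs to a directory
#'
#' Materialises a [simulate_methylome()] result as the plain-text files a
#' real study would provide: `genome.fa`, `beta.tsv`, `metadata.tsv`,
#' `manifest.csv`, `gerp.bedGraph`, `snps.tsv`, `tss.bed`, `sets.gmt`,
#' and `truth.json` (the planted ground truth). Output is deterministic:
#' the same simulation writes byte-identical files.
#'
#' @param sim result of [simulate_methylome()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- c(
    genome = file.path(outdir, "genome.fa"),
    beta = file.path(outdir, "beta.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    manifest = file.path(outdir, "manifest.csv"),
    gerp = file.path(outdir, "gerp.bedGraph"),
    snps = file.path(outdir, "snps.tsv"),
    tss = file.path(outdir, "tss.bed"),
    gmt = file.path(outdir, "sets.gmt"),
    truth = file.path(outdir, "truth.json"))
  write_genome_fasta(sim$genome, p[["genome"]])
  beta_out <- round(sim$beta, 6)
  write_beta_tsv(beta_out, p[["beta"]])
  write_table_tsv(sim$metadata, p[["metadata"]])
  write_manifest_csv(sim$manifest, p[["manifest"]])
  write_bedgraph(sim$gerp, p[["gerp"]])
  write_table_tsv(sim$snps, p[["snps"]])
  write_bed6(sim$tss, p[["tss"]])
  write_gmt(sim$gmt, p[["gmt"]])
  truth <- list(
    regions = sim$regions,
    probe_truth = sim$probe_truth,
    genes = sim$genes,
    gene_sets = sim$gene_sets,
    selected_snps = sim$selected_snps,
    config = unclass(sim$config))
  jsonlite::write_json(truth, p[["truth"]], digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(p)
}
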