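# CpG cluster discovery and density classification.
#
# Genomic regions are classed by three criteria on (GC content, observed/
# expected CpG ratio, length): high-density clusters (HC) require
# GC > 55%, Obs/Exp > 0.75 and length > 500 bp; intermediate-density (IC)
# GC > 50%, Obs/Exp > 0.48 and length > 200 bp; everything else is
# low-density (LC). All inequalities are strict.

HC_GC <- 0.55; HC_OE <- 0.75; HC_LEN <- 500
IC_GC <- 0.50; IC_OE <- 0.48; IC_LEN <- 200

#' Observed/expected CpG ratio of a sequence
#'
#' The classic CpG-island enrichment measure: the number of CpG
#' dinucleotides relative to the count expected from the C and G base
#' composition, \eqn{(N_{CpG} \times L) / (N_C \times N_G)}. `N` bases are
#' excluded from all counts and from the effective length `L`. Returns 0
#' when the sequence contains no C or no G.
#'
#' @param sequence a single character string over the alphabet A,C,G,T,N.
#' @return the Obs/Exp CpG ratio (non-negative scalar).
#' @examples
#' obs_exp_ratio("CGCG")   # 2
#' obs_exp_ratio("ATCGAT") # 6
#' obs_exp_ratio("AATT")   # 0
#' @export
obs_exp_ratio <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence", call. = FALSE)
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(x %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence alphabet must be {A,C,G,T,N}", call. = FALSE)
  }
  n_c <- sum(x == "C")
  n_g <- sum(x == "G")
  if (n_c == 0L || n_g == 0L) return(0)
  n_cg <- sum(x[-length(x)] == "C" & x[-1L] == "G")
  L <- sum(x != "N")
  (n_cg * L) / (n_c * n_g)
}

#' Classify a genomic region as HC, IC or neither
#'
#' Applies the density-class criteria (strict inequalities). A region is HC
#' if GC content > 0.55, Obs/Exp CpG ratio > 0.75 and length > 500 bp;
#' otherwise IC if GC > 0.50, Obs/Exp > 0.48 and length > 200 bp;
#' otherwise `NA` (the region is not a CpG cluster; probes outside any
#' cluster are low-density, LC). Vectorised over its arguments.
#'
#' @param gc_content GC fraction in \[0,1\].
#' @param obs_exp Obs/Exp CpG ratio (>= 0).
#' @param length region length in bp.
#' @return character vector of `"HC"`, `"IC"` or `NA`.
#' @examples
#' classify_region(0.56, 0.80, 600) # "HC"
#' classify_region(0.52, 0.50, 300) # "IC"
#' classify_region(0.40, 0.30, 100) # NA
#' @export
classify_region <- function(gc_content, obs_exp, length) {
  stopifnot(all(is.finite(gc_content)), all(is.finite(obs_exp)),
            all(is.finite(length)),
            all(gc_content >= 0 & gc_content <= 1), all(length >= 0))
  cls <- rep(NA_character_, base::length(gc_content))
  ic <- gc_content > IC_GC & obs_exp > IC_OE & length > IC_LEN
  hc <- gc_content > HC_GC & obs_exp > HC_OE & length > HC_LEN
  cls[ic] <- "IC"
  cls[hc] <- "HC"
  cls
}

# Coerce a genome argument (FASTA path, DNAStringSet, or named character
# vector) to a named list of uppercase per-chromosome character vectors.
genome_as_chars <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    # FASTA headers may carry descriptions; keep the first word
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named",
                                     call. = FALSE)
    seqs <- toupper(genome)
  } else {
    stop("'genome' must be a FASTA path, DNAStringSet or named character",
         call. = FALSE)
  }
  lapply(seqs, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]])
}

# Per-chromosome cumulative counts used for O(1) window statistics.
chrom_cumstats <- function(x) {
  n <- length(x)
  cg <- if (n >= 2L) c(x[-n] == "C" & x[-1L] == "G", FALSE) else logical(n)
  list(
    n = n,
    c = cumsum(x == "C"),
    g = cumsum(x == "G"),
    nn = cumsum(x == "N"),
    cg = cumsum(cg)
  )
}

# Stats of the 0-based half-open span [s, e): gc over non-N bases, Obs/Exp
# with effective (non-N) length, genomic span length.
span_stats <- function(cs, s, e) {
  at <- function(v, i) ifelse(i > 0L, v[pmax(i, 1L)], 0L)
  n_c <- at(cs$c, e) - at(cs$c, s)
  n_g <- at(cs$g, e) - at(cs$g, s)
  n_n <- at(cs$nn, e) - at(cs$nn, s)
  # CG dinucleotides fully inside the span start in [s, e-1)
  n_cg <- at(cs$cg, e - 1L) - at(cs$cg, s)
  eff <- (e - s) - n_n
  gc <- ifelse(eff > 0L, (n_c + n_g) / eff, 0)
  oe <- ifelse(n_c > 0L & n_g > 0L, (n_cg * eff) / (n_c * n_g), 0)
  data.frame(gc_content = gc, obs_exp = oe, length = e - s)
}

#' Discover CpG clusters from sequence
#'
#' Deterministic per-chromosome scan: sliding 200-bp windows at 50-bp steps
#' are seeds when they meet the IC minima (GC > 0.50 and Obs/Exp > 0.48);
#' overlapping or touching seeds merge into maximal regions; each merged
#' region is re-measured in full and classified with [classify_region()];
#' regions classifying to neither HC nor IC are dropped. Output is sorted
#' by (chrom, start) and non-overlapping.
#'
#' @param genome FASTA file path, `Biostrings::DNAStringSet`, or a named
#'   character vector of chromosome sequences.
#' @param window,step window width and step in bp.
#' @return data.frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `gc_content`, `obs_exp`, `class`.
#' @export
find_cpg_clusters <- function(genome, window = 200L, step = 50L) {
  chars <- genome_as_chars(genome)
  out <- list()
  for (ch in names(chars)) {
    x <- chars[[ch]]
    if (length(x) < window) next
    cs <- chrom_cumstats(x)
    starts <- seq.int(0L, length(x) - window, by = step)
    st <- span_stats(cs, starts, starts + window)
    seed <- st$gc_content > IC_GC & st$obs_exp > IC_OE
    if (!any(seed)) next
    ss <- starts[seed]
    se <- ss + window
    # merge overlapping/adjacent seed windows into maximal spans
    brk <- which(ss[-1L] > se[-length(se)])
    grp <- rep.int(seq_len(length(brk) + 1L),
                   diff(c(0L, brk, length(ss))))
    ms <- tapply(ss, grp, min)
    me <- tapply(se, grp, max)
    reg <- span_stats(cs, as.integer(ms), as.integer(me))
    cls <- classify_region(reg$gc_content, reg$obs_exp, reg$length)
    keep <- !is.na(cls)
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch, start = as.integer(ms)[keep], end = as.integer(me)[keep],
      length = reg$length[keep], gc_content = reg$gc_content[keep],
      obs_exp = reg$obs_exp[keep], class = cls[keep],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      gc_content = numeric(), obs_exp = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign each probe a density class
#'
#' A probe inside an HC region is HC, inside an IC region IC, and LC
#' otherwise. Containment converts the probe's 1-based position to 0-based
#' and tests against half-open regions.
#'
#' @param regions data.frame as returned by [find_cpg_clusters()] (sorted,
#'   non-overlapping, with `class`).
#' @param manifest probe manifest data.frame with `probe`, `chrom`, `pos`
#'   (1-based).
#' @return data.frame with `probe` and `class` (factor HC/IC/LC); every
#'   input probe appears exactly once.
#' @export
assign_density <- function(regions, manifest) {
  idx <- interval_lookup(manifest$chrom, manifest$pos - 1L, regions)
  cls <- ifelse(is.na(idx), "LC", regions$class[idx])
  data.frame(probe = manifest$probe,
             class = factor(cls, levels = c("HC", "IC", "LC")),
             stringsAsFactors = FALSE)
}
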