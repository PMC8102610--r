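#' SNP and sample filter configuration
#'
#' Thresholds for the post-calling filter cascade, applied in a fixed
#' order by [filter_snps()]: (1) locus call rate, (2) minor allele count,
#' (3) observed heterozygosity, (4) linkage-disequilibrium pruning within
#' a physical window, (5) per-sample missingness.
#'
#' @param min_locus_call_rate loci genotyped in fewer than this proportion
#'   of samples are removed (default 0.80).
#' @param min_minor_allele_count loci whose minor allele is observed fewer
#'   than this many times are removed (default 3).
#' @param max_obs_het loci with observed heterozygosity above this are
#'   removed (default 0.5; guards against paralog collapse).
#' @param ld_threshold dosage-correlation threshold for pruning (default
#'   0.5).
#' @param ld_stat whether `ld_threshold` applies to `|r|` (default) or to
#'   `r^2`.
#' @param ld_window_bp only locus pairs closer than this on a scaffold are
#'   tested (default 100000).
#' @param ld_min_shared minimum pairwise-complete samples for a
#'   correlation to be trusted (default 10; pairs below are skipped).
#' @param max_sample_missing samples missing more than this proportion of
#'   calls (after locus filters) are removed (default 0.25).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_locus_call_rate = 0.80,
                          min_minor_allele_count = 3,
                          max_obs_het = 0.5,
                          ld_threshold = 0.5,
                          ld_stat = c("r", "r2"),
                          ld_window_bp = 100000,
                          ld_min_shared = 10,
                          max_sample_missing = 0.25) {
  ld_stat <- match.arg(ld_stat)
  stopifnot(min_locus_call_rate >= 0, min_locus_call_rate <= 1,
            min_minor_allele_count >= 0,
            max_obs_het >= 0, max_obs_het <= 1,
            ld_threshold >= 0, ld_threshold <= 1,
            ld_window_bp > 0, ld_min_shared >= 2,
            max_sample_missing >= 0, max_sample_missing <= 1)
  structure(list(min_locus_call_rate = min_locus_call_rate,
                 min_minor_allele_count = as.integer(min_minor_allele_count),
                 max_obs_het = max_obs_het,
                 ld_threshold = ld_threshold, ld_stat = ld_stat,
                 ld_window_bp = as.integer(ld_window_bp),
                 ld_min_shared = as.integer(ld_min_shared),
                 max_sample_missing = max_sample_missing),
            class = "filter_config")
}

#' Apply the SNP/sample filter cascade
#'
#' Stages run in a fixed, documented order; the counts in the returned
#' report depend on that order. LD pruning scans each scaffold in
#' position order and, for every still-retained pair closer than the
#' window whose pairwise-complete dosage correlation exceeds the
#' threshold, drops the member with more missing data (ties: the later
#' position) - deterministic and favouring completeness.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with `genotypes` (the filtered matrix) and `report`, a
#'   `filter_report` recording per-stage input/removed/retained counts
#'   and the overall missing-data proportion of the final panel.
#' @export
filter_snps <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g) == 0 || nrow(g) == 0) stop("empty genotype matrix")
  stages <- list()
  note <- function(stage, unit, n_in, n_removed) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, unit = unit, n_in = n_in,
      n_removed = n_removed, n_retained = n_in - n_removed)
  }

  # (1) locus call rate
  call_rate <- colMeans(!is.na(g))
  keep <- call_rate >= cfg$min_locus_call_rate
  note("locus_call_rate", "locus", ncol(g), sum(!keep))
  g <- g[, keep]

  # (2) minor allele count
  alt <- colSums(unclass(g), na.rm = TRUE)
  copies <- 2L * colSums(!is.na(g))
  mac <- pmin(alt, copies - alt)
  keep <- mac >= cfg$min_minor_allele_count
  note("minor_allele_count", "locus", ncol(g), sum(!keep))
  g <- g[, keep]

  # (3) observed heterozygosity
  ho <- colMeans(unclass(g) == 1L, na.rm = TRUE)
  keep <- ho <= cfg$max_obs_het
  note("observed_het", "locus", ncol(g), sum(!keep))
  g <- g[, keep]

  # (4) LD pruning
  drop <- ld_prune(g, cfg)
  note("ld_pruning", "locus", ncol(g), length(drop))
  if (length(drop)) g <- g[, setdiff(seq_len(ncol(g)), drop)]

  # (5) sample missingness
  smiss <- rowMeans(is.na(g))
  keep_s <- smiss <= cfg$max_sample_missing
  note("sample_missing", "sample", nrow(g), sum(!keep_s))
  g <- g[keep_s, ]

  if (ncol(g) == 0) stop("empty panel: all loci removed by filters")
  report <- structure(
    list(stages = do.call(rbind, stages),
         n_samples = nrow(g), n_loci = ncol(g),
         missing_rate = mean(is.na(g)),
         config = cfg),
    class = "filter_report")
  list(genotypes = g, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP/sample filter cascade\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final panel: %d samples x %d loci; %.2f%% missing\n",
              x$n_samples, x$n_loci, 100 * x$missing_rate))
  cat(sprintf("LD rule: |%s| > %g within %d bp\n",
              x$config$ld_stat, x$config$ld_threshold, x$config$ld_window_bp))
  invisible(x)
}

# indices of loci to drop by windowed LD pruning (see filter_snps docs)
ld_prune <- function(g, cfg) {
  li <- loci_info(g)
  ord <- order(li$scaffold, li$position)
  nmiss <- colSums(is.na(g))
  dropped <- logical(ncol(g))
  m <- unclass(g)
  for (idx in seq_along(ord)) {
    i <- ord[idx]
    if (dropped[i]) next
    jdx <- idx + 1L
    while (jdx <= length(ord)) {
      j <- ord[jdx]
      if (li$scaffold[j] != li$scaffold[i] ||
          li$position[j] - li$position[i] >= cfg$ld_window_bp) break
      if (!dropped[j]) {
        ok <- !is.na(m[, i]) & !is.na(m[, j])
        if (sum(ok) >= cfg$ld_min_shared) {
          r <- suppressWarnings(stats::cor(m[ok, i], m[ok, j]))
          stat <- if (cfg$ld_stat == "r") abs(r) else r^2
          if (!is.na(stat) && stat > cfg$ld_threshold) {
            # drop the lossier locus; tie -> later position
            victim <- if (nmiss[j] >= nmiss[i]) j else i
            dropped[victim] <- TRUE
            if (victim == i) break
          }
        }
      }
      jdx <- jdx + 1L
    }
  }
  which(dropped)
}

#' Per-population allele frequencies with gene-copy counts
#'
#' @param g a [genotype_matrix()].
#' @param map a population map (see [validate_popmap()]).
#' @return list with matrices `p` (alternate-allele frequency, loci x
#'   populations; `NA` where a population has no genotyped sample) and
#'   `copies` (number of genotyped gene copies, 2 x samples called).
#' @export
allele_frequencies <- function(g, map) {
  map <- align_map(g, map)
  pops <- unique(map$population)
  m <- unclass(g)
  p <- matrix(NA_real_, ncol(g), length(pops),
              dimnames = list(colnames(g), pops))
  copies <- matrix(0L, ncol(g), length(pops),
                   dimnames = list(colnames(g), pops))
  for (k in seq_along(pops)) {
    rows <- map$population == pops[k]
    sub <- m[rows, , drop = FALSE]
    ncalled <- colSums(!is.na(sub))
    copies[, k] <- 2L * ncalled
    p[, k] <- ifelse(ncalled > 0, colSums(sub, na.rm = TRUE) / (2 * ncalled), NA)
  }
  list(p = p, copies = copies)
}
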