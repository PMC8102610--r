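#' Pipeline configuration
#'
#' Bundles every stage option of [run_pipeline()] with a single global
#' seed that propagates to all stochastic stages.
#'
#' @param genotypes path to a VCF or dosage CSV, or a
#'   [genotype_matrix()].
#' @param popmap path to a population-map CSV, or a data.frame.
#' @param env path to an environment CSV, or a data.frame; `NULL` skips
#'   the hypervolume stage.
#' @param outdir output directory for CSV tables and the run log.
#' @param filter a [filter_config()].
#' @param min_n_diversity population-inclusion threshold for diversity
#'   and differentiation tables.
#' @param n_perm_fst permutations per population pair for the F_ST test.
#' @param kin_threshold kinship flag threshold.
#' @param autocorr_region region(s) used for the correlogram (`NULL` =
#'   all samples).
#' @param n_perm_autocorr correlogram permutations.
#' @param cascade_weighted weighting mode of the diversity cascade.
#' @param budgets,n_iter,n_per_pop,g_copies prioritisation options (see
#'   [max_coverage()]).
#' @param hv_group_by grouping column for niche hypervolumes.
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, popmap, env = NULL, outdir = ".",
                            filter = filter_config(),
                            min_n_diversity = 6, n_perm_fst = 1000,
                            kin_threshold = 0.125,
                            autocorr_region = NULL, n_perm_autocorr = 999,
                            cascade_weighted = TRUE,
                            budgets = 1:5, n_iter = 100, n_per_pop = 4,
                            g_copies = 8, hv_group_by = "region",
                            seed = 1L) {
  for (p in list(genotypes, popmap, env))
    if (is.character(p) && !file.exists(p)) stop("file not found: ", p)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: SNP/sample filtering; diversity and
#' differentiation tables; kinship screening plus a robustness re-run of
#' diversity and differentiation on the kin-pruned sample set (with a
#' paired-difference table); population- and individual-level PCoA;
#' the spatial autocorrelation correlogram; the Rao-Q diversity
#' cascade; rarefied allelic richness, leave-one-out contributions and
#' maximum-coverage prioritisation; and niche hypervolumes (when an
#' environment table is supplied). One CSV per result table is written
#' to `outdir` along with `run_log.txt`; a stage failure halts with the
#' stage name, retaining earlier outputs. Outputs are pure functions of
#' (inputs, config, seed): re-running a config reproduces them byte for
#' byte.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with every stage's object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cf$outdir, "run_log.txt")
  cat(sprintf("conigen %s | R %s | seed %d\n",
              as.character(utils::packageVersion("conigen")),
              paste(R.version$major, R.version$minor, sep = "."), cf$seed),
      file = logf)
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  res <- list(config = cf)
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logline("stage %s: ok", name)
    out
  }
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(cf$outdir, paste0(name, ".csv")), row.names = FALSE)
  wmat <- function(x, name) utils::write.csv(
    as.data.frame(x), file.path(cf$outdir, paste0(name, ".csv")),
    row.names = TRUE)

  g <- if (is.character(cf$genotypes)) {
    fmt <- if (grepl("\\.vcf(\\.gz)?$", cf$genotypes)) "vcf" else "matrix"
    read_genotypes(cf$genotypes, fmt)
  } else cf$genotypes
  map <- if (is.character(cf$popmap)) read_popmap(cf$popmap) else cf$popmap
  env <- if (is.character(cf$env)) read_env(cf$env) else cf$env

  set.seed(cf$seed)
  filt <- stage("filter", filter_snps(g, cf$filter))
  g <- filt$genotypes
  wcsv(filt$report$stages, "filter_report")
  logline("filter: %d samples x %d loci retained; missing %.4f; LD rule |%s| > %g",
          nrow(g), ncol(g), filt$report$missing_rate,
          cf$filter$ld_stat, cf$filter$ld_threshold)
  res$filter <- filt

  res$diversity <- stage("diversity",
                         diversity_table(g, map, min_n = cf$min_n_diversity))
  wcsv(res$diversity, "diversity_table")

  res$differentiation <- stage("differentiation",
                               pairwise_fst(g, map, n_perm = cf$n_perm_fst))
  wmat(res$differentiation$fst, "fst_matrix")
  wmat(res$differentiation$gst_pp, "gst_pp_matrix")
  wmat(res$differentiation$p_value, "fst_p_values")

  res$kinship <- stage("kinship", kinship_screen(g, map, cf$kin_threshold))
  wcsv(res$kinship$pairs, "kinship_pairs")
  logline("kinship: %d flagged pairs, %d samples pruned for robustness rerun",
          nrow(res$kinship$flagged_pairs), length(res$kinship$pruned_samples))

  # robustness re-run on kin-pruned samples
  if (length(res$kinship$pruned_samples)) {
    gk <- g[rownames(g) %in% res$kinship$kept_samples, ]
    div2 <- stage("diversity_kin_pruned",
                  diversity_table(gk, map, min_n = min(cf$min_n_diversity, 2)))
    fst2 <- stage("differentiation_kin_pruned", pairwise_fst(gk, map, n_perm = 0))
    shared <- intersect(res$diversity$population, div2$population)
    diff_tab <- data.frame(
      population = shared,
      d_H_O = div2$H_O[match(shared, div2$population)] -
        res$diversity$H_O[match(shared, res$diversity$population)],
      d_F_IS = div2$F_IS[match(shared, div2$population)] -
        res$diversity$F_IS[match(shared, res$diversity$population)])
    wcsv(diff_tab, "kin_pruned_diversity_shift")
    wmat(fst2$fst, "fst_matrix_kin_pruned")
    res$kin_pruned <- list(diversity = div2, differentiation = fst2,
                           shift = diff_tab)
  }

  freqs <- allele_frequencies(g, map)
  res$pcoa_population <- stage("pcoa_population",
                               pcoa(nei_distance(freqs), "population"))
  wmat(res$pcoa_population$coordinates, "pcoa_population")
  res$pcoa_individual <- stage("pcoa_individual",
                               pcoa(prevosti_distance(g), "individual"))
  wmat(res$pcoa_individual$coordinates, "pcoa_individual")

  set.seed(cf$seed + 1L)
  res$correlogram <- stage("autocorrelation",
                           autocorrelation(g, map, n_perm = cf$n_perm_autocorr,
                                           region = cf$autocorr_region))
  wcsv(as.data.frame(res$correlogram), "correlogram")

  res$cascade <- stage("cascade", cascade(g, map, weighted = cf$cascade_weighted))
  wcsv(res$cascade$table, "diversity_cascade")
  logline("cascade: gamma %.4f delta %.4f bartlett_p %.4f over %d loci",
          res$cascade$gamma, res$cascade$delta, res$cascade$bartlett_p,
          res$cascade$n_loci)

  res$contributions <- stage("contributions",
                             loo_contributions(g, map, g_copies = cf$g_copies))
  wcsv(res$contributions$richness, "allelic_richness")
  res$prioritization <- stage("prioritization",
                              max_coverage(g, map, budgets = cf$budgets,
                                           n_iter = cf$n_iter,
                                           n_per_pop = cf$n_per_pop,
                                           g_copies = cf$g_copies,
                                           seed = cf$seed + 2L))
  wmat(res$prioritization$selection_freq, "selection_frequency")
  wcsv(res$prioritization$coverage, "coverage_by_budget")

  if (!is.null(env)) {
    res$hypervolumes <- stage("hypervolumes",
                              niche_hypervolumes(env, map,
                                                 group_by = cf$hv_group_by,
                                                 seed = cf$seed + 3L))
    vols <- data.frame(
      group = names(res$hypervolumes$hypervolumes),
      volume = vapply(res$hypervolumes$hypervolumes, `[[`, numeric(1), "volume"),
      volume_se = vapply(res$hypervolumes$hypervolumes, `[[`, numeric(1), "volume_se"))
    wcsv(vols, "hypervolume_volumes")
    if (!is.null(res$hypervolumes$overlaps))
      wcsv(res$hypervolumes$overlaps, "hypervolume_overlap")
  }
  logline("pipeline complete")
  structure(res, class = "pipeline_result")
}
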