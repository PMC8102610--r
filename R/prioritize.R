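#' Rarefied allelic richness per population group
#'
#' Hypergeometric rarefaction to a standard sample of `g_copies` gene
#' copies: at a locus where a group holds `N` genotyped copies of which
#' `N_a` carry allele `a`, the expected number of distinct alleles in a
#' subsample of `g_copies` copies is
#' `AR = sum_a (1 - choose(N - N_a, g) / choose(N, g))`. A group's value
#' is the mean over included loci; `AR(t)` pools all groups. By default
#' loci where any group holds fewer than `g_copies` copies are excluded
#' for every group (listwise, so all values share a locus panel);
#' `listwise = FALSE` instead skips such loci per group.
#'
#' Groups are defined by the `group` column if present in the map, else
#' by population; small populations can be merged upstream by assigning
#' them one group label.
#'
#' @param g a [genotype_matrix()].
#' @param map a population map, optionally with a `group` column.
#' @param g_copies standardised number of gene copies (default 8).
#' @param listwise exclude a locus for all groups when any group falls
#'   below `g_copies` there (default TRUE).
#' @return list of class `richness_result`: data.frame `richness` (group,
#'   mean AR, SD across loci, n_loci), `total_ar` = AR(t), `g_copies`.
#' @export
rarefied_ar <- function(g, map, g_copies = 8, listwise = TRUE) {
  map <- align_map(g, map)
  grp <- group_labels(map)
  groups <- unique(grp)
  m <- unclass(g)
  cnt <- lapply(groups, function(gk) allele_counts(m[grp == gk, , drop = FALSE]))
  names(cnt) <- groups
  Nmat <- matrix(vapply(cnt, function(x) x$N, numeric(ncol(m))),
                 ncol = length(groups), dimnames = list(NULL, groups))
  enough <- Nmat >= g_copies
  if (any(colSums(enough) == 0))
    stop("group(s) below ", g_copies, " gene copies at every locus: ",
         paste(groups[colSums(enough) == 0], collapse = ", "))
  ok_all <- rowSums(enough) == length(groups)
  if (listwise && !any(ok_all))
    stop("no locus has >= ", g_copies, " gene copies in every group")
  rows <- lapply(groups, function(gk) {
    use <- if (listwise) ok_all else cnt[[gk]]$N >= g_copies
    ar <- rarefaction_curve(cnt[[gk]]$alt[use], cnt[[gk]]$N[use], g_copies)
    data.frame(group = gk, mean_AR = mean(ar), sd_AR = stats::sd(ar),
               n_loci = sum(use), stringsAsFactors = FALSE)
  })
  pooled <- allele_counts(m)
  use_t <- if (listwise) ok_all else pooled$N >= g_copies
  ar_t <- rarefaction_curve(pooled$alt[use_t], pooled$N[use_t], g_copies)
  structure(list(richness = do.call(rbind, rows),
                 total_ar = mean(ar_t), g_copies = g_copies,
                 listwise = listwise, loci_used = which(if (listwise) ok_all else use_t)),
            class = "richness_result")
}

# per-locus alternate-allele copy counts and total genotyped copies
allele_counts <- function(m) {
  n <- colSums(!is.na(m))
  list(alt = colSums(m, na.rm = TRUE), N = 2 * n)
}

# closed-form rarefied allele count per locus for biallelic counts
rarefaction_curve <- function(alt, N, g) {
  ref <- N - alt
  miss <- function(na) ifelse(N - na >= g, exp(lchoose(N - na, g) - lchoose(N, g)), 0)
  (1 - miss(alt)) + (1 - miss(ref))
}

#' Leave-one-out contribution of each group to total allelic richness
#'
#' `C_i = (AR(t) - AR(-i)) / (AR(t) - 1)`, where `AR(-i)` is the pooled
#' rarefied richness with group `i` excluded: the proportional loss of
#' standardised allelic richness if the group were lost. Negative values
#' are possible (a depauperate group can raise pooled AR when removed).
#'
#' @inheritParams rarefied_ar
#' @return list of class `richness_result` with `richness` additionally
#'   carrying `AR_loo` (= AR(-i)) and `contribution` columns.
#' @export
loo_contributions <- function(g, map, g_copies = 8, listwise = TRUE) {
  map <- align_map(g, map)
  grp <- group_labels(map)
  groups <- unique(grp)
  if (length(groups) < 2) stop("need at least 2 groups")
  base <- rarefied_ar(g, map, g_copies = g_copies, listwise = listwise)
  if (base$total_ar <= 1)
    stop("total AR = 1 (all loci monomorphic): contributions undefined")
  m <- unclass(g)
  use <- rep(FALSE, ncol(m)); use[base$loci_used] <- TRUE
  ar_loo <- vapply(groups, function(gk) {
    sub <- m[grp != gk, , drop = FALSE]
    cc <- allele_counts(sub)
    ok <- use & cc$N >= g_copies
    mean(rarefaction_curve(cc$alt[ok], cc$N[ok], g_copies))
  }, numeric(1))
  base$richness$AR_loo <- ar_loo[base$richness$group]
  base$richness$contribution <-
    (base$total_ar - base$richness$AR_loo) / (base$total_ar - 1)
  base
}

group_labels <- function(map) {
  if ("group" %in% names(map)) as.character(map$group) else map$population
}

#' @export
print.richness_result <- function(x, ...) {
  cat(sprintf("Rarefied allelic richness (g = %d copies, %d loci); AR(t) = %.3f\n",
              x$g_copies, length(x$loci_used), x$total_ar))
  tab <- x$richness
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Resampled exact maximum-coverage prioritisation of population groups
#'
#' Emulates a reserve-selection analysis under a maximum-coverage (of
#' alleles) objective with unit cost per group: in each iteration
#' `n_per_pop` individuals are drawn per group without replacement, an
#' allele-presence matrix is built (an allele is covered by a group iff
#' at least one copy is observed in the subsample), and for each budget
#' `b` the optimal subset of `b` groups is found exactly by enumerating
#' all subsets. Ties on coverage are broken by the rarefied allelic
#' richness of the selected union, then by lexicographic group order
#' (never randomised, so selection-frequency splits reflect resampling
#' variation only).
#'
#' @inheritParams rarefied_ar
#' @param budgets integer budgets (numbers of groups conserved); budgets
#'   above the number of groups are capped with a warning.
#' @param n_iter resampling iterations (default 100).
#' @param n_per_pop individuals drawn per group per iteration (default 4).
#' @param seed integer seed for the resampling.
#' @return list of class `prioritization_result`: `selection_freq`
#'   (budget x group proportion of iterations selected), `coverage`
#'   (data.frame per budget: mean/min/max proportion of alleles covered,
#'   mean rarefied AR of the selected union), and `iterations` (list of
#'   per-iteration chosen sets).
#' @export
max_coverage <- function(g, map, budgets = 1:5, n_iter = 100, n_per_pop = 4,
                         g_copies = 8, seed = 1L) {
  map <- align_map(g, map)
  grp <- group_labels(map)
  groups <- sort(unique(grp))
  G <- length(groups)
  n_by_group <- vapply(groups, function(gk) sum(grp == gk), numeric(1))
  if (any(n_by_group < n_per_pop))
    stop("group(s) with fewer than n_per_pop individuals: ",
         paste(groups[n_by_group < n_per_pop], collapse = ", "),
         " (merge small groups upstream via a 'group' column)")
  if (any(budgets > G)) {
    warning("budgets above the number of groups capped at ", G)
    budgets <- pmin(budgets, G)
  }
  budgets <- sort(unique(as.integer(budgets)))
  m <- unclass(g)
  set.seed(seed)
  sel_count <- matrix(0, length(budgets), G,
                      dimnames = list(paste0("budget_", budgets), groups))
  cov_stats <- array(NA_real_, c(length(budgets), n_iter, 2))
  iterations <- vector("list", n_iter)
  subsets <- lapply(budgets, function(b) utils::combn(G, b, simplify = FALSE))
  for (it in seq_len(n_iter)) {
    rows <- unlist(lapply(groups, function(gk)
      sample(which(grp == gk), n_per_pop)))
    sub <- m[rows, , drop = FALSE]
    sgrp <- rep(groups, each = n_per_pop)
    # presence: group x allele (ref and alt per locus)
    cnts <- lapply(groups, function(gk)
      allele_counts(sub[sgrp == gk, , drop = FALSE]))
    alt_pres <- vapply(cnts, function(x) x$alt > 0, logical(ncol(m)))
    ref_pres <- vapply(cnts, function(x) x$N - x$alt > 0, logical(ncol(m)))
    pres <- rbind(alt_pres, ref_pres)      # allele x group
    total_alleles <- sum(rowSums(pres) > 0)
    chosen <- vector("list", length(budgets))
    for (bi in seq_along(budgets)) {
      best <- NULL; best_cov <- -1; best_ar <- -Inf
      for (s in subsets[[bi]]) {
        covered <- sum(rowSums(pres[, s, drop = FALSE]) > 0)
        if (covered > best_cov) {
          best <- s; best_cov <- covered
          best_ar <- union_ar(sub, sgrp, groups[s], g_copies)
        } else if (covered == best_cov) {
          ar <- union_ar(sub, sgrp, groups[s], g_copies)
          if (ar > best_ar + 1e-12) { best <- s; best_ar <- ar }
        }
      }
      sel_count[bi, best] <- sel_count[bi, best] + 1
      cov_stats[bi, it, 1] <- best_cov / total_alleles
      cov_stats[bi, it, 2] <- best_ar
      chosen[[bi]] <- groups[best]
    }
    iterations[[it]] <- stats::setNames(chosen, paste0("budget_", budgets))
  }
  coverage <- data.frame(
    budget = budgets,
    mean_coverage = apply(cov_stats[, , 1, drop = FALSE], 1, mean),
    min_coverage = apply(cov_stats[, , 1, drop = FALSE], 1, min),
    max_coverage = apply(cov_stats[, , 1, drop = FALSE], 1, max),
    mean_AR = apply(cov_stats[, , 2, drop = FALSE], 1, mean))
  structure(list(selection_freq = sel_count / n_iter, coverage = coverage,
                 iterations = iterations, budgets = budgets,
                 n_iter = n_iter, n_per_pop = n_per_pop, seed = seed),
            class = "prioritization_result")
}

# pooled rarefied AR of the union of selected groups in a subsample
union_ar <- function(sub, sgrp, sel_groups, g_copies) {
  cc <- allele_counts(sub[sgrp %in% sel_groups, , drop = FALSE])
  ok <- cc$N >= g_copies
  if (!any(ok)) return(NA_real_)
  mean(rarefaction_curve(cc$alt[ok], cc$N[ok], g_copies))
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf("Maximum-coverage prioritisation: %d iterations, %d individuals/group\n",
              x$n_iter, x$n_per_pop))
  cat("Selection frequency by budget:\n")
  print(round(x$selection_freq, 2))
  cat("Coverage by budget:\n")
  print(transform(x$coverage,
                  mean_coverage = round(mean_coverage, 3),
                  min_coverage = round(min_coverage, 3),
                  max_coverage = round(max_coverage, 3),
                  mean_AR = round(mean_AR, 3)), row.names = FALSE)
  invisible(x)
}
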