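#' Complete-case SNP panel
#'
#' Drops every locus with at least one missing genotype (the hierarchical
#' diversity cascade requires complete data).
#'
#' @param g a [genotype_matrix()].
#' @return the reduced `genotype_matrix`.
#' @export
complete_case_panel <- function(g) {
  keep <- colSums(is.na(g)) == 0L
  message(sum(!keep), " loci with missing genotypes removed; ",
          sum(keep), " retained")
  if (!any(keep)) stop("no complete-case loci remain")
  g[, keep]
}

#' Rao quadratic entropy of a set of allele-frequency vectors
#'
#' With unit mismatch distance between distinct alleles the per-locus
#' quadratic entropy collapses to the Simpson/gene-diversity form
#' `Q_l = 1 - sum_a p_a^2`. Loci are aggregated through effective
#' diversities: `D_l = 1 / (1 - Q_l)`, the stratum effective diversity is
#' the arithmetic mean of `D_l` over loci, and the stratum
#' `Q = 1 - 1 / D`.
#'
#' @param p alternate-allele frequencies, one per locus (biallelic).
#' @return list with the stratum `Q`, effective diversity `D`, and the
#'   per-locus effective diversities `D_locus`.
#' @export
rao_q <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q_locus <- 1 - (p^2 + (1 - p)^2)
  d_locus <- 1 / (1 - q_locus)
  D <- mean(d_locus)
  list(Q = 1 - 1 / D, D = D, D_locus = d_locus)
}

#' Hierarchical diversity cascade from Rao's quadratic entropy
#'
#' Partitions standardised genomic diversity into a cascade of strata:
#' grand-total gamma, among-region delta, within-region sigma, among-
#' population-within-region beta, and within-population alpha. All
#' components live in effective-diversity space where the partition is
#' multiplicative: `D_GT = D_AR x mean_r D_WR(r)` and
#' `D_WR(r) = D_AP(r) x mean_p D_alpha(p)`, with stratum means weighted
#' by sample size by default. Q values are `1 - 1/D`. Homogeneity of the
#' within-region per-locus diversities is tested with Bartlett's test,
#' with a label-permutation alternative for the among-population
#' comparison (per-locus D values are far from Gaussian).
#'
#' Requires a complete-case panel ([complete_case_panel()] is applied
#' automatically when missing calls are present).
#'
#' @param g a [genotype_matrix()].
#' @param map a population map.
#' @param weighted use sample-size-weighted stratum means (default TRUE);
#'   FALSE gives unweighted means.
#' @return list of class `diversity_cascade`: `gamma`, `delta`, `sigma`
#'   (per region), `beta` (per region; `NA` for single-population
#'   regions), `alpha` (per population), `bartlett_p`, `n_loci`, plus the
#'   effective diversities (`D_GT`, `D_AR`, `D_WR`, `D_AP`, `D_alpha`)
#'   and a long-format `table`.
#' @export
cascade <- function(g, map, weighted = TRUE) {
  map <- align_map(g, map)
  if (anyNA(g)) g <- suppressMessages(complete_case_panel(g))
  m <- unclass(g)
  pops <- unique(map$population)
  p2r <- unique(map[, c("population", "region")])
  regions <- unique(p2r$region)
  n_pop <- vapply(pops, function(pk) sum(map$population == pk), numeric(1))
  n_reg <- vapply(regions, function(rk) sum(map$region == rk), numeric(1))
  wmean <- function(x, w) if (weighted) sum(x * w) / sum(w) else mean(x)

  freq_of <- function(rows) colSums(m[rows, , drop = FALSE]) / (2 * length(rows))
  d_alpha <- vapply(pops, function(pk) rao_q(freq_of(which(map$population == pk)))$D,
                    numeric(1))
  reg_q <- lapply(regions, function(rk) rao_q(freq_of(which(map$region == rk))))
  names(reg_q) <- regions
  d_wr <- vapply(reg_q, `[[`, numeric(1), "D")
  grand <- rao_q(freq_of(seq_len(nrow(m))))

  d_ar <- grand$D / wmean(d_wr, n_reg)
  d_ap <- vapply(regions, function(rk) {
    pk <- p2r$population[p2r$region == rk]
    if (length(pk) < 2) return(NA_real_)
    d_wr[rk] / wmean(d_alpha[pk], n_pop[pk])
  }, numeric(1))

  alpha <- 1 - 1 / d_alpha
  sigma <- 1 - 1 / d_wr
  beta <- 1 - 1 / d_ap
  delta <- 1 - 1 / d_ar
  gamma <- grand$Q

  bartlett_p <- if (length(regions) >= 2) {
    dl <- lapply(reg_q, `[[`, "D_locus")
    stats::bartlett.test(unlist(dl),
                         factor(rep(regions, each = ncol(m))))$p.value
  } else NA_real_

  tab <- rbind(
    data.frame(parameter = "gamma", region = "", population = "", Q = gamma),
    data.frame(parameter = "delta", region = "", population = "", Q = delta),
    data.frame(parameter = "sigma", region = regions, population = "", Q = sigma),
    data.frame(parameter = "beta", region = regions, population = "", Q = beta),
    data.frame(parameter = "alpha", region = p2r$region[match(pops, p2r$population)],
               population = pops, Q = alpha))
  rownames(tab) <- NULL
  structure(list(gamma = gamma, delta = delta, sigma = sigma, beta = beta,
                 alpha = alpha, bartlett_p = bartlett_p, n_loci = ncol(m),
                 D_GT = grand$D, D_AR = d_ar, D_WR = d_wr, D_AP = d_ap,
                 D_alpha = d_alpha, weighted = weighted,
                 n_region = n_reg, n_population = n_pop, table = tab),
            class = "diversity_cascade")
}

#' @export
print.diversity_cascade <- function(x, ...) {
  cat(sprintf("Diversity cascade over %d loci (%s stratum means)\n",
              x$n_loci, if (x$weighted) "weighted" else "unweighted"))
  tab <- x$table
  tab$Q <- round(tab$Q, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Bartlett within-region homogeneity: P = %.3f\n", x$bartlett_p))
  invisible(x)
}

#' Permutation test for among-population diversity between regions
#'
#' Compares a region's among-population component (beta) against a null
#' in which populations are reassigned to regions at random, preserving
#' region sizes. Reported per region as the proportion of permutations
#' with a beta at least as large.
#'
#' @param g a [genotype_matrix()].
#' @param map a population map.
#' @param n_perm number of permutations.
#' @param weighted passed to [cascade()].
#' @return named vector of one-sided p-values per region.
#' @export
beta_permutation_test <- function(g, map, n_perm = 199, weighted = TRUE) {
  map <- align_map(g, map)
  obs <- cascade(g, map, weighted = weighted)
  p2r <- unique(map[, c("population", "region")])
  hits <- setNames(rep(1, length(obs$beta)), names(obs$beta))
  n_eval <- setNames(rep(1, length(obs$beta)), names(obs$beta))
  for (i in seq_len(n_perm)) {
    perm <- p2r
    perm$region <- sample(perm$region)
    pm <- map
    pm$region <- perm$region[match(pm$population, perm$population)]
    b <- cascade(g, pm, weighted = weighted)$beta
    for (rk in names(hits)) {
      if (is.na(obs$beta[rk]) || !(rk %in% names(b)) || is.na(b[rk])) next
      n_eval[rk] <- n_eval[rk] + 1
      if (b[rk] >= obs$beta[rk]) hits[rk] <- hits[rk] + 1
    }
  }
  hits / n_eval
}
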