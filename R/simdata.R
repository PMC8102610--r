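#' Simulation configuration for the hierarchical Balding-Nichols generator
#'
#' Defines a two-level island-model hierarchy (regions, i.e. lineages,
#' containing populations) from which synthetic biallelic SNP genotypes,
#' a population map with coordinates, and per-sample environmental
#' vectors are drawn. Defaults emulate the sampling design of a
#' strongly structured declining mammal: two lineages, four populations
#' with 6-15 individuals each, ~10^4 SNPs, between-lineage
#' differentiation far exceeding within-lineage differentiation, ~2%
#' missing genotypes, and region-specific environmental distributions
#' with non-overlapping niches.
#'
#' @param n_regions number of regions (lineages).
#' @param pops_per_region integer vector, populations per region.
#' @param n_per_pop integer vector (recycled) of individuals per population.
#' @param n_loci number of biallelic SNP loci.
#' @param f_region Balding-Nichols divergence of regions from the
#'   ancestral pool, in `[0, 1)`.
#' @param f_pop divergence of populations from their region, in `[0, 1)`.
#' @param ancestral_maf_range interval in (0, 0.5] for the folded
#'   ancestral minor-allele frequency (drawn uniformly).
#' @param missing_rate proportion of genotype calls dropped completely at
#'   random.
#' @param n_kin_pairs number of planted parent-offspring pairs; each
#'   replaces one individual with a Mendelian offspring of two others in
#'   the same population.
#' @param n_dup_loci number of planted duplicated loci (exact copies of a
#'   random locus placed nearby on the same scaffold) for exercising LD
#'   pruning; simulated loci are otherwise unlinked.
#' @param env_means matrix `n_regions` x 5 of regional environmental
#'   means (annual rainfall mm, max temp hottest month degC, min temp
#'   coldest month degC, elevation m, ruggedness index).
#' @param env_sd matrix (or vector recycled) of regional environmental SDs.
#' @param geo_centroids matrix `n_pops` x 2 of population (lat, lon)
#'   centroids in decimal degrees; default lays regions ~600 km apart and
#'   populations ~100 km apart.
#' @param geo_scatter_km within-population coordinate scatter (SD, km).
#' @param loci_per_scaffold loci per synthetic scaffold; positions are
#'   uniformly spaced `locus_spacing_bp` apart.
#' @param locus_spacing_bp spacing between adjacent locus positions.
#' @param seed integer seed; identical configuration and seed give a
#'   bit-identical dataset.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [expected_fst()]
#' @export
sim_config <- function(n_regions = 2,
                       pops_per_region = c(2, 2),
                       n_per_pop = c(15, 10, 6, 11),
                       n_loci = 10000,
                       f_region = 0.5,
                       f_pop = 0.05,
                       ancestral_maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       n_kin_pairs = 0,
                       n_dup_loci = 0,
                       env_means = NULL,
                       env_sd = NULL,
                       geo_centroids = NULL,
                       geo_scatter_km = 2,
                       loci_per_scaffold = 500,
                       locus_spacing_bp = 10000,
                       seed = 1L) {
  stopifnot(n_regions >= 1, length(pops_per_region) == n_regions,
            all(pops_per_region >= 1))
  n_pops <- sum(pops_per_region)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  stopifnot(all(n_per_pop >= 1), n_loci >= 1,
            f_region >= 0, f_region < 1, f_pop >= 0, f_pop < 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            n_kin_pairs >= 0, n_dup_loci >= 0, geo_scatter_km >= 0)
  if (n_kin_pairs > 0 && all(n_per_pop < 3))
    stop("kin planting needs at least one population with >= 3 individuals")
  if (is.null(env_means)) {
    # disjoint regional niches: wetter/hotter lowland vs drier rugged upland,
    # stepped so pooled-SD separation is large
    base <- c(rain_mm = 1400, tmax_c = 34, tmin_c = 17,
              elev_m = 50, rugged = 1.5)
    step <- c(-600, 2.5, 4, 180, 2.5)
    env_means <- t(vapply(seq_len(n_regions) - 1L,
                          function(r) base + r * step, numeric(5)))
    colnames(env_means) <- names(base)
  }
  env_means <- as.matrix(env_means)
  stopifnot(nrow(env_means) == n_regions, ncol(env_means) == 5)
  if (is.null(env_sd)) {
    # later regions emulate insular lineages confined to an increasingly
    # narrow envelope of conditions, so niche volumes differ strongly
    env_sd <- outer(0.4^(seq_len(n_regions) - 1), c(60, 0.4, 0.5, 20, 0.3))
  }
  if (!is.matrix(env_sd))
    env_sd <- matrix(rep_len(env_sd, 5), n_regions, 5, byrow = TRUE)
  stopifnot(all(env_sd > 0), nrow(env_sd) == n_regions)
  if (is.null(geo_centroids)) {
    region_of_pop <- rep(seq_len(n_regions), pops_per_region)
    idx_in_region <- unlist(lapply(pops_per_region, seq_len))
    # ~5.4 deg (~600 km) between regions, ~0.9 deg (~100 km) between pops
    geo_centroids <- cbind(lat = -12 - 0.9 * (idx_in_region - 1),
                           lon = 125 + 5.4 * (region_of_pop - 1))
  }
  geo_centroids <- as.matrix(geo_centroids)
  stopifnot(nrow(geo_centroids) == n_pops, ncol(geo_centroids) == 2)
  structure(list(n_regions = n_regions, pops_per_region = pops_per_region,
                 n_per_pop = n_per_pop, n_loci = as.integer(n_loci),
                 f_region = f_region, f_pop = f_pop,
                 ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate,
                 n_kin_pairs = as.integer(n_kin_pairs),
                 n_dup_loci = as.integer(n_dup_loci),
                 env_means = env_means, env_sd = env_sd,
                 geo_centroids = geo_centroids,
                 geo_scatter_km = geo_scatter_km,
                 loci_per_scaffold = as.integer(loci_per_scaffold),
                 locus_spacing_bp = as.integer(locus_spacing_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected pairwise F_ST under the hierarchical Balding-Nichols model
#'
#' Divergence compounds multiplicatively across levels: two populations in
#' different regions have expected differentiation
#' `1 - (1 - f_region) * (1 - f_pop)`; two populations within one region
#' have `f_pop`.
#'
#' @param f_region,f_pop divergence parameters in `[0, 1)`.
#' @return list with `between_region` and `within_region` expected F_ST.
#' @export
expected_fst <- function(f_region, f_pop) {
  stopifnot(f_region >= 0, f_region < 1, f_pop >= 0, f_pop < 1)
  list(between_region = 1 - (1 - f_region) * (1 - f_pop),
       within_region = f_pop)
}

#' Simulate a hierarchical SNP dataset
#'
#' Draws an ancestral folded minor-allele frequency per locus, regional
#' frequencies by Balding-Nichols drift (`f_region`), population
#' frequencies by a second round of drift (`f_pop`), and genotypes as
#' `Binomial(2, p)` under Hardy-Weinberg. Optionally plants
#' parent-offspring pairs (Mendelian transmission), duplicated loci, and
#' completely-at-random missing calls. Environmental vectors are Gaussian
#' per region; coordinates scatter around population centroids.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]),
#'   `popmap` (sample, population, region, lat, lon), `env` (sample plus
#'   five environmental variables), `pop_freqs` (population-level allele
#'   frequencies actually used, loci x populations) and `kin_pairs`
#'   (planted trios: both parents and the offspring, if any; the
#'   offspring forms a parent-offspring pair with each parent).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  n_pops <- sum(cf$pops_per_region)
  region_of_pop <- rep(seq_len(cf$n_regions), cf$pops_per_region)
  pop_names <- paste0("pop", seq_len(n_pops))
  region_names <- paste0("region", seq_len(cf$n_regions))

  L <- cf$n_loci
  p0 <- stats::runif(L, cf$ancestral_maf_range[1], cf$ancestral_maf_range[2])
  p_region <- vapply(seq_len(cf$n_regions),
                     function(r) rbn_vec(p0, cf$f_region),
                     numeric(L))
  p_pop <- vapply(seq_len(n_pops),
                  function(k) rbn_vec(p_region[, region_of_pop[k]], cf$f_pop),
                  numeric(L))
  colnames(p_pop) <- pop_names

  n_tot <- sum(cf$n_per_pop)
  pop_of_sample <- rep(seq_len(n_pops), cf$n_per_pop)
  sample_ids <- paste0(pop_names[pop_of_sample], "_i",
                       unlist(lapply(cf$n_per_pop, seq_len)))
  dosage <- matrix(0L, n_tot, L, dimnames = list(sample_ids, NULL))
  for (k in seq_len(n_pops)) {
    rows <- which(pop_of_sample == k)
    dosage[rows, ] <- matrix(stats::rbinom(length(rows) * L, 2, rep(p_pop[, k], each = length(rows))),
                             nrow = length(rows))
  }

  # plant parent-offspring pairs: a third individual of the population is
  # replaced by a Mendelian offspring of the first two
  kin_pairs <- NULL
  if (cf$n_kin_pairs > 0) {
    eligible <- which(cf$n_per_pop >= 3)
    host <- rep_len(eligible, cf$n_kin_pairs)
    used <- integer(0)
    kin <- vector("list", cf$n_kin_pairs)
    for (q in seq_len(cf$n_kin_pairs)) {
      rows <- setdiff(which(pop_of_sample == host[q]), used)
      if (length(rows) < 3) next
      p1 <- rows[1]; p2 <- rows[2]; child <- rows[3]
      gam1 <- stats::rbinom(L, 1, dosage[p1, ] / 2)
      gam2 <- stats::rbinom(L, 1, dosage[p2, ] / 2)
      dosage[child, ] <- gam1 + gam2
      used <- c(used, p1, p2, child)
      kin[[q]] <- data.frame(parent_1 = sample_ids[p1],
                             parent_2 = sample_ids[p2],
                             offspring = sample_ids[child],
                             population = pop_names[host[q]])
    }
    kin_pairs <- do.call(rbind, kin)
  }

  # duplicated loci for LD-pruning tests: exact copies placed one spacing away
  scaffold <- paste0("scaffold_", (seq_len(L) - 1L) %/% cf$loci_per_scaffold + 1L)
  pos_in_scaf <- (seq_len(L) - 1L) %% cf$loci_per_scaffold
  position <- pos_in_scaf * cf$locus_spacing_bp + 1L
  if (cf$n_dup_loci > 0) {
    src <- sample(L, cf$n_dup_loci, replace = cf$n_dup_loci > L)
    dosage <- cbind(dosage, dosage[, src, drop = FALSE])
    scaffold <- c(scaffold, scaffold[src])
    position <- c(position, position[src] + cf$locus_spacing_bp %/% 2L)
    p_pop <- rbind(p_pop, p_pop[src, , drop = FALSE])
  }
  Ltot <- ncol(dosage)
  colnames(dosage) <- paste0("L", seq_len(Ltot))
  rownames(p_pop) <- colnames(dosage)

  if (cf$missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < cf$missing_rate
    dosage[miss] <- NA_integer_
  }

  g <- genotype_matrix(dosage, scaffold, position)

  # coordinates: Gaussian scatter around centroids (1 deg lat ~ 111.19 km)
  km_per_deg <- 111.19
  lat <- cf$geo_centroids[pop_of_sample, 1] +
    stats::rnorm(n_tot, 0, cf$geo_scatter_km / km_per_deg)
  lon <- cf$geo_centroids[pop_of_sample, 2] +
    stats::rnorm(n_tot, 0, cf$geo_scatter_km /
                   (km_per_deg * cos(cf$geo_centroids[pop_of_sample, 1] * pi / 180)))
  popmap <- data.frame(sample = sample_ids,
                       population = pop_names[pop_of_sample],
                       region = region_names[region_of_pop[pop_of_sample]],
                       lat = lat, lon = lon, stringsAsFactors = FALSE)

  region_of_sample <- region_of_pop[pop_of_sample]
  env <- cf$env_means[region_of_sample, , drop = FALSE] +
    matrix(stats::rnorm(n_tot * 5), n_tot, 5) * cf$env_sd[region_of_sample, , drop = FALSE]
  env <- data.frame(sample = sample_ids, env, stringsAsFactors = FALSE)

  list(genotypes = g, popmap = popmap, env = env,
       pop_freqs = p_pop, kin_pairs = kin_pairs, config = cf)
}

# vectorised Balding-Nichols draw of daughter frequencies around per-locus
# parent frequencies p with divergence f; f = 0 is the exact no-drift limit
rbn_vec <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}
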